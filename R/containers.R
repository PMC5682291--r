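#' @useDynLib traitdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile rnorm runif fft lm coef rgamma cor
#' @importFrom utils write.csv read.csv
NULL

#' Single-band trait raster
#'
#' A numeric matrix of trait values on a regular grid with known pixel size.
#' Values are stored row/col with the origin at the top-left corner; `NA`
#' marks nodata. After [normalize_trait()] all valid values lie in `[0, 1]`.
#'
#' @param values numeric matrix of trait values (`NA` = nodata).
#' @param trait_name name of the trait, one of `"CH"`, `"PAI"`, `"FHD"`,
#'   `"CHL"`, `"CAR"`, `"EWT"`, or any label for intermediate products.
#' @param pixel_size pixel edge length in metres (> 0).
#' @param normalized logical; `TRUE` once values have been min-max scaled.
#' @return An object of class `trait_raster`.
#' @export
trait_raster <- function(values, trait_name, pixel_size, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  if (normalized) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("normalized trait raster has values outside [0, 1]")
  }
  structure(
    list(values = values, trait_name = as.character(trait_name),
         pixel_size = pixel_size, normalized = isTRUE(normalized)),
    class = "trait_raster")
}

#' @export
print.trait_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<trait_raster> %s: %d x %d px @ %g m, %d valid, range [%s]\n",
              x$trait_name, nrow(x$values), ncol(x$values), x$pixel_size,
              length(v),
              if (length(v)) sprintf("%.4g, %.4g", min(v), max(v)) else "-"))
  invisible(x)
}

#' Aligned stack of three trait rasters with a forest mask
#'
#' The central input of the diversity mapping: three normalized trait layers
#' of one family (morphological CH/FHD/PAI or physiological CHL/CAR/EWT) on
#' an identical grid, plus a logical forest mask. The mask is intersected
#' with trait validity, so `mask[i, j]` is `TRUE` only where all three
#' traits are non-nodata.
#'
#' @param traits list of three [trait_raster] objects on identical grids.
#' @param forest_mask logical matrix, same dimensions; `NULL` means all
#'   pixels are candidate forest.
#' @return An object of class `trait_stack` with elements `traits`, `mask`,
#'   `pixel_size`, `trait_names`.
#' @export
trait_stack <- function(traits, forest_mask = NULL) {
  stopifnot(is.list(traits), length(traits) == 3L)
  for (t in traits) {
    if (!inherits(t, "trait_raster")) stop("traits must be trait_raster objects")
  }
  dims <- vapply(traits, function(t) dim(t$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("trait rasters have mismatching grids: ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = " vs "))
  ps <- vapply(traits, function(t) t$pixel_size, numeric(1))
  if (max(ps) - min(ps) > 1e-9)
    stop("trait rasters have mismatching pixel sizes")
  d <- dims[, 1]
  if (is.null(forest_mask)) forest_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(forest_mask), all(dim(forest_mask) == d))
  valid <- !is.na(traits[[1]]$values) & !is.na(traits[[2]]$values) &
    !is.na(traits[[3]]$values)
  mask <- forest_mask & valid
  structure(
    list(traits = traits, mask = mask, pixel_size = ps[1],
         trait_names = vapply(traits, function(t) t$trait_name, character(1))),
    class = "trait_stack")
}

#' @export
print.trait_stack <- function(x, ...) {
  cat(sprintf("<trait_stack> [%s]: %d x %d px @ %g m, %d forest pixels\n",
              paste(x$trait_names, collapse = ", "),
              nrow(x$mask), ncol(x$mask), x$pixel_size, sum(x$mask)))
  invisible(x)
}

# matrix of masked trait triplets (one row per forest pixel, column-major
# pixel order), with the flat pixel index as rownames-free attribute
stack_points <- function(stack) {
  idx <- which(stack$mask)
  pts <- cbind(stack$traits[[1]]$values[idx],
               stack$traits[[2]]$values[idx],
               stack$traits[[3]]$values[idx])
  colnames(pts) <- stack$trait_names
  attr(pts, "pixel_index") <- idx
  pts
}

#' Wavelength-indexed reflectance cube
#'
#' @param values numeric array `(band, row, col)` of reflectance factors.
#'   Valid values lie in `[0, 1.5]` (slight atmospheric overcorrection is
#'   tolerated); `NA` = nodata.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @param pixel_size pixel edge length in metres.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(values, wavelengths, pixel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(wavelengths) != dim(values)[1])
    stop("need one wavelength per band")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1.5))
    stop("reflectance outside [0, 1.5]")
  stopifnot(pixel_size > 0)
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 pixel_size = pixel_size),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  cat(sprintf("<reflectance_cube> %d bands (%g-%g nm), %d x %d px @ %g m\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              dim(x$values)[2], dim(x$values)[3], x$pixel_size))
  invisible(x)
}

#' Vertical plant-area profile stack
#'
#' Per-pixel vertical profiles of plant area density, the input of the
#' foliage height diversity computation. Layer 1 is the lowest canopy layer.
#'
#' @param pai_per_layer numeric array `(layer, row, col)` of plant area per
#'   layer; all values >= 0.
#' @param layer_thickness vertical bin thickness in metres.
#' @param pixel_size pixel edge length in metres.
#' @return An object of class `vertical_profile_stack`.
#' @export
vertical_profile_stack <- function(pai_per_layer, layer_thickness,
                                   pixel_size) {
  stopifnot(is.array(pai_per_layer), length(dim(pai_per_layer)) == 3L,
            dim(pai_per_layer)[1] >= 1L)
  v <- pai_per_layer[!is.na(pai_per_layer)]
  if (length(v) && min(v) < 0) stop("plant area per layer must be >= 0")
  stopifnot(layer_thickness > 0, pixel_size > 0)
  structure(list(pai_per_layer = pai_per_layer,
                 layer_thickness = layer_thickness, pixel_size = pixel_size),
            class = "vertical_profile_stack")
}

#' Canopy height model
#'
#' @param heights numeric matrix of canopy heights in metres (`NA` = nodata);
#'   valid heights are >= 0.
#' @param pixel_size pixel edge length in metres.
#' @return An object of class `canopy_height_model`.
#' @export
canopy_height_model <- function(heights, pixel_size) {
  stopifnot(is.matrix(heights), pixel_size > 0)
  v <- heights[!is.na(heights)]
  if (length(v) && min(v) < 0) stop("canopy heights must be >= 0")
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "canopy_height_model")
}
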