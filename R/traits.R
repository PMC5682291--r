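#' Foliage height diversity from vertical plant-area profiles
#'
#' Applies the Shannon-Wiener index to each pixel's vertical profile:
#' \deqn{FHD = -\sum_i p_i \ln p_i}
#' where \eqn{p_i} is the proportion of the total plant area in canopy layer
#' \eqn{i}. Layers with zero plant area contribute nothing; pixels whose
#' profile is entirely zero (or nodata) become nodata. The result is an
#' un-normalized trait raster; pass it through [normalize_trait()] before
#' stacking.
#'
#' @param profile a [vertical_profile_stack].
#' @return A [trait_raster] named `"FHD"`.
#' @export
compute_fhd <- function(profile) {
  stopifnot(inherits(profile, "vertical_profile_stack"))
  a <- profile$pai_per_layer
  d <- dim(a)
  tot <- apply(a, c(2, 3), function(v) sum(v, na.rm = TRUE))
  out <- matrix(NA_real_, d[2], d[3])
  ok <- which(tot > 0)
  for (i in ok) {
    r <- (i - 1L) %% d[2] + 1L
    c <- (i - 1L) %/% d[2] + 1L
    p <- a[, r, c]
    p <- p[!is.na(p) & p > 0] / tot[i]
    out[r, c] <- -sum(p * log(p))
  }
  trait_raster(out, "FHD", profile$pixel_size)
}

#' Mean reflectance over a wavelength window
#'
#' Unweighted mean across all bands whose centre wavelength lies in the
#' closed interval `[lo, hi]` nm.
#'
#' @param cube a [reflectance_cube].
#' @param lo,hi window bounds in nm.
#' @return Numeric matrix of per-pixel mean reflectance.
#' @export
band_mean <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "reflectance_cube"), lo <= hi)
  sel <- which(cube$wavelengths >= lo & cube$wavelengths <= hi)
  if (!length(sel))
    stop(sprintf("no band in requested range %g-%g nm", lo, hi))
  d <- dim(cube$values)
  if (length(sel) == 1L) return(matrix(cube$values[sel, , ], d[2], d[3]))
  matrix(apply(cube$values[sel, , , drop = FALSE], c(2, 3), mean),
         d[2], d[3])
}

# shared shape of the two three-band pigment indices:
# (1/R_a - 1/R_b) * R_nir, nodata where a window mean is 0 or nodata
three_band_index <- function(cube, win_a, win_b, name) {
  ra <- band_mean(cube, win_a[1], win_a[2])
  rb <- band_mean(cube, win_b[1], win_b[2])
  rn <- band_mean(cube, 760, 800)
  bad <- is.na(ra) | is.na(rb) | is.na(rn) | ra == 0 | rb == 0
  out <- (1 / ra - 1 / rb) * rn
  out[bad] <- NA_real_
  trait_raster(out, name, cube$pixel_size)
}

#' Relative chlorophyll index from a reflectance cube
#'
#' Three-band pigment model:
#' \deqn{CHL = (1/R_{540-560} - 1/R_{760-800}) \cdot R_{760-800}}
#' where \eqn{R_{i-j}} is the mean reflectance over the i-j nm window.
#' Pixels with zero reflectance in a required window become nodata.
#'
#' @param cube a [reflectance_cube] covering 540-560 and 760-800 nm.
#' @return An un-normalized [trait_raster] named `"CHL"`.
#' @export
chl_index <- function(cube) {
  three_band_index(cube, c(540, 560), c(760, 800), "CHL")
}

#' Relative carotenoid index from a reflectance cube
#'
#' \deqn{CAR = (1/R_{510-520} - 1/R_{690-710}) \cdot R_{760-800}}
#'
#' @param cube a [reflectance_cube] covering 510-520, 690-710 and
#'   760-800 nm.
#' @return An un-normalized [trait_raster] named `"CAR"`.
#' @export
car_index <- function(cube) {
  three_band_index(cube, c(510, 520), c(690, 710), "CAR")
}

#' Relative equivalent water thickness index
#'
#' Simple-ratio water index \eqn{EWT = 1 - R_{1193}/R_{1126}}, using the
#' single band nearest each target wavelength (within `tol` nm; an error is
#' raised if no band is close enough). Negative values are possible and are
#' retained; normalization later maps them into `[0, 1]`.
#'
#' @param cube a [reflectance_cube] with bands near 1126 and 1193 nm.
#' @param tol maximum |band - target| distance in nm (default 10).
#' @return An un-normalized [trait_raster] named `"EWT"`.
#' @export
ewt_index <- function(cube, tol = 10) {
  nearest <- function(target) {
    d <- abs(cube$wavelengths - target)
    i <- which.min(d)
    if (d[i] > tol)
      stop(sprintf("no band within %g nm of %g nm (nearest: %g nm)",
                   tol, target, cube$wavelengths[i]))
    i
  }
  d <- dim(cube$values)
  r1193 <- matrix(cube$values[nearest(1193), , ], d[2], d[3])
  r1126 <- matrix(cube$values[nearest(1126), , ], d[2], d[3])
  bad <- is.na(r1193) | is.na(r1126) | r1126 == 0
  out <- 1 - r1193 / r1126
  out[bad] <- NA_real_
  trait_raster(out, "EWT", cube$pixel_size)
}

#' Aggregate a fine raster by averaging the brightest pixels per block
#'
#' Reduces each `factor` x `factor` block (e.g. 3 x 3, 2 m to 6 m) to the
#' mean trait value of its `n_brightest` brightest valid pixels, a
#' shadow-suppression step: shaded pixels are dark and carry distorted
#' trait retrievals. Blocks with fewer valid pixels use all of them;
#' all-nodata blocks become nodata. Grids that `factor` does not divide are
#' padded with nodata at the bottom/right edge.
#'
#' @param trait a [trait_raster] at fine resolution.
#' @param brightness numeric matrix aligned with `trait` (by default the
#'   mean 760-800 nm reflectance, the least shadow-distorted window).
#' @param factor integer block edge (3 for the standard 2 m to 6 m step).
#' @param n_brightest number of pixels averaged per block (default 3).
#' @return A [trait_raster] at `factor`-times coarser resolution.
#' @export
aggregate_brightest <- function(trait, brightness, factor, n_brightest = 3) {
  stopifnot(inherits(trait, "trait_raster"), is.matrix(brightness))
  if (!all(dim(brightness) == dim(trait$values)))
    stop("brightness grid is not aligned with the trait grid")
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  v <- trait$values
  b <- brightness
  nr <- ceiling(nrow(v) / factor) * factor
  nc <- ceiling(ncol(v) / factor) * factor
  if (nr != nrow(v) || nc != ncol(v)) {
    pad <- function(m) {
      out <- matrix(NA_real_, nr, nc)
      out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      out
    }
    v <- pad(v); b <- pad(b)
  }
  out <- matrix(NA_real_, nr / factor, nc / factor)
  for (i in seq_len(nrow(out))) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(ncol(out))) {
      cols <- ((j - 1) * factor + 1):(j * factor)
      tv <- v[rows, cols]
      bv <- b[rows, cols]
      ok <- which(!is.na(tv) & !is.na(bv))
      if (!length(ok)) next
      sel <- ok[order(bv[ok], decreasing = TRUE)]
      sel <- sel[seq_len(min(n_brightest, length(sel)))]
      out[i, j] <- mean(tv[sel])
    }
  }
  trait_raster(out, trait$trait_name, trait$pixel_size * factor)
}

#' Min-max normalize a trait raster to the unit interval
#'
#' Scene-wide affine rescaling over valid pixels (optionally restricted to a
#' forest mask) so the trait attains 0 and 1. An optional percentile clip
#' (default off) guards against extreme outliers: values are winsorized at
#' the given quantiles before scaling and the result clamped to `[0, 1]`.
#'
#' @param raster a [trait_raster].
#' @param mask optional logical matrix; only `TRUE` pixels define the bounds
#'   (all pixels are still rescaled).
#' @param clip `NULL` (default) or length-2 probabilities, e.g.
#'   `c(0.01, 0.99)`.
#' @return A normalized [trait_raster]; attributes `range_low`/`range_high`
#'   record the bounds used.
#' @export
normalize_trait <- function(raster, mask = NULL, clip = NULL) {
  stopifnot(inherits(raster, "trait_raster"))
  v <- raster$values
  sel <- !is.na(v)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(v)))
    sel <- sel & mask
  }
  vals <- v[sel]
  if (length(vals) < 2L) stop("need at least two valid pixels to normalize")
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] < clip[2])
    bounds <- quantile(vals, probs = clip, names = FALSE, type = 7)
  } else {
    bounds <- range(vals)
  }
  if (diff(bounds) <= 0)
    stop("constant trait raster: zero range, cannot normalize")
  out <- (v - bounds[1]) / (bounds[2] - bounds[1])
  out <- pmin(pmax(out, 0), 1)
  res <- trait_raster(out, raster$trait_name, raster$pixel_size,
                      normalized = TRUE)
  attr(res, "range_low") <- bounds[1]
  attr(res, "range_high") <- bounds[2]
  res
}

# flood fill from the border over `open` cells (4-connectivity); returns
# logical matrix of open cells reachable from the border
reachable_from_border <- function(open) {
  nr <- nrow(open); nc <- ncol(open)
  reach <- matrix(FALSE, nr, nc)
  border <- c(which(open[1, ]) * nr - nr + 1L,
              which(open[nr, ]) * nr,
              which(open[, 1]),
              (nc - 1L) * nr + which(open[, nc]))
  frontier <- unique(border[open[border]])
  reach[frontier] <- TRUE
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    up    <- frontier[r > 1L] - 1L
    down  <- frontier[r < nr] + 1L
    left  <- frontier[frontier > nr] - nr
    right <- frontier[frontier <= (nc - 1L) * nr] + nr
    cand <- c(up, down, left, right)
    cand <- cand[open[cand] & !reach[cand]]
    cand <- unique(cand)
    reach[cand] <- TRUE
    frontier <- cand
  }
  reach
}

#' Derive the forest mask from a canopy height model
#'
#' Three steps: (1) select mature forest as CH >= `mature_height` (removes
#' agricultural fields and grassland); (2) fill gaps fully enclosed by the
#' mature mask, so juvenile patches inside the forest are recovered
#' (4-connected holes not touching the raster border); (3) intersect with
#' CH >= `tree_height` to drop true canopy gaps and understorey.
#'
#' @param chm a [canopy_height_model].
#' @param mature_height mature-forest threshold in metres (default 10).
#' @param tree_height minimum tree height in metres (default 4).
#' @return Logical matrix: `TRUE` = forest.
#' @export
forest_mask <- function(chm, mature_height = 10, tree_height = 4) {
  stopifnot(inherits(chm, "canopy_height_model"))
  h <- chm$heights
  mature <- !is.na(h) & h >= mature_height
  open <- !mature
  holes <- open & !reachable_from_border(open)
  filled <- mature | holes
  filled & !is.na(h) & h >= tree_height
}

#' RGB composite of a normalized trait stack
#'
#' Builds a `(row, col, 3)` array mapping traits to colour channels. The
#' defaults follow the field convention for these trait families:
#' morphological R = CH, G = FHD, B = PAI; physiological R = CAR, G = CHL,
#' B = EWT. Channel values are the normalized traits, passed through
#' unchanged; masked (non-forest) pixels receive `background`.
#'
#' @param stack a normalized [trait_stack].
#' @param channels named character vector mapping `c(R=, G=, B=)` to trait
#'   names present in the stack; `NULL` picks the convention for the stack's
#'   trait family.
#' @param background length-3 numeric in `[0, 1]` for masked pixels.
#' @return Numeric array `(row, col, 3)` in `[0, 1]`.
#' @export
rgb_composite <- function(stack, channels = NULL,
                          background = c(0.85, 0.85, 0.85)) {
  stopifnot(inherits(stack, "trait_stack"), length(background) == 3L)
  nm <- stack$trait_names
  if (is.null(channels)) {
    channels <- if (all(c("CH", "FHD", "PAI") %in% nm)) {
      c(R = "CH", G = "FHD", B = "PAI")
    } else if (all(c("CHL", "CAR", "EWT") %in% nm)) {
      c(R = "CAR", G = "CHL", B = "EWT")
    } else {
      stats::setNames(nm, c("R", "G", "B"))
    }
  }
  if (!all(channels %in% nm))
    stop("unknown trait name in channel assignment: ",
         paste(setdiff(channels, nm), collapse = ", "))
  d <- dim(stack$mask)
  out <- array(NA_real_, c(d, 3L))
  for (k in 1:3) {
    layer <- stack$traits[[match(channels[k], nm)]]$values
    layer[!stack$mask] <- background[k]
    out[, , k] <- layer
  }
  out
}

#' Bilinear block resampling of a trait raster
#'
#' Resamples a raster to a coarser grid (e.g. 2 m morphological traits to
#' the 6 m working resolution) by bilinear interpolation at the coarse
#' pixel centres, clamping sample positions at the raster edge.
#'
#' @param raster a [trait_raster].
#' @param factor coarsening factor (> 1; need not be an integer).
#' @return A [trait_raster] at `pixel_size * factor`.
#' @export
resample_bilinear <- function(raster, factor) {
  stopifnot(inherits(raster, "trait_raster"), factor > 1)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  nr2 <- max(1L, floor(nr / factor))
  nc2 <- max(1L, floor(nc / factor))
  # coarse pixel centres in fine-grid fractional row/col coordinates
  # (fine pixel k has centre k; coarse pixel i spans fine (i-1)f+1 .. i*f)
  rc <- (seq_len(nr2) - 0.5) * factor + 0.5
  cc <- (seq_len(nc2) - 0.5) * factor + 0.5
  rc <- pmin(pmax(rc, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rc), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rc - r0; fc <- cc - c0
  out <- matrix(NA_real_, nr2, nc2)
  for (j in seq_len(nc2)) {
    j0 <- c0[j]; wj <- fc[j]
    a <- v[cbind(r0, rep(j0, nr2))]
    b <- v[cbind(r0 + 1L, rep(j0, nr2))]
    cch <- v[cbind(r0, rep(j0 + 1L, nr2))]
    dch <- v[cbind(r0 + 1L, rep(j0 + 1L, nr2))]
    out[, j] <- (a * (1 - fr) + b * fr) * (1 - wj) +
      (cch * (1 - fr) + dch * fr) * wj
  }
  trait_raster(out, raster$trait_name, raster$pixel_size * factor)
}
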