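#' Write a raster to an ESRI ASCII grid
#'
#' Single-band text raster with the standard 6-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`), readable
#' by common GIS tools. Values are written row by row from the top of the
#' grid.
#'
#' @param obj a [trait_raster], [canopy_height_model], [diversity_map],
#'   numeric or logical matrix.
#' @param path output file path (conventionally `.asc`).
#' @param pixel_size required when `obj` is a bare matrix.
#' @param nodata nodata sentinel written for `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(obj, path, pixel_size = NULL, nodata = -9999) {
  if (inherits(obj, "trait_raster")) {
    v <- obj$values; ps <- obj$pixel_size
  } else if (inherits(obj, "canopy_height_model")) {
    v <- obj$heights; ps <- obj$pixel_size
  } else if (inherits(obj, "diversity_map")) {
    v <- obj$values; ps <- obj$pixel_size
  } else if (is.matrix(obj)) {
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
    v <- obj * 1; ps <- pixel_size
  } else stop("unsupported object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %.10g", ps),
               sprintf("NODATA_value %g", nodata)), con)
  v[is.na(v)] <- nodata
  write.table(format(v, digits = 9, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @param as `"trait_raster"` (default), `"chm"` or `"matrix"`.
#' @param trait_name trait label when `as = "trait_raster"`.
#' @return The requested object; nodata becomes `NA`.
#' @export
read_ascii_grid <- function(path, as = c("trait_raster", "chm", "matrix"),
                            trait_name = "trait") {
  as <- match.arg(as)
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1])
  val <- as.numeric(kv[, 2])
  names(val) <- key
  v <- as.matrix(read.table(path, skip = 6L))
  dimnames(v) <- NULL
  if (nrow(v) != val["nrows"] || ncol(v) != val["ncols"])
    stop("grid dimensions do not match header")
  v[v == val["nodata_value"]] <- NA_real_
  ps <- unname(val["cellsize"])
  switch(as,
         matrix = v,
         chm = canopy_height_model(v, ps),
         trait_raster = trait_raster(v, trait_name, ps))
}

#' Write a reflectance cube as ENVI BSQ
#'
#' Band-sequential float32 binary (`.bsq`) plus a text ENVI header (`.hdr`)
#' carrying the grid dimensions, interleave, byte order, pixel size and the
#' wavelength list in nm.
#'
#' @param cube a [reflectance_cube].
#' @param path output path without extension (writes `path.bsq` and
#'   `path.hdr`).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$values)  # band, row, col
  hdr <- c("ENVI",
           sprintf("samples = %d", d[3]),
           sprintf("lines = %d", d[2]),
           sprintf("bands = %d", d[1]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq",
           sprintf("byte order = %d", as.integer(.Platform$endian == "big")),
           sprintf("pixel size = {%g, %g}", cube$pixel_size,
                   cube$pixel_size),
           sprintf("wavelength units = Nanometers"),
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bsq"), "wb")
  on.exit(close(con))
  # BSQ: band-major, within band row-interleaved by line (row-major)
  for (b in seq_len(d[1])) {
    v <- cube$values[b, , ]
    writeBin(as.numeric(t(v)), con, size = 4L)
  }
  invisible(path)
}

#' Read an ENVI BSQ reflectance cube
#'
#' @param path path without extension, or the `.bsq`/`.hdr` file.
#' @return A [reflectance_cube].
#' @export
read_envi_cube <- function(path) {
  path <- sub("\\.(bsq|hdr)$", "", path)
  hdr <- readLines(paste0(path, ".hdr"))
  grab <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("missing '", key, "' in ENVI header")
    trimws(sub(".*=", "", ln[1]))
  }
  samples <- as.integer(grab("samples"))
  lines_ <- as.integer(grab("lines"))
  bands <- as.integer(grab("bands"))
  wl_ln <- grep("wavelength *= *\\{", hdr)
  if (!length(wl_ln)) stop("missing wavelengths in ENVI header")
  wl_txt <- paste(hdr[wl_ln[1]:length(hdr)], collapse = " ")
  wl_txt <- sub(".*wavelength *= *\\{", "", wl_txt)
  wl_txt <- sub("\\}.*", "", wl_txt)
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  if (length(wl) != bands) stop("wavelength count does not match bands")
  px_ln <- grep("pixel size *= *\\{", hdr, value = TRUE)
  ps <- if (length(px_ln)) {
    as.numeric(strsplit(gsub(".*\\{|\\}.*", "", px_ln[1]), ",")[[1]][1])
  } else 1
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = samples * lines_ * bands, size = 4L)
  cube <- array(NA_real_, c(bands, lines_, samples))
  for (b in seq_len(bands)) {
    seg <- raw[((b - 1) * lines_ * samples + 1):(b * lines_ * samples)]
    cube[b, , ] <- matrix(seg, lines_, samples, byrow = TRUE)
  }
  reflectance_cube(cube, wl, ps)
}

#' Write a diversity-area curve as CSV
#'
#' Columns `radius_m`, `area_m2`, `mean`, `sd`, `n`; full double precision
#' so a re-read curve reproduces fits exactly.
#'
#' @param curve a [diversity_area_curve] data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  df <- as.data.frame(curve)
  df$mean <- sprintf("%.17g", df$mean)
  df$sd <- sprintf("%.17g", df$sd)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diversity-area curve CSV
#'
#' @param path CSV written by [write_curve()].
#' @return A `diversity_area_curve` data.frame.
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  df$mean <- as.numeric(df$mean)
  df$sd <- as.numeric(df$sd)
  class(df) <- c("diversity_area_curve", "data.frame")
  df
}

#' Write a scaling fit as JSON
#'
#' @param fit a `scaling_fit` from [fit_power_law()] or
#'   [fit_logarithmic()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "scaling_fit"))
  keep <- fit[setdiff(names(fit), "fit")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
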