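#' Specification of a synthetic trait landscape
#'
#' Parameters of the seedable landscape generator used for testing and
#' demonstration: three correlated Gaussian random fields with tunable
#' spatial autocorrelation, an altitudinal-style linear gradient, and
#' discrete disturbance patches with shifted trait values.
#'
#' The defaults mimic a temperate mixed mountain forest mapped at 6 m
#' grain: a 200 x 200 pixel scene (1.2 x 1.2 km), autocorrelation lengths
#' of ~60 m (stands of similar structure), a strong correlation (r2 = 0.7)
#' between the first two traits as observed between canopy height and
#' foliage height diversity, weaker correlations (~0.3) elsewhere, a mild
#' cross-scene gradient, and a handful of disturbance patches 30-90 m in
#' radius with offset traits (juvenile regrowth).
#'
#' @param nrow,ncol grid size in pixels.
#' @param pixel_size pixel edge in metres.
#' @param range_m autocorrelation length (Gaussian kernel sd) per trait, m.
#' @param nugget fraction of each trait's variance that is spatially
#'   unstructured (pixel-scale crown and sensor variability). Without a
#'   nugget, nearby pixels are also each other's nearest trait-space
#'   neighbours, which makes the observed arrangement itself maximally
#'   under-dispersed -- unrealistically smooth for measured trait maps.
#' @param mean,sd pre-normalization trait means and sds.
#' @param correlation 3x3 positive semi-definite trait correlation matrix.
#' @param gradient per-trait change per metre along the row axis.
#' @param n_patches number of circular disturbance patches.
#' @param patch_radius_m length-2 range of patch radii, metres.
#' @param patch_offset per-trait additive offset inside patches (in sd
#'   units).
#' @param border_px non-forest border width in pixels.
#' @param seed integer seed.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(nrow = 200, ncol = 200, pixel_size = 6,
                           range_m = c(60, 60, 60),
                           nugget = 0.1,
                           mean = c(20, 1.5, 4),
                           sd = c(6, 0.5, 1.2),
                           correlation = rbind(c(1, sqrt(0.7), sqrt(0.3)),
                                               c(sqrt(0.7), 1, sqrt(0.3)),
                                               c(sqrt(0.3), sqrt(0.3), 1)),
                           gradient = c(-0.004, -0.0002, -0.0005),
                           n_patches = 4,
                           patch_radius_m = c(30, 90),
                           patch_offset = c(-1.5, -1, 0.8),
                           border_px = 4,
                           seed = 1) {
  stopifnot(nrow > 0, ncol > 0, pixel_size > 0,
            length(range_m) == 3, length(mean) == 3, length(sd) == 3,
            nugget >= 0, nugget <= 1,
            all(dim(correlation) == c(3, 3)))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, range_m = range_m,
                 nugget = nugget, mean = mean,
                 sd = sd, correlation = correlation, gradient = gradient,
                 n_patches = n_patches, patch_radius_m = patch_radius_m,
                 patch_offset = patch_offset, border_px = border_px,
                 seed = seed),
            class = "landscape_spec")
}

# unit-variance Gaussian random field: white noise convolved with a
# Gaussian kernel of sd `range_px` pixels, via FFT on a padded grid
gaussian_random_field <- function(nrow, ncol, range_px) {
  if (range_px <= 0) return(matrix(rnorm(nrow * ncol), nrow, ncol))
  pad <- ceiling(3 * range_px)
  nr <- nrow + 2 * pad; nc <- ncol + 2 * pad
  noise <- matrix(rnorm(nr * nc), nr, nc)
  kr <- stats::dnorm(c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)), sd = range_px)
  kc <- stats::dnorm(c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)), sd = range_px)
  ker <- outer(kr, kc)
  sm <- Re(fft(fft(noise) * fft(ker), inverse = TRUE)) / (nr * nc)
  sm <- sm[pad + seq_len(nrow), pad + seq_len(ncol)]
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic normalized trait stack
#'
#' Builds three correlated Gaussian random fields (white noise convolved
#' with a Gaussian kernel, mixed by the Cholesky factor of the requested
#' correlation matrix), adds the linear gradient and patch offsets, records
#' the raw fields as ground truth, then min-max normalizes each trait over
#' forest pixels and assembles a [trait_stack] with a non-forest border.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [landscape_spec].
#' @param trait_names names for the three layers (default CH, FHD, PAI).
#' @return A [trait_stack]; attribute `ground_truth` holds the
#'   pre-normalization fields and patch geometry.
#' @export
generate_trait_stack <- function(spec,
                                 trait_names = c("CH", "FHD", "PAI")) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$nrow; nc <- spec$ncol; ps <- spec$pixel_size
    fields <- lapply(spec$range_m / ps, function(rp) {
      f <- gaussian_random_field(nr, nc, rp)
      if (spec$nugget > 0)
        f <- sqrt(1 - spec$nugget) * f +
          sqrt(spec$nugget) * matrix(rnorm(nr * nc), nr, nc)
      f
    })
    # cross-trait correlation by Cholesky mixing of the standard fields
    L <- t(chol(spec$correlation))
    Z <- cbind(as.vector(fields[[1]]), as.vector(fields[[2]]),
               as.vector(fields[[3]]))
    X <- Z %*% t(L)
    rows_m <- (seq_len(nr) - 0.5) * ps
    patches <- if (spec$n_patches > 0) {
      data.frame(row = runif(spec$n_patches, 1, nr),
                 col = runif(spec$n_patches, 1, nc),
                 radius_m = runif(spec$n_patches, spec$patch_radius_m[1],
                                  spec$patch_radius_m[2]))
    } else data.frame(row = numeric(0), col = numeric(0),
                      radius_m = numeric(0))
    raw <- vector("list", 3)
    for (k in 1:3) {
      f <- matrix(X[, k], nr, nc)
      f <- spec$mean[k] + spec$sd[k] * f +
        spec$gradient[k] * matrix(rows_m, nr, nc)
      for (p in seq_len(nrow(patches))) {
        dr <- (row(f) - patches$row[p]) * ps
        dc <- (col(f) - patches$col[p]) * ps
        inside <- dr^2 + dc^2 <= patches$radius_m[p]^2
        f[inside] <- f[inside] + spec$patch_offset[k] * spec$sd[k]
      }
      raw[[k]] <- f
    }
    mask <- matrix(TRUE, nr, nc)
    b <- spec$border_px
    if (b > 0) {
      mask[c(seq_len(b), nr - seq_len(b) + 1L), ] <- FALSE
      mask[, c(seq_len(b), nc - seq_len(b) + 1L)] <- FALSE
    }
    traits <- lapply(1:3, function(k)
      normalize_trait(trait_raster(raw[[k]], trait_names[k], ps),
                      mask = mask))
    st <- trait_stack(traits, forest_mask = mask)
    attr(st, "ground_truth") <- list(raw = raw, patches = patches,
                                     spec = spec)
    st
  })
}

#' Forward-model a toy reflectance cube from trait fields
#'
#' Builds a reflectance cube whose band values respond monotonically to
#' three generating trait fields (chlorophyll, carotenoid, water), so the
#' spectral indices recover the fields rank-for-rank. The NIR plateau
#' (760-800 nm) is held constant; reflectance in each index's absorption
#' window decreases with the generating trait:
#' green 540-560 nm responds to CHL, blue-green 510-520 nm to CAR (with a
#' fixed red-edge 690-710 nm reference), and the 1193 nm water band dips
#' below the 1126 nm reference in proportion to EWT.
#'
#' @param chl,car,ewt numeric matrices in `[0, 1]` (identical grids).
#' @param pixel_size metres.
#' @param r_nir NIR plateau reflectance (default 0.5).
#' @param strength index value at trait = 1 (controls absorption depth).
#' @return A [reflectance_cube] with 14 bands covering all index windows.
#' @export
generate_reflectance_cube <- function(chl, car, ewt, pixel_size = 6,
                                      r_nir = 0.5, strength = 4) {
  stopifnot(all(dim(chl) == dim(car)), all(dim(chl) == dim(ewt)))
  rng <- range(c(chl, car, ewt), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("trait fields must lie in [0, 1]")
  wl <- c(510, 515, 520, 545, 550, 555, 690, 700, 710,
          760, 780, 800, 1126, 1193)
  d <- dim(chl)
  cube <- array(NA_real_, c(length(wl), d[1], d[2]))
  r_rededge <- 0.25
  # invert the three-band form: index = (1/R_win - 1/R_ref) * R_nir
  r_green <- 1 / (strength * chl / r_nir + 1 / r_nir)
  r_bluegreen <- 1 / (strength * car / r_nir + 1 / r_rededge)
  r_1126 <- 0.45
  r_1193 <- r_1126 * (1 - 0.8 * ewt)
  for (i in 1:3) cube[i, , ] <- r_bluegreen
  for (i in 4:6) cube[i, , ] <- r_green
  for (i in 7:9) cube[i, , ] <- r_rededge
  for (i in 10:12) cube[i, , ] <- r_nir
  cube[13, , ] <- r_1126
  cube[14, , ] <- r_1193
  reflectance_cube(cube, wl, pixel_size)
}

#' Generate a synthetic canopy height model
#'
#' Rescales a random field to canopy heights (default 12-55 m, the range of
#' a mature temperate forest), then optionally inserts clearings (height
#' below the tree threshold), an enclosed low gap (for testing gap
#' filling), and a zero-height border.
#'
#' @param spec a [landscape_spec] (grid, autocorrelation and seed reused).
#' @param height_range length-2 metres for the forest interior.
#' @param n_clearings circular clearings at < 1 m height.
#' @param gap optional length-3 `c(row, col, radius_px)` low (6 m) gap.
#' @param border_px zero-height border width.
#' @return A [canopy_height_model].
#' @export
generate_chm <- function(spec, height_range = c(12, 55), n_clearings = 2,
                         gap = NULL, border_px = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (is.null(border_px)) border_px <- spec$border_px
  with_local_seed(spec$seed + 1L, {
    nr <- spec$nrow; nc <- spec$ncol
    f <- gaussian_random_field(nr, nc, spec$range_m[1] / spec$pixel_size)
    f <- (f - min(f)) / (max(f) - min(f))
    h <- height_range[1] + f * diff(height_range)
    for (k in seq_len(n_clearings)) {
      cr <- runif(1, nr * 0.2, nr * 0.8)
      cc <- runif(1, nc * 0.2, nc * 0.8)
      rad <- runif(1, 3, 8)
      inside <- (row(h) - cr)^2 + (col(h) - cc)^2 <= rad^2
      h[inside] <- runif(sum(inside), 0, 0.8)
    }
    if (!is.null(gap)) {
      inside <- (row(h) - gap[1])^2 + (col(h) - gap[2])^2 <= gap[3]^2
      h[inside] <- 6
    }
    if (border_px > 0) {
      h[c(seq_len(border_px), nr - seq_len(border_px) + 1L), ] <- 0
      h[, c(seq_len(border_px), nc - seq_len(border_px) + 1L)] <- 0
    }
    canopy_height_model(h, spec$pixel_size)
  })
}

#' Generate synthetic vertical plant-area profiles
#'
#' Per-pixel layer proportions drawn from a symmetric Dirichlet whose
#' concentration varies across pixels, so the foliage height diversity of
#' the result has a known rank order: high concentration gives uniform
#' layering (FHD near `log(n_layers)`), low concentration a single dominant
#' layer (FHD near 0).
#'
#' @param spec a [landscape_spec].
#' @param n_layers number of vertical bins (>= 1).
#' @param concentration_range length-2 range of the Dirichlet concentration
#'   across the scene (mapped from a smooth random field).
#' @param layer_thickness metres per bin.
#' @return A [vertical_profile_stack]; attribute `concentration` holds the
#'   per-pixel ground-truth concentration field.
#' @export
generate_profile_stack <- function(spec, n_layers = 8,
                                   concentration_range = c(0.2, 20),
                                   layer_thickness = 5) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  with_local_seed(spec$seed + 2L, {
    nr <- spec$nrow; nc <- spec$ncol
    f <- gaussian_random_field(nr, nc, spec$range_m[1] / spec$pixel_size)
    f <- (f - min(f)) / (max(f) - min(f))
    conc <- exp(log(concentration_range[1]) +
                  f * diff(log(concentration_range)))
    a <- array(NA_real_, c(n_layers, nr, nc))
    g <- matrix(rgamma(n_layers * nr * nc, shape = rep(as.vector(conc),
                                                       each = n_layers)),
                n_layers)
    tot <- colSums(g)
    tot[tot == 0] <- 1
    a[] <- sweep(g, 2, tot, "/")
    ps <- vertical_profile_stack(a, layer_thickness, spec$pixel_size)
    attr(ps, "concentration") <- conc
    ps
  })
}
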