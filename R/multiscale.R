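#' Radius schedule for multi-scale analysis
#'
#' The sequence of circular window radii over which diversity-area curves
#' are computed. The defaults reproduce the working schedule of 6-1020 m in
#' 6 m steps: 170 extents spanning areas from 113 m2 to 3.27e6 m2.
#'
#' @param r_min,r_max first and last radius in metres.
#' @param step increment in metres.
#' @return A data.frame of class `radius_schedule` with columns `radius_m`
#'   and `area_m2` (`pi * r^2`).
#' @export
radius_schedule <- function(r_min = 6, r_max = 1020, step = 6) {
  if (!(r_min > 0 && r_min <= r_max && step > 0))
    stop("need 0 < r_min <= r_max and step > 0")
  radii <- seq(r_min, r_max, by = step)
  out <- data.frame(radius_m = radii, area_m2 = pi * radii^2)
  class(out) <- c("radius_schedule", "data.frame")
  out
}

# (drow, dcol) integer offsets of pixel centres within Euclidean distance
# <= radius of the focal centre (closed disc, distances in map metres);
# max_px caps the offset range at the raster extent so oversized radii
# ("whole scene") stay affordable
disc_offsets <- function(radius, pixel_size, max_px = Inf) {
  m <- min(floor(radius / pixel_size), max_px)
  d <- expand.grid(dr = -m:m, dc = -m:m)
  keep <- (d$dr^2 + d$dc^2) * pixel_size^2 <= radius^2 + 1e-9
  as.matrix(d[keep, , drop = FALSE])
}

#' Extract the trait triplets of one circular neighbourhood
#'
#' All forest-masked pixels whose centre lies within Euclidean distance
#' `radius` of the focal pixel centre (closed disc), the focal included if
#' masked. A non-forest focal yields whatever masked pixels fall in its
#' disc, possibly an empty sample.
#'
#' @param stack a [trait_stack].
#' @param focal length-2 integer `c(row, col)`.
#' @param radius window radius in metres.
#' @return A [neighborhood_sample], or an empty 0-row matrix if no masked
#'   pixel falls in the disc.
#' @export
extract_neighborhood <- function(stack, focal, radius) {
  stopifnot(inherits(stack, "trait_stack"), length(focal) == 2L)
  d <- dim(stack$mask)
  if (focal[1] < 1 || focal[1] > d[1] || focal[2] < 1 || focal[2] > d[2])
    stop("focal pixel outside the grid")
  off <- disc_offsets(radius, stack$pixel_size, max_px = max(d) - 1L)
  rr <- focal[1] + off[, 1]
  cc <- focal[2] + off[, 2]
  keep <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  rr <- rr[keep]; cc <- cc[keep]
  idx <- cbind(rr, cc)
  masked <- stack$mask[idx]
  idx <- idx[masked, , drop = FALSE]
  pts <- cbind(stack$traits[[1]]$values[idx],
               stack$traits[[2]]$values[idx],
               stack$traits[[3]]$values[idx])
  colnames(pts) <- stack$trait_names
  if (!nrow(pts)) return(pts)
  neighborhood_sample(pts, focal_id = focal)
}

index_code <- function(index_name) {
  switch(match.arg(index_name, c("richness", "divergence", "evenness")),
         richness = 1L, divergence = 2L, evenness = 3L)
}

#' Moving-window diversity map at one radius
#'
#' Computes one diversity index for every forest pixel from its circular
#' neighbourhood sample. The window never crosses the forest mask:
#' non-forest pixels are simply absent from the samples. Pixels whose index
#' is undefined (e.g. evenness with S < 3, or richness with fewer than
#' `min_points` pixels) are nodata.
#'
#' @param stack a normalized [trait_stack].
#' @param index_name `"richness"`, `"divergence"` or `"evenness"`.
#' @param radius window radius in metres.
#' @param min_points minimum sample size for richness (default 4, the
#'   smallest S that can enclose volume); ignored by the other indices.
#' @return An object of class `diversity_map`: list with `values` (matrix,
#'   `NA` = nodata), `index_name`, `radius`, `pixel_size`.
#' @export
diversity_map <- function(stack, index_name, radius, min_points = 4) {
  stopifnot(inherits(stack, "trait_stack"))
  code <- index_code(index_name)
  off <- disc_offsets(radius, stack$pixel_size,
                      max_px = max(dim(stack$mask)) - 1L)
  vals <- cpp_diversity_map(stack$traits[[1]]$values,
                            stack$traits[[2]]$values,
                            stack$traits[[3]]$values,
                            stack$mask, off, code, as.integer(min_points))
  structure(list(values = vals,
                 index_name = c("richness", "divergence", "evenness")[code],
                 radius = radius, pixel_size = stack$pixel_size),
            class = "diversity_map")
}

#' @export
print.diversity_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<diversity_map> %s @ r = %g m: %d x %d px, %d valid, mean %.4f\n",
    x$index_name, x$radius, nrow(x$values), ncol(x$values), length(v),
    if (length(v)) mean(v) else NA_real_))
  invisible(x)
}

# focal pixels on a regular grid with spacing 2r whose full disc lies
# inside the forest mask (non-overlapping circles fully within forest)
grid_focals <- function(stack, radius) {
  ps <- stack$pixel_size
  spacing <- max(1L, ceiling(2 * radius / ps))
  d <- dim(stack$mask)
  rows <- seq(1L + spacing %/% 2L, d[1], by = spacing)
  cols <- seq(1L + spacing %/% 2L, d[2], by = spacing)
  off <- disc_offsets(radius, ps)
  keep <- list()
  for (r in rows) for (c in cols) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    if (any(rr < 1 | rr > d[1] | cc < 1 | cc > d[2])) next
    if (all(stack$mask[cbind(rr, cc)])) keep[[length(keep) + 1L]] <- c(r, c)
  }
  if (!length(keep)) matrix(integer(0), 0, 2) else do.call(rbind, keep)
}

#' Diversity-area curve across a radius schedule
#'
#' For each radius of the schedule, computes the index map and summarises
#' it as the mean and standard deviation over forested pixels. With
#' `sampling = "grid"` the index is instead evaluated at focal pixels on a
#' regular grid chosen so the circular neighbourhoods do not overlap and
#' lie fully inside the forest (the sampling used for plot-like
#' statistics).
#'
#' @param stack a normalized [trait_stack].
#' @param index_name `"richness"`, `"divergence"` or `"evenness"`.
#' @param schedule a [radius_schedule].
#' @param sampling `"all"` (every masked pixel) or `"grid"`.
#' @param min_points see [diversity_map()].
#' @return A data.frame of class `diversity_area_curve` with columns
#'   `radius_m`, `area_m2`, `mean`, `sd`, `n` plus attribute `index_name`.
#' @export
diversity_area_curve <- function(stack, index_name, schedule,
                                 sampling = c("all", "grid"),
                                 min_points = 4) {
  stopifnot(inherits(stack, "trait_stack"),
            inherits(schedule, "radius_schedule"))
  sampling <- match.arg(sampling)
  if (!any(stack$mask)) stop("no forested pixel in the stack")
  code <- index_code(index_name)
  fn <- list(functional_richness, functional_divergence,
             functional_evenness)[[code]]
  res <- lapply(seq_len(nrow(schedule)), function(i) {
    r <- schedule$radius_m[i]
    if (sampling == "all") {
      m <- diversity_map(stack, index_name, r, min_points = min_points)
      v <- m$values[!is.na(m$values)]
    } else {
      focals <- grid_focals(stack, r)
      v <- apply(focals, 1, function(f) {
        s <- extract_neighborhood(stack, f, r)
        if (!nrow(s)) return(NA_real_)
        if (code == 1L && nrow(s) < min_points) return(NA_real_)
        suppressWarnings(fn(s))
      })
      v <- v[!is.na(v)]
    }
    data.frame(radius_m = r, area_m2 = schedule$area_m2[i],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, res)
  attr(out, "index_name") <- c("richness", "divergence", "evenness")[code]
  class(out) <- c("diversity_area_curve", "data.frame")
  out
}

# coefficient of determination without summary.lm (which warns on
# numerically perfect fits)
rsq <- function(fit) {
  y <- fit$model[[1]]
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(1)
  max(0, min(1, 1 - sum(fit$residuals^2) / tss))
}

fit_validate <- function(curve, min_area, positive_only) {
  stopifnot(is.data.frame(curve),
            all(c("area_m2", "mean") %in% names(curve)))
  use <- is.finite(curve$mean) & curve$area_m2 >= min_area
  if (positive_only) {
    drop <- use & curve$mean <= 0
    if (any(drop)) {
      warning(sum(drop), " non-positive mean value(s) excluded from the fit")
      use <- use & curve$mean > 0
    }
  }
  if (sum(use) < 3L) stop("need at least 3 usable points to fit")
  use
}

#' Power-law fit to a diversity-area curve
#'
#' Fits \eqn{V = c \cdot A^z} by ordinary least squares of
#' \eqn{\ln(\bar V)} on \eqn{\ln A}, the classical log-log form of
#' richness-area relationships. Non-positive means are excluded with a
#' warning.
#'
#' @param curve a [diversity_area_curve] (or any data.frame with `area_m2`
#'   and `mean`).
#' @param min_area restrict the fit to areas >= this value in m2
#'   (default 0 = full schedule).
#' @return A list of class `scaling_fit`: `model = "power"`, `c`, `z`,
#'   `r2`, `n`, `domain`.
#' @export
fit_power_law <- function(curve, min_area = 0) {
  use <- fit_validate(curve, min_area, positive_only = TRUE)
  fit <- lm(log(mean) ~ log(area_m2), data = curve[use, ])
  co <- coef(fit)
  structure(list(model = "power", c = unname(exp(co[1])), z = unname(co[2]),
                 r2 = rsq(fit), n = sum(use),
                 domain = range(curve$area_m2[use]), fit = fit),
            class = "scaling_fit")
}

#' Logarithmic fit to a diversity-area curve
#'
#' Fits \eqn{V = a + b \ln A} by ordinary least squares, the form that
#' tracks richness-area curves which flatten on the log-log scale at large
#' areas.
#'
#' @inheritParams fit_power_law
#' @return A list of class `scaling_fit`: `model = "logarithmic"`, `a`,
#'   `b`, `r2`, `n`, `domain`.
#' @export
fit_logarithmic <- function(curve, min_area = 0) {
  use <- fit_validate(curve, min_area, positive_only = FALSE)
  fit <- lm(mean ~ log(area_m2), data = curve[use, ])
  co <- coef(fit)
  structure(list(model = "logarithmic", a = unname(co[1]), b = unname(co[2]),
                 r2 = rsq(fit), n = sum(use),
                 domain = range(curve$area_m2[use]), fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  if (x$model == "power") {
    cat(sprintf("<scaling_fit> V = %.4g * A^%.4g  (r2 = %.4f, n = %d)\n",
                x$c, x$z, x$r2, x$n))
  } else {
    cat(sprintf("<scaling_fit> V = %.4g + %.4g ln A  (r2 = %.4f, n = %d)\n",
                x$a, x$b, x$r2, x$n))
  }
  invisible(x)
}

#' Circular averaging filter on a diversity map
#'
#' Replaces each valid pixel by the mean of valid pixels within the
#' circular kernel (nodata neighbours are ignored; nodata pixels stay
#' nodata). Used for display smoothing of the per-pixel maps. A kernel
#' radius smaller than the pixel size is the identity.
#'
#' @param map a [diversity_map].
#' @param radius kernel radius in metres.
#' @return A smoothed [diversity_map].
#' @export
circular_smooth <- function(map, radius) {
  stopifnot(inherits(map, "diversity_map"))
  off <- disc_offsets(radius, map$pixel_size)
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  vz <- ifelse(is.na(v), 0, v)
  ok <- !is.na(v)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    acc[r1, c1] <- acc[r1, c1] + vz[r1 + dr, c1 + dc]
    cnt[r1, c1] <- cnt[r1, c1] + ok[r1 + dr, c1 + dc]
  }
  out <- ifelse(cnt > 0 & ok, acc / pmax(cnt, 1), NA_real_)
  structure(list(values = out, index_name = map$index_name,
                 radius = map$radius, pixel_size = map$pixel_size),
            class = "diversity_map")
}
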