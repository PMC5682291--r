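# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards; seed = NULL leaves the RNG alone
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random-shuffle null model
#'
#' Reshuffles the forest pixels' trait triplets uniformly at random over the
#' masked pixel positions. The relationship among the three traits of a
#' pixel is preserved (triplets are never split across traits) and only
#' masked positions take part, so the scene-wide trait histograms and
#' inter-trait correlations are exactly unchanged while all spatial
#' autocorrelation is destroyed. Deterministic given `seed`.
#'
#' @param stack a [trait_stack] with at least 2 masked pixels.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [trait_stack] with permuted trait layers and the same mask.
#' @export
shuffle_null <- function(stack, seed = NULL) {
  stopifnot(inherits(stack, "trait_stack"))
  idx <- which(stack$mask)
  if (length(idx) < 2L) stop("need at least 2 masked pixels to shuffle")
  perm <- with_local_seed(seed, sample(length(idx)))
  traits <- lapply(stack$traits, function(t) {
    v <- t$values
    v[idx] <- v[idx][perm]
    trait_raster(v, t$trait_name, t$pixel_size, normalized = t$normalized)
  })
  trait_stack(traits, forest_mask = stack$mask)
}

#' Maximal under-dispersion sample for one focal pixel
#'
#' The reference sample for maximal environmental filtering: instead of the
#' N pixels geographically nearest to the focal pixel, the N masked pixels
#' nearest to it in trait space (Euclidean distance on the normalized
#' triplet) are selected, with N the size of the geographic neighbourhood
#' at the same (focal, radius). The focal itself (distance 0) is always
#' included. Ties in trait distance are broken towards the smaller flat
#' pixel index (column-major), making the sample deterministic.
#'
#' @param stack a [trait_stack].
#' @param focal length-2 integer `c(row, col)`; must be masked.
#' @param radius window radius in metres defining N.
#' @return A [neighborhood_sample] of the same size as the geographic one.
#' @export
underdispersion_sample <- function(stack, focal, radius) {
  stopifnot(inherits(stack, "trait_stack"), length(focal) == 2L)
  if (!stack$mask[focal[1], focal[2]])
    stop("focal pixel is not forest-masked")
  geo <- extract_neighborhood(stack, focal, radius)
  n <- nrow(geo)
  pts <- stack_points(stack)
  f <- c(stack$traits[[1]]$values[focal[1], focal[2]],
         stack$traits[[2]]$values[focal[1], focal[2]],
         stack$traits[[3]]$values[focal[1], focal[2]])
  d2 <- (pts[, 1] - f[1])^2 + (pts[, 2] - f[2])^2 + (pts[, 3] - f[3])^2
  ord <- order(d2, attr(pts, "pixel_index"))[seq_len(n)]
  neighborhood_sample(pts[ord, , drop = FALSE], focal_id = focal)
}

#' Null-model diversity-area curve
#'
#' Reference curves against which the observed diversity-area relationship
#' is compared. For `model = "shuffle"` the stack is reshuffled
#' `n_replicates` times (replicate k uses sub-seed `seed + k`, so any
#' replicate is reproducible in isolation); the returned `mean` is the
#' across-replicate mean of the per-replicate curve means and `sd` their
#' across-replicate standard deviation. For `model = "underdispersion"` the
#' model is deterministic and computed once: at each radius, every sampled
#' focal pixel's geographic sample is replaced by its trait-space
#' nearest-neighbour sample of the same size.
#'
#' @param stack a normalized [trait_stack].
#' @param index_name `"richness"`, `"divergence"` or `"evenness"`.
#' @param schedule a [radius_schedule].
#' @param model `"shuffle"` or `"underdispersion"`.
#' @param n_replicates shuffle replicates (default 50).
#' @param seed master seed for the shuffle model.
#' @param sampling passed to [diversity_area_curve()]; for the
#'   under-dispersion model, `"grid"` keeps the trait-space
#'   nearest-neighbour search affordable.
#' @param min_points see [diversity_map()].
#' @return A `diversity_area_curve` data.frame; for shuffle, attribute
#'   `replicates` holds the per-replicate mean matrix.
#' @export
null_curve <- function(stack, index_name, schedule,
                       model = c("shuffle", "underdispersion"),
                       n_replicates = 50, seed = 1,
                       sampling = c("all", "grid"), min_points = 4) {
  stopifnot(inherits(stack, "trait_stack"),
            inherits(schedule, "radius_schedule"))
  model <- match.arg(model)
  sampling <- match.arg(sampling)
  code <- index_code(index_name)
  if (model == "shuffle") {
    stopifnot(n_replicates >= 1)
    reps <- vapply(seq_len(n_replicates), function(k) {
      sh <- shuffle_null(stack, seed = seed + k)
      diversity_area_curve(sh, index_name, schedule, sampling = sampling,
                           min_points = min_points)$mean
    }, numeric(nrow(schedule)))
    reps <- matrix(reps, nrow = nrow(schedule))
    out <- data.frame(radius_m = schedule$radius_m,
                      area_m2 = schedule$area_m2,
                      mean = rowMeans(reps),
                      sd = apply(reps, 1, sd),
                      n = n_replicates)
    attr(out, "replicates") <- reps
  } else {
    fn <- list(functional_richness, functional_divergence,
               functional_evenness)[[code]]
    rows <- lapply(seq_len(nrow(schedule)), function(i) {
      r <- schedule$radius_m[i]
      focals <- if (sampling == "grid") grid_focals(stack, r) else
        which(stack$mask, arr.ind = TRUE)
      v <- apply(focals, 1, function(f) {
        s <- underdispersion_sample(stack, f, r)
        if (code == 1L && nrow(s) < min_points) return(NA_real_)
        suppressWarnings(fn(s))
      })
      v <- v[!is.na(v)]
      data.frame(radius_m = r, area_m2 = schedule$area_m2[i],
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 n = length(v))
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "index_name") <- c("richness", "divergence", "evenness")[code]
  attr(out, "model") <- model
  class(out) <- c("diversity_area_curve", "data.frame")
  out
}

#' Moran's I spatial autocorrelation of a raster layer
#'
#' Global Moran's I with binary queen (8-neighbour) weights, restricted to
#' pixel pairs where both members are valid. A diagnostic for the shuffle
#' null model: reshuffling drives Moran's I of every trait to about zero.
#'
#' @param values numeric matrix (`NA` = excluded).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values) {
  stopifnot(is.matrix(values))
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) return(NA_real_)
  z <- values - mean(values[ok])
  z[!ok] <- 0
  nr <- nrow(values); nc <- ncol(values)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  num <- 0; W <- 0
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    pair_ok <- ok[r1, c1] & ok[r1 + dr, c1 + dc]
    num <- num + sum(z[r1, c1] * z[r1 + dr, c1 + dc] * pair_ok)
    W <- W + sum(pair_ok)
  }
  (n / W) * num / sum(z[ok]^2)
}
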