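#' Trait triplets of one circular neighbourhood
#'
#' Validates and wraps a set of points in normalized three-trait space, the
#' unit on which all three diversity indices operate. Every coordinate must
#' lie in `[0, 1]` (the normalization contract) and no point may contain
#' nodata.
#'
#' @param points numeric matrix with 3 columns (one row per pixel).
#' @param focal_id optional reference to the focal pixel (any scalar).
#' @return The validated points matrix, class `neighborhood_sample`, with
#'   attributes `S` (point count) and `focal_id`.
#' @export
neighborhood_sample <- function(points, focal_id = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("need 3 trait columns")
  if (nrow(points) < 1L) stop("need at least one point")
  if (anyNA(points)) stop("sample contains nodata points")
  if (min(points) < -1e-9 || max(points) > 1 + 1e-9)
    stop("trait coordinates outside [0, 1]: normalization contract broken")
  structure(points, class = c("neighborhood_sample", class(points)),
            S = nrow(points), focal_id = focal_id)
}

as_points <- function(sample) {
  if (inherits(sample, "neighborhood_sample")) {
    unclass(sample)
  } else {
    neighborhood_sample(sample)  # validate plain matrices too
  }
}

#' Functional richness: convex hull volume in trait space
#'
#' The volume of the 3D convex hull of the sample's trait triplets. Since
#' traits are normalized to the unit cube the value lies in `[0, 1]`: 1
#' means the community niche fills the entire possible trait space.
#' Degenerate samples (fewer than 4 points, or collinear/coplanar
#' configurations) have zero volume; these are returned as 0 with attribute
#' `degenerate = TRUE`, treating flat neighbourhoods as genuine zero-volume
#' niches rather than missing data.
#'
#' @param sample a [neighborhood_sample] or 3-column matrix in `[0, 1]`.
#' @param degenerate_as_na if `TRUE`, return `NA` instead of 0 for
#'   degenerate samples.
#' @return Hull volume in `[0, 1]`.
#' @export
functional_richness <- function(sample, degenerate_as_na = FALSE) {
  pts <- as_points(sample)
  v <- cpp_hull_volume(pts)
  if (v <= 0) {
    v <- if (degenerate_as_na) NA_real_ else 0
    attr(v, "degenerate") <- TRUE
  }
  v
}

#' Functional divergence: spread relative to the centre of gravity
#'
#' With \eqn{dG_i} the Euclidean distance of point \eqn{i} to the centre of
#' gravity of the sample, \eqn{\bar{dG}} their mean and
#' \eqn{\Delta|d| = \sum_i |dG_i - \bar{dG}| / S} the mean absolute
#' deviation:
#' \deqn{FDiv = \bar{dG} / (\Delta|d| + \bar{dG})}
#' All points are weighted equally (each pixel is one trait measurement; no
#' abundance weighting). FDiv = 1 iff all points are equidistant from the
#' centre (e.g. on a sphere). Undefined (returned as `NA`) when all points
#' coincide.
#'
#' @inheritParams functional_richness
#' @return FDiv in `[0, 1]`, or `NA`.
#' @export
functional_divergence <- function(sample) {
  pts <- as_points(sample)
  if (nrow(pts) < 2L) return(NA_real_)
  cpp_fdiv(pts)
}

#' Functional evenness: regularity of spacing along the spanning tree
#'
#' Builds the Euclidean minimum spanning tree of the sample (Prim's
#' algorithm) and measures how evenly its branch lengths are distributed:
#' with \eqn{PEW_l = EW_l / \sum EW} the partial weighted evenness of branch
#' \eqn{l},
#' \deqn{FEve = \frac{\sum_l \min(PEW_l, 1/(S-1)) - 1/(S-1)}{1 - 1/(S-1)}}
#' FEve = 1 when all branches are equally long (perfectly regular spacing).
#' Undefined for S < 3 (the denominator vanishes at S = 2) and when all
#' points coincide; both return `NA`.
#'
#' @inheritParams functional_richness
#' @return FEve in `[0, 1]`, or `NA`.
#' @export
functional_evenness <- function(sample) {
  pts <- as_points(sample)
  if (nrow(pts) < 3L) {
    warning("functional evenness undefined for fewer than 3 points")
    return(NA_real_)
  }
  cpp_feve(pts)
}

#' Euclidean minimum spanning tree of a point set
#'
#' Prim's algorithm on the dense Euclidean distance matrix. Ties between
#' equal-length candidate edges are broken towards the lexicographically
#' smaller (origin index, destination index) pair, making the tree
#' bit-reproducible. Duplicated points yield zero-length edges; the tree
#' still spans all S points with S - 1 edges.
#'
#' @param points numeric matrix with 3 columns (finite coordinates; this
#'   operation does not require the unit-cube contract).
#' @return A data.frame with columns `from`, `to` (1-based point indices)
#'   and `length`; `S - 1` rows.
#' @export
minimum_spanning_tree <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L, all(is.finite(points)))
  m <- cpp_mst(points)
  data.frame(from = m$from + 1L, to = m$to + 1L, length = m$length)
}

#' Centre-of-gravity geometry of a sample
#'
#' The intermediate quantities of the divergence index, useful for
#' inspection and testing: the centre of gravity, per-point distances, their
#' mean and the mean absolute deviation.
#'
#' @inheritParams functional_richness
#' @return List with `centre`, `distances`, `mean_distance`,
#'   `mean_abs_deviation`.
#' @export
divergence_geometry <- function(sample) {
  pts <- as_points(sample)
  centre <- colMeans(pts)
  d <- sqrt(rowSums((pts - rep(centre, each = nrow(pts)))^2))
  list(centre = centre, distances = d, mean_distance = mean(d),
       mean_abs_deviation = mean(abs(d - mean(d))))
}
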