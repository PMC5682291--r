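# Independent oracles, deliberately implemented with different algorithms
# than the package (which uses an incremental hull and Prim's MST in C++).

# Brute-force 3D hull facets: every triple of points whose plane has all
# other points on one side. O(n^4); intended for small point sets in
# general position (continuous random coordinates).
brute_hull_facets <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  triples <- t(combn(n, 3))
  facets <- list()
  for (k in seq_len(nrow(triples))) {
    i <- triples[k, ]
    a <- pts[i[1], ]; b <- pts[i[2], ]; cc <- pts[i[3], ]
    nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
             (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
             (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    if (sum(abs(nrm)) < 1e-12) next
    s <- (pts %*% nrm) - sum(nrm * a)
    if (all(s <= 1e-10) || all(s >= -1e-10))
      facets[[length(facets) + 1L]] <- list(n = nrm, a = a, idx = i)
  }
  facets
}

# Exact hull volume from brute-force facets: cone decomposition around the
# point-set centroid (inside the hull by convexity).
brute_hull_volume <- function(pts) {
  facets <- brute_hull_facets(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (f in facets) {
    a <- pts[f$idx[1], ] - ctr
    b <- pts[f$idx[2], ] - ctr
    cc <- pts[f$idx[3], ] - ctr
    vol <- vol + abs(a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                       a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                       a[3] * (b[1] * cc[2] - b[2] * cc[1]))
  }
  vol / 6
}

# Monte-Carlo rejection oracle: fraction of uniform draws in the unit cube
# that satisfy every supporting half-space of the brute-force facet set.
mc_hull_volume <- function(pts, n_draws = 1e5) {
  facets <- brute_hull_facets(pts)
  draws <- matrix(runif(3 * n_draws), ncol = 3)
  inside <- rep(TRUE, n_draws)
  ctr <- colMeans(pts)
  for (f in facets) {
    side <- sign(sum(f$n * ctr) - sum(f$n * f$a))
    s <- (draws %*% f$n) - sum(f$n * f$a)
    inside <- inside & (side * s >= -1e-10)
  }
  p <- mean(inside)
  list(volume = p, se = sqrt(p * (1 - p) / n_draws))
}

# Kruskal MST total length (sort + union-find), independent of Prim.
kruskal_mst_length <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[edges])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  tot <- 0; used <- 0L
  for (k in ord) {
    i <- edges[k, 1]; j <- edges[k, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      tot <- tot + d[i, j]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  tot
}

# Exhaustive minimum over all spanning trees via Prufer-sequence
# enumeration (n^(n-2) labelled trees).
prufer_min_spanning_length <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3, n <= 8)
  d <- as.matrix(dist(pts))
  m <- n - 2L
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    tot <- 0
    deg <- degree
    for (v in pr) {
      leaf <- which.min(ifelse(deg == 1L, seq_len(n), Inf))
      tot <- tot + d[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    rest <- which(deg == 1L)
    tot <- tot + d[rest[1], rest[2]]
    if (tot < best) best <- tot
  }
  best
}

# small helpers for building fixtures -------------------------------------

# trait stack straight from three matrices (already in [0, 1])
stack_from_matrices <- function(m1, m2, m3, pixel_size = 6, mask = NULL,
                                names = c("CH", "FHD", "PAI")) {
  traits <- Map(function(m, nm)
    trait_raster(m, nm, pixel_size, normalized = TRUE),
    list(m1, m2, m3), names)
  trait_stack(traits, forest_mask = mask)
}

# i.i.d. uniform trait landscape
uniform_stack <- function(nr, nc, pixel_size = 6, seed = 1, mask = NULL) {
  set.seed(seed)
  stack_from_matrices(matrix(runif(nr * nc), nr, nc),
                      matrix(runif(nr * nc), nr, nc),
                      matrix(runif(nr * nc), nr, nc),
                      pixel_size = pixel_size, mask = mask)
}

# flat-spectrum cube at constant reflectance
constant_cube <- function(value = 0.3, nr = 4, nc = 5,
                          wl = c(510, 515, 520, 545, 550, 555, 690, 700,
                                 710, 760, 780, 800, 1126, 1193)) {
  reflectance_cube(array(value, c(length(wl), nr, nc)), wl, pixel_size = 2)
}
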