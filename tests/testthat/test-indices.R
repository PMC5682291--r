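cube_corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
tetrahedron <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("richness is the hull volume: cube, tetrahedron, degenerate sets", {
  expect_equal(functional_richness(cube_corners), 1)
  expect_equal(functional_richness(tetrahedron), 1 / 6, tolerance = 1e-12)

  # 50 coplanar points enclose no volume
  set.seed(1)
  flat <- cbind(runif(50), runif(50), 0.4)
  v <- functional_richness(flat)
  expect_equal(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "degenerate")))
  expect_true(is.na(functional_richness(flat, degenerate_as_na = TRUE)))

  # collinear and tiny sets are degenerate too
  expect_equal(as.numeric(functional_richness(cbind(0:2, 0:2, 0:2) / 2)), 0)
  expect_equal(as.numeric(functional_richness(rbind(c(0.5, 0.5, 0.5)))), 0)
})

test_that("richness rejects coordinates outside the unit cube", {
  expect_error(functional_richness(rbind(c(0, 0, 1.2), c(0, 0, 0),
                                         c(1, 0, 0), c(0, 1, 0))),
               "normalization")
})

test_that("hull volume agrees with brute-force and Monte-Carlo oracles", {
  set.seed(101)
  for (n in c(10, 25, 60)) {
    pts <- matrix(runif(3 * n), ncol = 3)
    v <- functional_richness(pts)
    expect_equal(v, brute_hull_volume(pts), tolerance = 1e-9)
  }
  pts <- matrix(runif(3 * 200), ncol = 3)
  v <- functional_richness(pts)
  mc <- mc_hull_volume(pts, n_draws = 1e5)
  expect_lt(abs(v - mc$volume), 3 * mc$se)
})

test_that("divergence matches hand evaluations of the centre-of-gravity form",
{
  # any two distinct points: both equidistant from the midpoint
  expect_equal(functional_divergence(rbind(c(0, 0, 0), c(1, 1, 1))), 1)
  # cube corners are all equidistant from the centre
  expect_equal(functional_divergence(cube_corners), 1)
  # two pairs at distances 0.1 and 0.3 from their centre (ratio 1:3):
  # dbar = 0.2, mean |d - dbar| = 0.1, FDiv = 0.2 / (0.1 + 0.2) = 2/3
  pts2 <- rbind(c(0.4, 0.5, 0.5), c(0.6, 0.5, 0.5),
                c(0.2, 0.5, 0.5), c(0.8, 0.5, 0.5))
  g <- divergence_geometry(pts2)
  expect_equal(g$centre, c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_equal(sort(g$distances), c(0.1, 0.1, 0.3, 0.3))
  expect_equal(functional_divergence(pts2), 2 / 3, tolerance = 1e-12)
  # all points identical: undefined
  expect_true(is.na(functional_divergence(matrix(0.5, 4, 3))))
})

test_that("evenness matches hand evaluations of the MST branch form", {
  # equally spaced collinear points, any S >= 3
  for (S in c(3, 5, 9)) {
    pts <- cbind(seq(0, 1, length.out = S), 0.5, 0.5)
    expect_equal(functional_evenness(pts), 1, tolerance = 1e-12)
  }
  # gaps 1 and 3: sum(min(PEW, 1/2)) = 0.25 + 0.5, FEve = 0.5
  pts <- cbind(c(0, 0.25, 1), 0, 0)
  expect_equal(functional_evenness(pts), 0.5, tolerance = 1e-12)
  # equilateral triangle: two equal MST edges
  pts <- cbind(c(0, 0.5, 1), c(0, sqrt(3) / 2, 0), 0.5)
  expect_equal(functional_evenness(pts), 1, tolerance = 1e-12)
  # S = 2 undefined (denominator vanishes); identical points undefined
  expect_warning(v <- functional_evenness(rbind(c(0, 0, 0), c(1, 1, 1))),
                 "fewer than 3")
  expect_true(is.na(v))
  expect_true(is.na(functional_evenness(matrix(0.3, 5, 3))))
})

test_that("MST picks adjacent segments, spans duplicates, matches oracles", {
  # collinear points: the two short segments, never the long chord
  pts <- cbind(c(0, 0.3, 1), 0, 0)
  mst <- minimum_spanning_tree(pts)
  expect_equal(nrow(mst), 2)
  expect_equal(sort(mst$length), c(0.3, 0.7))

  # duplicated point: zero-length edge, still spanning
  pts <- rbind(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2), c(0.8, 0.1, 0.4))
  mst <- minimum_spanning_tree(pts)
  expect_equal(nrow(mst), 2)
  expect_equal(min(mst$length), 0)
  expect_setequal(c(mst$from, mst$to), 1:3)

  # exhaustive enumeration over all labelled spanning trees (small S)
  set.seed(2)
  for (S in c(4, 5, 6)) {
    pts <- matrix(runif(3 * S), ncol = 3)
    expect_equal(sum(minimum_spanning_tree(pts)$length),
                 prufer_min_spanning_length(pts), tolerance = 1e-12)
  }
  # Kruskal union-find oracle at larger S
  for (S in c(8, 20, 40)) {
    pts <- matrix(runif(3 * S), ncol = 3)
    expect_equal(sum(minimum_spanning_tree(pts)$length),
                 kruskal_mst_length(pts), tolerance = 1e-10)
  }
})

test_that("MST total length matches igraph on random point sets", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (S in c(10, 30)) {
    pts <- matrix(runif(3 * S), ncol = 3)
    g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(pts)),
                                             mode = "undirected",
                                             weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(minimum_spanning_tree(pts)$length), ref,
                 tolerance = 1e-10)
  }
})

test_that("richness is monotone under point insertion", {
  set.seed(4)
  for (rep in 1:50) {
    base <- matrix(runif(3 * 10), ncol = 3)
    extra <- matrix(runif(3 * 5), ncol = 3)
    expect_gte(functional_richness(rbind(base, extra)) + 1e-12,
               functional_richness(base))
  }
})

test_that("indices are permutation invariant and bounded in [0, 1]", {
  set.seed(5)
  for (rep in 1:40) {
    S <- sample(3:40, 1)
    pts <- matrix(runif(3 * S), ncol = 3)
    perm <- pts[sample(S), ]
    expect_equal(functional_richness(perm), functional_richness(pts),
                 tolerance = 1e-9)
    expect_equal(functional_divergence(perm), functional_divergence(pts),
                 tolerance = 1e-12)
    expect_equal(functional_evenness(perm), functional_evenness(pts),
                 tolerance = 1e-12)
    for (v in c(functional_richness(pts), functional_divergence(pts),
                functional_evenness(pts))) {
      expect_gte(v, 0)
      expect_lte(v, 1 + 1e-12)
    }
  }
})

test_that("duplicating points keeps richness but may move FDiv and FEve", {
  set.seed(6)
  pts <- matrix(runif(3 * 12), ncol = 3)
  dup <- rbind(pts, pts[1:4, ])
  expect_equal(functional_richness(dup), functional_richness(pts),
               tolerance = 1e-9)
  # divergence and evenness are distribution-sensitive: duplicated mass
  # changes them (documented behaviour, not an error)
  expect_false(isTRUE(all.equal(functional_divergence(dup),
                                functional_divergence(pts))))
})

test_that("divergence is exactly 1 for centre-symmetric configurations", {
  # octahedron vertices around the cube centre
  oct <- rbind(c(0.1, 0.5, 0.5), c(0.9, 0.5, 0.5), c(0.5, 0.1, 0.5),
               c(0.5, 0.9, 0.5), c(0.5, 0.5, 0.1), c(0.5, 0.5, 0.9))
  expect_equal(functional_divergence(oct), 1)
  # antipodal pairs on a sphere: centre of gravity is the sphere centre,
  # so every point is equidistant from it
  set.seed(7)
  z <- matrix(rnorm(3 * 15), ncol = 3)
  z <- 0.3 * z / sqrt(rowSums(z^2))
  sphere <- rbind(0.5 + z, 0.5 - z)
  expect_equal(functional_divergence(sphere), 1, tolerance = 1e-12)
})

test_that("neighborhood_sample enforces its contract", {
  expect_error(neighborhood_sample(matrix(1, 2, 2)), "3 trait")
  expect_error(neighborhood_sample(rbind(c(0.1, NA, 0.3))), "nodata")
  expect_error(neighborhood_sample(rbind(c(0.1, 1.4, 0.3))), "\\[0, 1\\]")
  s <- neighborhood_sample(tetrahedron, focal_id = c(3, 7))
  expect_equal(attr(s, "S"), 4)
  expect_equal(attr(s, "focal_id"), c(3, 7))
})
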