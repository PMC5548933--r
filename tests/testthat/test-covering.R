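test_that("dual graph boundary conventions", {
  tri <- weighted_graph(cbind(c(1, 2, 1), c(2, 3, 3), c(1, 1, 1)))
  D <- network_distances(tri)
  A <- dual_graph(D, 2) # l > diameter: no dual edges
  expect_false(any(A))
  A2 <- dual_graph(D, 0.5) # l below every distance: complete dual
  expect_true(all(A2[upper.tri(A2)]))
  A3 <- dual_graph(D, 1) # d = 1 >= l: boundary pairs are dual-adjacent
  expect_true(all(A3[upper.tri(A3)]))
})

test_that("box covering degenerate scales", {
  g3 <- sierpinski_network(3, 0.5, 3)
  D <- network_distances(g3)
  cov_big <- box_cover(D, network_diameter(D) * 1.01, trials = 5, seed = 1)
  expect_equal(cov_big$n_boxes, 1L)
  expect_equal(cov_big$measures, 1)
  cov_small <- box_cover(D, min(D[D > 0]), trials = 5, seed = 1)
  expect_equal(cov_small$n_boxes, nrow(D)) # strict convention: all singletons
})

test_that("box covering partitions nodes into boxes of pairwise distance < l", {
  g <- toy_networks()$random8
  D <- network_distances(g)
  for (l in as.numeric(unique_distance_scales(D))[c(2, 5, 9)]) {
    cov <- box_cover(D, l, trials = 50, seed = 2)
    expect_equal(sort(unique(cov$assignment)), seq_len(cov$n_boxes))
    expect_equal(sum(cov$masses), nrow(D))
    expect_true(all(cov$masses > 0))
    expect_equal(sum(cov$measures), 1)
    for (b in seq_len(cov$n_boxes)) {
      memb <- which(cov$assignment == b)
      if (length(memb) > 1) {
        expect_true(all(D[memb, memb] < l - 1e-9 | diag(length(memb)) == 1))
      }
    }
  }
})

test_that("greedy covering attains the exhaustive minimal coloring on small toys", {
  for (g in toy_networks()) {
    D <- network_distances(g)
    sc <- as.numeric(unique_distance_scales(D))
    probe <- unique(c(sc, (sc[-length(sc)] + sc[-1]) / 2))
    for (l in probe) {
      adj <- dual_graph(D, l)
      cov <- box_cover(D, l, trials = 300, seed = 11)
      expect_equal(cov$n_boxes, oracle_chromatic(adj),
                   info = sprintf("l = %g", l))
    }
  }
})

test_that("box count is non-increasing in the scale", {
  g <- toy_networks()$two_triangles
  D <- network_distances(g)
  sc <- as.numeric(unique_distance_scales(D))
  counts <- vapply(sc, function(l) box_cover(D, l, trials = 200, seed = 3)$n_boxes,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("partition function normalization and q behaviour", {
  g <- toy_networks()$k4
  D <- network_distances(g)
  sc <- as.numeric(unique_distance_scales(D))
  for (l in sc) {
    cov <- box_cover(D, l, trials = 50, seed = 4)
    expect_equal(partition_function(cov, 1), 1)
    expect_equal(partition_function(cov, 0), cov$n_boxes)
    if (cov$n_boxes >= 2) {
      qs <- c(-2, -1, 0, 1, 2, 3)
      vals <- vapply(qs, function(q) partition_function(cov, q), numeric(1))
      expect_true(all(diff(vals) < 0)) # strictly decreasing in q
    }
  }
  # two equal boxes
  cov2 <- structure(list(measures = c(0.5, 0.5), masses = c(2L, 2L),
                         n_boxes = 2L), class = "box_covering")
  expect_equal(partition_function(cov2, 2), 0.5)

  g3 <- sierpinski_network(3, 0.5, 3)
  D3 <- network_distances(g3)
  mid <- stats::median(as.numeric(unique_distance_scales(D3)))
  cov3 <- box_cover(D3, mid, trials = 50, seed = 5)
  expect_equal(partition_function(cov3, -2),
               sum((cov3$masses / sum(cov3$masses))^(-2)))
})

test_that("sandbox counts match a brute-force scan of the distance row", {
  g3 <- sierpinski_network(3, 0.5, 3)
  D <- network_distances(g3)
  L <- network_diameter(D)
  sc <- as.numeric(unique_distance_scales(D))
  for (center in c(1, 5, 39)) {
    prev <- -1
    for (l in sc) {
      sb <- sandbox_count(D, center, l)
      expect_equal(sb$count, sum(D[-center, center] <= l + 1e-9))
      expect_equal(sb$measure, sb$count / nrow(D))
      expect_gte(sb$count, prev) # monotone non-decreasing in l
      prev <- sb$count
    }
    expect_equal(sandbox_count(D, center, L)$count, nrow(D) - 1L)
    expect_equal(sandbox_count(D, center, min(D[D > 0]) / 2)$count, 0L)
  }
  expect_equal(sandbox_count(D, 2, 0.25, include_center = TRUE)$count,
               sandbox_count(D, 2, 0.25)$count + 1L)
})

test_that("sandbox moments reduce to closed forms and brute-force averages", {
  # ring of N unit edges: every radius-l sandbox holds 2*floor(l) nodes
  N <- 24
  ring <- igraph::make_ring(N)
  igraph::E(ring)$weight <- 1
  D <- network_distances(ring)
  for (l in c(1, 2.5, 4)) {
    m <- 2 * floor(l)
    expect_equal(sandbox_moment(D, l, 2, seq_len(N)), m / N)
    expect_equal(sandbox_moment(D, l, 0, seq_len(N)), (m / N)^(-1))
  }

  g3 <- sierpinski_network(3, 0.5, 3)
  D3 <- network_distances(g3)
  l <- 0.75
  cnt <- vapply(seq_len(nrow(D3)), function(i) sum(D3[-i, i] <= l + 1e-9),
                numeric(1))
  expect_equal(sandbox_moment(D3, l, -6, seq_len(nrow(D3))),
               mean((cnt / nrow(D3))^(-7)))
  # all centers empty at a sub-minimal radius
  expect_error(sandbox_moment(D3, 1e-4, 0, seq_len(nrow(D3))), "zero count")
})

test_that("box measures shift from uniform to peaked as the scale grows", {
  g4 <- sierpinski_network(3, 0.5, 4)
  D <- network_distances(g4)
  sc <- as.numeric(unique_distance_scales(D))
  md <- measure_distribution(g4, scales = c(min(sc), stats::median(sc), max(sc) * 1.01),
                             trials = 30, seed = 9)
  expect_equal(length(md[[1]]), nrow(D)) # all singletons: uniform measure
  expect_true(all(abs(md[[1]] - 1 / nrow(D)) < 1e-12))
  expect_equal(as.numeric(md[[3]]), 1) # beyond the diameter: one box
  maxmu <- vapply(md, function(m) attr(m, "max_measure"), numeric(1))
  expect_true(all(diff(maxmu) > 0))
})
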