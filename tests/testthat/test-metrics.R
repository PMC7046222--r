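test_that("degree distribution sums to one on canonical graphs", {
  dd <- degree_distribution(path_network(4))
  expect_equal(dd$k, c(1L, 2L))
  expect_equal(dd$p, c(0.5, 0.5))

  dd2 <- degree_distribution(complete_network(4))
  expect_equal(dd2$k, 3L)
  expect_equal(dd2$p, 1)

  dd3 <- degree_distribution(contact_network(3, matrix(integer(0), 0, 2)))
  expect_equal(dd3$k, 0L)
  expect_equal(dd3$p, 1)
  expect_equal(sum(degree_distribution(cycle_network(6))$p), 1)
})

test_that("average degree equals 2E/N", {
  expect_equal(average_degree(path_network(10)), 1.8)
  expect_equal(average_degree(complete_network(3)), 2)
})

test_that("graph diameter matches closed forms and reports disconnection", {
  expect_equal(graph_diameter(path_network(9)), 8L)
  expect_equal(graph_diameter(complete_network(5)), 1L)
  expect_equal(graph_diameter(cycle_network(6)), 3L)
  disconnected <- contact_network(4, rbind(c(1, 2), c(3, 4)))
  expect_error(graph_diameter(disconnected), "2 connected components")
})

test_that("graph diameter agrees with brute-force BFS on random graphs", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(5:60, 1)
    # random connected graph: random tree plus extra edges
    tree <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
    extra <- t(utils::combn(n, 2))
    extra <- extra[sample(nrow(extra), min(nrow(extra), n)), , drop = FALSE]
    net <- contact_network(n, rbind(tree, extra))
    expect_equal(graph_diameter(net), brute_force_diameter(net))
  }
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(make_straight_chain(3)), sqrt(2 / 3),
               tolerance = 1e-12)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(1 / 2), tolerance = 1e-12)
  for (n in c(2, 5, 17, 50)) {
    expect_equal(radius_of_gyration(make_straight_chain(n)),
                 sqrt((n^2 - 1) / 12), tolerance = 1e-9)
  }
})

test_that("Laplacian spectra match closed forms for paths and complete graphs", {
  s2 <- laplacian_spectrum(path_network(2))
  expect_equal(s2$values, c(0, 2), tolerance = 1e-9)
  expect_equal(s2$second_largest, 0)

  s3 <- laplacian_spectrum(path_network(3))
  expect_equal(s3$values, c(0, 1, 3), tolerance = 1e-9)

  # path eigenvalues 2 - 2 cos(k pi / n)
  for (n in c(5, 9)) {
    expect_equal(laplacian_spectrum(path_network(n))$values,
                 sort(2 - 2 * cos((seq_len(n) - 1) * pi / n)),
                 tolerance = 1e-9)
  }

  s4 <- laplacian_spectrum(complete_network(4))
  expect_equal(s4$values, c(0, 4, 4, 4), tolerance = 1e-9)
  expect_equal(s4$second_largest, 4, tolerance = 1e-9)
  expect_equal(s4$fiedler, 4, tolerance = 1e-9)
})

test_that("Laplacian invariants: trace identity, zero modes count components", {
  set.seed(5)
  for (rep in 1:6) {
    n <- sample(4:40, 1)
    m <- sample(n:(2 * n), 1)
    pairs <- t(utils::combn(n, 2))
    net <- contact_network(n, pairs[sample(nrow(pairs), min(m, nrow(pairs))), ])
    sp <- laplacian_spectrum(net)
    expect_gte(min(sp$values), -1e-9)
    expect_equal(sum(sp$values), 2 * n_edges(net), tolerance = 1e-8)
    n_zero <- sum(abs(sp$values) < 1e-8)
    n_comp <- igraph::components(as_igraph(net))$no
    expect_equal(n_zero, n_comp)
    # largest eigenvalue is at most twice the maximum degree
    expect_lte(max(sp$values), 2 * max(node_degrees(net)) + 1e-9)
  }
})

test_that("spectrum histograms pool, normalize and locate the peak", {
  h <- spectrum_histogram(list(c(0, 2)), bin_width = 1)
  expect_equal(h$p, c(0.5, 0.5))
  expect_equal(h$mids, c(0.5, 2.5))
  expect_equal(h$peak, 0.5)  # tie broken toward smaller eigenvalue

  sp <- laplacian_spectrum(complete_network(4))
  h1 <- spectrum_histogram(list(sp), bin_width = 0.5)
  h2 <- spectrum_histogram(list(sp, sp, sp), bin_width = 0.5)
  expect_equal(h1$p, h2$p)
  expect_equal(h1$peak, h2$peak)
  expect_equal(sum(h1$p), 1)
  expect_error(spectrum_histogram(list(sp), bin_width = 0), "positive")
})
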