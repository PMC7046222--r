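test_that("straight chains are collinear with touching beads", {
  ch <- make_straight_chain(3)
  expect_equal(ch$positions, cbind(c(0, 1, 2), 0, 0))

  ch2 <- make_straight_chain(2, seed = 7)
  expect_equal(dist(ch2$positions)[1], 1)

  ch3 <- make_straight_chain(10, a = 0.3, seed = 1)
  gaps <- sqrt(rowSums(diff(ch3$positions)^2))
  expect_equal(gaps, ch3$radii[-10] + ch3$radii[-1], tolerance = 1e-12)
  d <- pairwise_distances(ch3)
  lim <- outer(ch3$radii, ch3$radii, "+")
  expect_true(all(d[upper.tri(d)] >= lim[upper.tri(lim)] * (1 - 1e-9)))
})

test_that("chain constructor validates sizes, radii and exclusion", {
  expect_error(make_straight_chain(1), "N")
  expect_error(make_straight_chain(5, a = 0.7), "0, 0.5")
  expect_error(bead_chain(cbind(0, 0, 0)), "at least 2")
  expect_error(bead_chain(rbind(c(0, 0, 0), c(1, 0, 0)), radii = c(0.5, -1)),
               "positive")
  expect_error(bead_chain(rbind(c(0, 0, 0), c(0.5, 0, 0))), "excluded volume")
})

test_that("pairwise distances satisfy metric properties and isometry invariance", {
  d <- pairwise_distances(make_straight_chain(3))
  expect_equal(d[1, 3], 2)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  tri <- bead_chain(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  dtri <- pairwise_distances(tri)
  expect_equal(dtri[upper.tri(dtri)], rep(1, 3), tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:5) {
    ch <- make_straight_chain(8, a = 0.2, seed = rep)
    theta <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(theta[1]), -sin(theta[1])),
                c(0, sin(theta[1]), cos(theta[1])))
    Rz <- rbind(c(cos(theta[2]), -sin(theta[2]), 0),
                c(sin(theta[2]), cos(theta[2]), 0), c(0, 0, 1))
    moved <- ch
    moved$positions <- ch$positions %*% (Rx %*% Rz) +
      rep(runif(3, -5, 5), each = 8)
    expect_equal(pairwise_distances(moved), pairwise_distances(ch),
                 tolerance = 1e-9)
  }
})

test_that("exclusion check flags offending pairs with their indices", {
  expect_false(violates_exclusion(make_straight_chain(6))$violated)

  touching <- bead_chain(rbind(c(0, 0, 0), c(0.5, 0, 0)), validate = FALSE)
  v <- violates_exclusion(touching)
  expect_true(v$violated)
  expect_equal(v$pairs[1, ], c(i = 1, j = 2))

  tol <- 1e-3
  boundary <- bead_chain(rbind(c(0, 0, 0), c(1 - tol / 2, 0, 0)),
                         validate = FALSE)
  expect_false(violates_exclusion(boundary, tol_overlap = tol)$violated)
})

test_that("radii sample means converge to the configured mean diameter", {
  a <- 0.4
  means <- vapply(1:40, function(s) {
    mean(2 * make_straight_chain(50, a = a, seed = s)$radii)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1), 3 * se + 1e-12)
})

test_that("XYZ files round-trip coordinates, radii and unit scale", {
  ch <- make_straight_chain(7, a = 0.25, seed = 3)
  ch$unit_scale <- 5.066
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ch, f)
  back <- read_xyz(f)
  expect_equal(back$positions, ch$positions)
  expect_equal(back$radii, ch$radii)
  expect_equal(back$unit_scale, ch$unit_scale)
  expect_identical(readLines(f)[3], sub("^C ", "C ", readLines(f)[3]))
})

test_that("edge-list CSVs use 0-based ids on disk and round-trip", {
  net <- contact_network(5, rbind(c(1, 2), c(2, 3), c(1, 5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_edges(net, f)
  on_disk <- read.csv(f)
  expect_equal(names(on_disk), c("i", "j"))
  expect_equal(min(on_disk$i), 0)
  back <- read_edges(f, n_nodes = 5)
  expect_equal(back$edges, net$edges)
})
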