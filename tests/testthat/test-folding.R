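test_that("tiny chains fold to their exact aggregates", {
  # N = 2: nothing to attempt, single backbone bond
  r2 <- run_folding(2, folding_params(seed = 11))
  expect_equal(nrow(r2$network$edges), 1)
  expect_equal(r2$l, 0)

  # N = 3: the single candidate pair always closes into a triangle
  for (s in 1:4) {
    r3 <- run_folding(3, folding_params(seed = s))
    expect_equal(nrow(r3$network$edges), 3)
    d <- pairwise_distances(r3$chain)
    expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 0.05)
  }

  # N = 4: four equal spheres can be mutually tangent (tetrahedron)
  for (s in 1:4) {
    r4 <- run_folding(4, folding_params(seed = s))
    expect_equal(nrow(r4$network$edges), 6)
  }

  # N = 5: five equal mutually tangent spheres are impossible in 3D
  for (s in 1:8) {
    r5 <- run_folding(5, folding_params(seed = s))
    expect_lt(nrow(r5$network$edges), 10)
  }
})

test_that("attempt_link enforces its preconditions", {
  ch <- make_straight_chain(5)
  net <- contact_network(5, cbind(1:4, 2:5))
  expect_error(attempt_link(ch, net, c(2, 3)), "backbone-adjacent")
  expect_error(attempt_link(ch, net, c(3, 3)), "itself")
  expect_error(attempt_link(ch, net, c(0, 2)), "node ids")
  linked <- attempt_link(ch, net, c(1, 3))
  expect_true(linked$success)
  expect_error(attempt_link(linked$chain, linked$net, c(1, 3)),
               "already linked")
})

test_that("failed attempts are side-effect-free", {
  # fold N = 5 completely, then try any remaining unlinked pair
  run <- run_folding(5, folding_params(seed = 3))
  all_pairs <- t(utils::combn(5, 2))
  linked <- paste(run$network$edges[, 1], run$network$edges[, 2])
  open <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% linked), ,
                    drop = FALSE]
  open <- open[open[, 2] - open[, 1] > 1, , drop = FALSE]
  skip_if(nrow(open) == 0)  # cannot happen for N = 5 (K5 is infeasible)
  res <- attempt_link(run$chain, run$network, open[1, ])
  expect_false(res$success)
  expect_equal(res$chain$positions, run$chain$positions, tolerance = 1e-12)
})

test_that("runs are reproducible from their seed", {
  a <- run_folding(25, folding_params(seed = 77), trace = TRUE)
  b <- run_folding(25, folding_params(seed = 77), trace = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$network$edges, b$network$edges)
  expect_equal(a$chain$positions, b$chain$positions, tolerance = 0)

  c_ <- run_folding(25, folding_params(seed = 78))
  expect_false(identical(b$network$edges, c_$network$edges))
})

test_that("folding invariants hold along a logged run", {
  run <- run_folding(60, folding_params(seed = 5), trace = TRUE,
                     check_every_step = TRUE)
  p <- run$params

  # excluded volume and bond conservation at every accepted step
  expect_lte(run$diagnostics$max_overlap_violation, p$tol_overlap)
  expect_lte(run$diagnostics$max_bond_violation, p$tol_bond)

  # the trace's success count l is monotone, i.e. links are never lost
  tr <- run$trace
  expect_true(all(diff(tr$l) >= 0))
  expect_equal(sum(tr$success), run$l)
  expect_equal(nrow(run$network$edges), 59 + run$l)

  # backbone present, aggregate connected, degrees below the kissing bound
  bb <- cbind(1:59, 2:60)
  key <- paste(run$network$edges[, 1], run$network$edges[, 2])
  expect_true(all(paste(bb[, 1], bb[, 2]) %in% key))
  expect_true(igraph::is_connected(as_igraph(run$network)))
  expect_lte(max(node_degrees(run$network)), 12)

  # compaction: final extent strictly below the straight chain's
  expect_lt(radius_of_gyration(run$chain), sqrt((60^2 - 1) / 12))

  # final state satisfies excluded volume at the working tolerance
  expect_false(violates_exclusion(run$chain, tol_overlap = p$tol_overlap)$violated)
})

test_that("snapshots record the requested intermediate states", {
  run <- run_folding(30, folding_params(seed = 9), snapshots = c(0, 2, 7))
  ls <- vapply(run$snapshots, function(s) s$l, numeric(1))
  expect_equal(ls, c(0, 2, 7))
  # the l = 0 snapshot is the (jittered) straight chain
  expect_equal(run$snapshots[[1]]$chain$positions[, 1],
               0:29, tolerance = 0.2)
  rgs <- vapply(run$snapshots, function(s) radius_of_gyration(s$chain),
                numeric(1))
  expect_true(all(diff(rgs) < 0))  # compaction as l grows
})

test_that("heterogeneous radii fold with touching preserved", {
  run <- run_folding(30, folding_params(seed = 13, a = 0.3))
  expect_equal(length(unique(run$chain$radii)), 30)
  expect_true(all(run$chain$radii >= 0.35 & run$chain$radii <= 0.65))
  d <- pairwise_distances(run$chain)
  lim <- outer(run$chain$radii, run$chain$radii, "+")
  off <- upper.tri(d)
  expect_true(all(d[off] >= lim[off] * (1 - run$params$tol_bond)))
})

test_that("ensembles have one row per run with derived seeds", {
  tab <- run_ensemble(c(3, 5), reps = 3, params = folding_params(seed = 42))
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$N)), c(3, 5))
  expect_equal(anyDuplicated(tab$seed), 0)
  expect_true(all(tab[tab$N == 3, "edges"] == 3))  # triangles always

  tab1 <- run_ensemble(c(2, 3), reps = 1, params = folding_params(seed = 1))
  expect_equal(nrow(tab1), 2)

  # repeatable
  tab2 <- run_ensemble(c(3, 5), reps = 3, params = folding_params(seed = 42))
  expect_identical(tab, tab2)
})

test_that("trace exports use the 0-based on-disk convention", {
  run <- run_folding(10, folding_params(seed = 4), trace = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(run, f)
  tr <- read.csv(f)
  expect_equal(names(tr), c("attempt_index", "i", "j", "outcome", "l"))
  expect_equal(tr$attempt_index[1], 0)
  expect_true(all(tr$outcome %in% c("success", "fail")))
  expect_equal(min(tr$i), min(run$trace$i) - 1L)
})
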