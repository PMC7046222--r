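test_that("read_calpha extracts one CA per residue in file order", {
  txt <- generate_toy_pdb("collinear", n = 3, spacing = 5)
  tr <- read_calpha(txt)
  expect_equal(nrow(tr$coordinates), 3)
  expect_equal(tr$coordinates[, 1], c(0, 5, 10))

  # extra side-chain atoms are ignored
  lines <- strsplit(txt, "\n")[[1]]
  cb <- "ATOM      9  CB  ALA A   2       5.500   1.000   0.000  1.00  0.00           C"
  with_cb <- paste(append(lines, cb, after = 2), collapse = "\n")
  expect_equal(nrow(read_calpha(with_cb)$coordinates), 3)

  # only the first MODEL of a multi-model file is used
  atoms <- lines[startsWith(lines, "ATOM")]
  two_models <- paste(c("MODEL     1", atoms, "ENDMDL",
                        "MODEL     2", sub("^ATOM", "ATOM", atoms), "ENDMDL",
                        "END"), collapse = "\n")
  expect_equal(nrow(read_calpha(two_models)$coordinates), 3)

  expect_error(read_calpha("TER\nEND\n"), "")
})

test_that("alternate locations keep the highest-occupancy copy", {
  rec <- function(serial, alt, occ, x) {
    sprintf("ATOM  %5d  CA %sALA A   1    %8.3f   0.000   0.000%6.2f  0.00           C",
            serial, alt, x, occ)
  }
  txt <- paste(c(rec(1, "A", 0.4, 0), rec(2, "B", 0.6, 3),
                 "ATOM      3  CA  ALA A   2      10.000   0.000   0.000  1.00  0.00           C",
                 "END"), collapse = "\n")
  tr <- read_calpha(txt)
  expect_equal(nrow(tr$coordinates), 2)
  expect_equal(tr$coordinates[1, 1], 3)  # occupancy 0.6 wins
})

test_that("build_prn applies the distance threshold inclusively", {
  tr <- residue_trace(cbind(c(0, 5, 10), 0, 0))
  net <- build_prn(tr, d_c = 6.5)
  expect_equal(net$edges, rbind(c(1L, 2L), c(2L, 3L)))

  net12 <- build_prn(tr, d_c = 12)
  expect_equal(nrow(net12$edges), 3)

  square <- residue_trace(6 * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  nsq <- build_prn(square, d_c = 6.5)
  expect_equal(nrow(nsq$edges), 4)  # diagonal 6 * sqrt(2) = 8.49 excluded

  # boundary: d equal to the cutoff counts as connected
  pair <- residue_trace(rbind(c(0, 0, 0), c(6.5, 0, 0)))
  expect_equal(nrow(build_prn(pair, d_c = 6.5)$edges), 1)
  expect_error(build_prn(tr, d_c = -1), "positive")
})

test_that("edges are monotone in the cutoff", {
  set.seed(3)
  tr <- random_trace(40, spacing = 3.8, seed = 9)
  cuts <- c(4, 5, 6.5, 8)
  nets <- lapply(cuts, function(dc) build_prn(tr, dc))
  for (k in seq_along(cuts)[-1]) {
    small <- apply(nets[[k - 1]]$edges, 1, paste, collapse = "-")
    large <- apply(nets[[k]]$edges, 1, paste, collapse = "-")
    expect_true(all(small %in% large))
  }
})

test_that("straight traces with s < d_c < 2s give exactly the path graph", {
  tr <- residue_trace(cbind(5 * (0:9), 0, 0))
  net <- build_prn(tr, d_c = 7)
  expect_equal(net$edges, cbind(1:9, 2:10))
})

test_that("build_prn equals the brute-force double loop on random traces", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    tr <- random_trace(n, spacing = 3.8, seed = 1000 + rep)
    dc <- runif(1, 4, 8)
    net <- build_prn(tr, d_c = dc)
    ref <- brute_force_prn_edges(tr$coordinates, dc)
    expect_equal(net$edges, matrix(as.integer(ref), ncol = 2),
                 info = sprintf("rep %d (n=%d, dc=%.3f)", rep, n, dc))
  }
})

test_that("mean link length averages edge distances", {
  tr <- residue_trace(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(mean_link_length(tr, build_prn(tr, 6.5)), 5)

  tr3 <- residue_trace(rbind(c(0, 0, 0), c(4, 0, 0), c(10, 0, 0)))
  net3 <- contact_network(3, rbind(c(1, 2), c(2, 3)))  # lengths 4 and 6
  expect_equal(mean_link_length(tr3, net3), 5)

  trc <- residue_trace(cbind(c(0, 5, 10), 0, 0))
  expect_equal(mean_link_length(trc, build_prn(trc, 6.5)), 5)

  empty <- contact_network(3, matrix(integer(0), 0, 2))
  expect_error(mean_link_length(trc, empty), "undefined")
})
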