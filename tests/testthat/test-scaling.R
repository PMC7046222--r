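test_that("power-law fits are exact on noiseless input", {
  N <- 3:100
  f <- fit_power_law(N, 2 * N^0.4)
  expect_equal(f$exponent, 0.4, tolerance = 1e-10)
  expect_equal(f$prefactor, 2, tolerance = 1e-10)
  expect_lt(f$stderr_exponent, 1e-10)

  f2 <- fit_power_law(c(8, 27, 64), c(8, 27, 64)^(1 / 3))
  expect_equal(f2$exponent, 1 / 3, tolerance = 1e-10)

  expect_equal(f$nu_SF, 1 / 3)
  expect_equal(f$nu_RW, 3 / 5)
})

test_that("power-law exponent is recovered under multiplicative noise", {
  set.seed(99)
  N <- round(exp(seq(log(3), log(200), length.out = 25)))
  reps <- 30
  y <- vapply(N, function(n) {
    mean(n^0.4 * exp(rnorm(reps, 0, 0.05)))
  }, numeric(1))
  f <- fit_power_law(N, y)
  expect_lt(abs(f$exponent - 0.4), 2 * f$stderr_exponent + 0.01)
})

test_that("exponent is invariant under rescaling of y", {
  N <- c(4, 9, 25, 64, 144)
  y <- N^0.52 * 1.7
  f1 <- fit_power_law(N, y)
  f2 <- fit_power_law(N, y * 37)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-12)
  expect_equal(f2$prefactor / f1$prefactor, 37, tolerance = 1e-9)
})

test_that("power-law fit validates its input", {
  expect_error(fit_power_law(1:5, c(-1, 2, 3, 4, 5)), "positive")
  expect_error(fit_power_law(c(2, 2, 2), c(1, 2, 3)), "distinct")
  expect_error(fit_power_law(1:3, 1:4), "lengths")
})

test_that("diameter scaling on unfolded chains has exponent one", {
  # a path graph on N nodes has diameter N - 1, so D + 1 = N exactly
  N <- c(4, 8, 16, 32, 64)
  tab <- data.frame(N = rep(N, each = 3),
                    diameter = rep(N, each = 3) - 1)
  f <- fit_diameter_scaling(tab)
  expect_equal(f$exponent, 1, tolerance = 1e-10)
  expect_equal(f$prefactor, 1, tolerance = 1e-10)
})

test_that("diameter scaling averages across realizations before fitting", {
  tab <- data.frame(N = c(10, 10, 20, 20, 40, 40),
                    diameter = c(3, 5, 6, 8, 10, 14))
  f <- fit_diameter_scaling(tab)
  agg <- aggregate(diameter ~ N, tab, mean)
  ref <- fit_power_law(agg$N, agg$diameter + 1)
  expect_equal(f$exponent, ref$exponent)
  f_all <- fit_diameter_scaling(tab, average_first = FALSE)
  expect_false(isTRUE(all.equal(f$stderr_exponent, f_all$stderr_exponent)))
})

test_that("diameter-vs-Rg fits recover exact linear relations", {
  rg <- seq(2, 30, length.out = 12)
  D <- 0.5 * rg - 1  # so D + 1 = 0.5 rg
  f <- fit_diameter_vs_rg(D, rg)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 0, tolerance = 1e-8)

  expect_error(fit_diameter_vs_rg(c(1, 2, 3), rep(4, 3)), "degenerate")
  expect_error(fit_diameter_vs_rg(1:4, 1:3), "lengths")
})

test_that("model units convert to Angstrom through the mean link length", {
  expect_equal(rg_to_angstrom(2), 2 * 5.066)
  expect_equal(rg_to_angstrom(c(1, 3), unit_scale = 2), c(2, 6))
})
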