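#' Power-law fit y ~ N^nu
#'
#' Ordinary least squares of `log(y)` on `log(N)`; the slope is the scaling
#' exponent `nu`, the exponentiated intercept the prefactor. Reference
#' exponents for 3D aggregates are attached for comparison: space-filling
#' `nu_SF = 1/3` and self-avoiding random walk `nu_RW = 3/5`.
#'
#' @param N_values chain lengths (at least 3 distinct values).
#' @param y_values positive observable values, same length as `N_values`.
#' @return An object of class `power_fit`: list with `exponent`,
#'   `prefactor`, `stderr_exponent`, `n_points`, `nu_SF`, `nu_RW` and the
#'   underlying `lm` fit.
#' @examples
#' f <- fit_power_law(3:50, 2 * (3:50)^0.4)
#' coef(f)
#' @export
fit_power_law <- function(N_values, y_values) {
  N_values <- as.numeric(N_values)
  y_values <- as.numeric(y_values)
  if (length(N_values) != length(y_values)) stop("input lengths differ")
  if (any(!is.finite(y_values)) || any(y_values <= 0))
    stop("all y values must be positive")
  if (any(!is.finite(N_values)) || any(N_values <= 0))
    stop("all N values must be positive")
  if (length(unique(N_values)) < 3L)
    stop("need at least 3 distinct N values")
  fit <- lm(log(y_values) ~ log(N_values))
  sm <- summary(fit)$coefficients
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = unname(exp(coef(fit)[1])),
                 stderr_exponent = unname(sm[2, 2]),
                 n_points = length(N_values),
                 nu_SF = 1 / 3, nu_RW = 3 / 5,
                 fit = fit),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Power-law fit over", x$n_points, "points\n")
  cat(sprintf("  exponent nu = %.4f (se %.4f), prefactor = %.4f\n",
              x$exponent, x$stderr_exponent, x$prefactor))
  cat(sprintf("  reference: nu_SF = %.4f (space filling), nu_RW = %.1f (SAW)\n",
              x$nu_SF, x$nu_RW))
  invisible(x)
}

#' @export
coef.power_fit <- function(object, ...) {
  c(prefactor = object$prefactor, exponent = object$exponent)
}

#' @export
summary.power_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.power_fit <- function(object, N, ...) {
  object$prefactor * as.numeric(N)^object$exponent
}

#' Diameter scaling with chain length
#'
#' Fits the shifted power law `(D + 1) ~ N^nu` to an ensemble table.
#' Diameters are averaged across realizations per chain length before the
#' log-log fit (per-run fitting is available with
#' `average_first = FALSE` for uncertainty checks). The shift by one makes
#' the smallest chains well behaved (`N = 2` has `D = 1`).
#'
#' @param ensemble a data frame with columns `N` and `diameter`, e.g. from
#'   [run_ensemble()].
#' @param average_first average `D` across realizations per `N` before
#'   fitting (default `TRUE`).
#' @return A [fit_power_law()] result (`power_fit`).
#' @export
fit_diameter_scaling <- function(ensemble, average_first = TRUE) {
  if (!all(c("N", "diameter") %in% names(ensemble)))
    stop("'ensemble' needs columns 'N' and 'diameter'")
  if (average_first) {
    agg <- aggregate(diameter ~ N, data = ensemble, FUN = mean)
    fit_power_law(agg$N, agg$diameter + 1)
  } else {
    fit_power_law(ensemble$N, ensemble$diameter + 1)
  }
}

#' Linear relation between diameter and radius of gyration
#'
#' Least-squares fit of `(D + 1)` on `R_g`. For comparison with residue
#' networks, model radii of gyration must first be converted to Angstrom
#' by multiplying with the mean link length (5.066 Angstrom per model
#' unit); the slope is then in 1/Angstrom.
#'
#' @param D_values graph diameters.
#' @param Rg_values radii of gyration (Angstrom), same length.
#' @return An object of class `linear_fit`: list with `slope`,
#'   `intercept`, `stderr_slope`, `n_points` and the `lm` fit.
#' @export
fit_diameter_vs_rg <- function(D_values, Rg_values) {
  D_values <- as.numeric(D_values)
  Rg_values <- as.numeric(Rg_values)
  if (length(D_values) != length(Rg_values)) stop("input lengths differ")
  if (length(D_values) < 3L) stop("need at least 3 points")
  if (var(Rg_values) == 0)
    stop("degenerate fit: all R_g values are equal")
  fit <- lm(I(D_values + 1) ~ Rg_values)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 stderr_slope = unname(sm[2, 2]),
                 n_points = length(D_values),
                 fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear fit (D + 1) ~ R_g over", x$n_points, "points\n")
  cat(sprintf("  slope = %.4f (se %.4f), intercept = %.4f\n",
              x$slope, x$stderr_slope, x$intercept))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Convert model radii of gyration to Angstrom
#'
#' Multiplies model-unit lengths by the mean PRN link length so that model
#' aggregates and residue networks can be compared on the same footing.
#'
#' @param rg radii of gyration in model units.
#' @param unit_scale Angstrom per model unit (default the reference
#'   `d_mean` = 5.066).
#' @return Lengths in Angstrom.
#' @export
rg_to_angstrom <- function(rg, unit_scale = reference_constants("d_mean")) {
  as.numeric(rg) * unit_scale
}
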