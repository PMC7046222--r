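#' Folding simulation parameters
#'
#' All knobs of the stochastic folding process. A pair counts as joined when
#' its gap is at most `tol_contact` times the contact distance; formed links
#' are held at contact within a relative `tol_bond`; volume exclusion is
#' enforced within a relative `tol_overlap`. An attempt fails when the pair
#' distance has not decreased by more than `stall_eps` over `stall_window`
#' consecutive steps or when `max_steps_per_attempt` (default `max(6 * N, 150)`)
#' is exhausted.
#'
#' @param a diameter heterogeneity in `[0, 0.5]`; sphere diameters are drawn
#'   uniformly from `[1 - a, 1 + a]`.
#' @param seed integer RNG seed; the whole run (radii, jitter, pair picks)
#'   is reproducible from it.
#' @param tol_contact relative contact tolerance for joining (default 1e-2).
#' @param tol_overlap relative excluded-volume tolerance (default 1e-3).
#' @param tol_bond relative slack on formed links (default 1e-2).
#' @param step_size displacement of each pulled bead per step, in model
#'   units (default 0.15).
#' @param max_steps_per_attempt step budget per attempt; `NULL` means
#'   `max(6 * N, 150)`.
#' @param stall_window steps without progress before an attempt is declared
#'   failed (default 5).
#' @param stall_eps minimal pair-distance decrease that counts as progress.
#' @return An object of class `folding_params`.
#' @export
folding_params <- function(a = 0, seed = 1L,
                           tol_contact = 1e-2, tol_overlap = 1e-3,
                           tol_bond = 1e-2, step_size = 0.15,
                           max_steps_per_attempt = NULL,
                           stall_window = 5L, stall_eps = 5e-2) {
  if (!is.numeric(a) || length(a) != 1L || a < 0 || a > 0.5)
    stop("'a' must lie in [0, 0.5]")
  for (nm in c("tol_contact", "tol_overlap", "tol_bond", "step_size", "stall_eps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("'", nm, "' must be a positive number")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  if (!is.null(max_steps_per_attempt)) {
    max_steps_per_attempt <- as.integer(max_steps_per_attempt)
    if (is.na(max_steps_per_attempt) || max_steps_per_attempt < 1L)
      stop("'max_steps_per_attempt' must be a positive integer")
  }
  structure(list(a = a, seed = seed, tol_contact = tol_contact,
                 tol_overlap = tol_overlap, tol_bond = tol_bond,
                 step_size = step_size,
                 max_steps_per_attempt = max_steps_per_attempt,
                 stall_window = as.integer(stall_window),
                 stall_eps = stall_eps),
            class = "folding_params")
}

#' @export
print.folding_params <- function(x, ...) {
  cat("Folding parameters: a =", x$a, " seed =", x$seed, "\n")
  cat("  tol_contact =", x$tol_contact, " tol_overlap =", x$tol_overlap,
      " tol_bond =", x$tol_bond, "\n")
  cat("  step_size =", x$step_size, " stall_window =", x$stall_window, "\n")
  invisible(x)
}

params_for_cpp <- function(params, N) {
  list(tol_contact = params$tol_contact,
       tol_overlap = params$tol_overlap,
       tol_bond = params$tol_bond,
       step_size = params$step_size,
       max_steps_per_attempt =
         if (is.null(params$max_steps_per_attempt)) max(6L * as.integer(N), 150L)
         else params$max_steps_per_attempt,
       stall_window = params$stall_window,
       stall_eps = params$stall_eps)
}

#' Attempt to join one pair of spheres
#'
#' Pulls beads `i` and `j` together under all geometric constraints (volume
#' exclusion for every pair, formed links held at contact; all beads may
#' move). On success the pair ends within the contact tolerance and the
#' link is added; on failure the configuration is rolled back unchanged.
#'
#' @param chain a [bead_chain()].
#' @param net the current [contact_network()] over the same beads (formed
#'   links, including the backbone).
#' @param pair integer vector `c(i, j)` of the beads to join (1-based).
#' @param params a [folding_params()].
#' @return A list with `success` (logical), `chain` (updated), `net`
#'   (updated on success) and `diagnostics`.
#' @export
attempt_link <- function(chain, net, pair, params = folding_params()) {
  stopifnot(inherits(chain, "bead_chain"), inherits(net, "contact_network"))
  pair <- as.integer(pair)
  if (length(pair) != 2L || any(is.na(pair)) || any(pair < 1L) || any(pair > chain$n))
    stop("'pair' must be two node ids in 1..N")
  i <- min(pair); j <- max(pair)
  if (i == j) stop("cannot link a bead to itself")
  if (j == i + 1L) stop("backbone-adjacent pair (", i, ", ", j, ") is already connected")
  if (nrow(net$edges) > 0L && any(net$edges[, 1] == i & net$edges[, 2] == j))
    stop("pair (", i, ", ", j, ") is already linked")
  res <- cpp_attempt_link(chain$positions, chain$radii, net$edges, i, j,
                          params_for_cpp(params, chain$n), TRUE)
  new_chain <- bead_chain(res$positions, radii = chain$radii,
                          unit_scale = chain$unit_scale, validate = FALSE)
  new_net <- if (res$success) contact_network(net$n_nodes, rbind(net$edges, c(i, j))) else net
  list(success = res$success, chain = new_chain, net = new_net,
       diagnostics = res$diagnostics)
}

#' Run one folding simulation
#'
#' Starts from a straight chain of `N` touching spheres (backbone links
#' fixed), then repeatedly picks a random unlinked non-backbone pair and
#' attempts to join it under the geometric constraints, until every
#' remaining pair is either connected or incapable of connecting. Failure
#' marks are cleared whenever a pair succeeds (earlier failures may become
#' feasible after the geometry changes); termination combines exhaustion of
#' the candidate set with a first-order rigidity certificate of the bond
#' framework, under which pairs away from contact provably cannot join.
#'
#' @param N integer chain length (>= 2).
#' @param params a [folding_params()].
#' @param snapshots integer vector of success counts `l` at which to record
#'   intermediate configurations (0 = initial chain).
#' @param trace record every attempt (default `TRUE`; the terminal sweep of
#'   an `N` in the hundreds adds tens of thousands of failed rows).
#' @param check_every_step assert the excluded-volume and bond-conservation
#'   invariants after every accepted dynamics step instead of only at the
#'   end (slower; used for invariant audits).
#' @return An object of class `geofold_run`: list with `chain` (final
#'   [bead_chain()]), `network` (final [contact_network()] including the
#'   backbone), `l` (number of successful joins), `trace` (data frame
#'   `i, j, success, l`), `snapshots` (list of `l`/[bead_chain()] pairs),
#'   `params` and `diagnostics` (max constraint violations observed,
#'   step/rigidity-test counts).
#' @examples
#' run <- run_folding(20, folding_params(seed = 42))
#' run$l
#' average_degree(run$network)
#' @export
run_folding <- function(N, params = folding_params(), snapshots = integer(0),
                        trace = TRUE, check_every_step = FALSE) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2")
  res <- cpp_run_folding(N, params$a, params$seed, params_for_cpp(params, N),
                         as.integer(snapshots), check_every_step, trace)
  chain <- bead_chain(res$positions, radii = res$radii, validate = FALSE)
  net <- contact_network(N, res$edges)
  snaps <- lapply(res$snapshots, function(s)
    list(l = s$l, chain = bead_chain(s$positions, radii = res$radii, validate = FALSE)))
  structure(list(chain = chain, network = net, l = res$l,
                 trace = if (trace) res$attempts else NULL,
                 snapshots = snaps, params = params,
                 diagnostics = res$diagnostics, N = N),
            class = "geofold_run")
}

#' @export
print.geofold_run <- function(x, ...) {
  cat("Folding run: N =", x$N, " seed =", x$params$seed, " a =", x$params$a, "\n")
  cat("  successful joins:", x$l, " edges:", nrow(x$network$edges),
      " mean degree:", format(average_degree(x$network), digits = 4), "\n")
  cat("  final R_g:", format(radius_of_gyration(x$chain), digits = 4),
      "(straight chain:",
      format(sqrt((x$N^2 - 1) / 12), digits = 4), "model units)\n")
  invisible(x)
}

#' @export
plot.geofold_run <- function(x, which = c("rg", "degree"), ...) {
  which <- match.arg(which)
  if (which == "degree") {
    dd <- degree_distribution(x$network)
    graphics::barplot(dd$p, names.arg = dd$k, xlab = "k", ylab = "P(k)", ...)
  } else {
    pos <- x$chain$positions
    graphics::plot(pos[, 1], pos[, 2], asp = 1, xlab = "x", ylab = "y",
                   main = paste0("final aggregate (N = ", x$N, "), xy projection"),
                   ...)
    graphics::lines(pos[, 1], pos[, 2], col = "grey60")
  }
  invisible(x)
}

#' Export a folding trace as CSV
#'
#' Columns `attempt_index,i,j,outcome,l` with 0-based node ids, matching
#' the edge-list convention.
#'
#' @param run a [run_folding()] result with a recorded trace.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace <- function(run, file) {
  stopifnot(inherits(run, "geofold_run"))
  if (is.null(run$trace)) stop("run was executed with trace = FALSE")
  tr <- run$trace
  df <- data.frame(attempt_index = seq_len(nrow(tr)) - 1L,
                   i = tr$i - 1L, j = tr$j - 1L,
                   outcome = ifelse(tr$success, "success", "fail"),
                   l = tr$l)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# deterministic per-run seed from a base seed (kept below 2^31)
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

#' Run an ensemble of folding simulations
#'
#' Repeats [run_folding()] for each chain length in `N_values`, `reps`
#' times, with per-run seeds derived deterministically from `params$seed`.
#' Per run the table records the observables used by the scaling analyses.
#'
#' @param N_values integer vector of chain lengths.
#' @param reps number of realizations per chain length (>= 1).
#' @param params a [folding_params()]; its `seed` is the ensemble base seed.
#' @param verbose print one progress line per run to stderr.
#' @return A data frame with one row per run and columns `N`, `rep`,
#'   `seed`, `edges`, `mean_degree`, `diameter`, `rg` (model units),
#'   `lambda2` (second-largest Laplacian eigenvalue) and `fiedler`.
#' @export
run_ensemble <- function(N_values, reps, params = folding_params(),
                         verbose = FALSE) {
  N_values <- as.integer(N_values)
  if (any(is.na(N_values)) || any(N_values < 2L)) stop("all N must be >= 2")
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("'reps' must be >= 1")
  grid <- expand.grid(rep = seq_len(reps), N = N_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    N <- grid$N[k]; rp <- grid$rep[k]
    sd <- derive_seed(params$seed, k)
    pr <- params; pr$seed <- sd
    run <- run_folding(N, pr, trace = FALSE)
    spec <- laplacian_spectrum(run$network)
    if (verbose)
      message(sprintf("geofold: N = %d rep = %d seed = %d edges = %d",
                      N, rp, sd, nrow(run$network$edges)))
    data.frame(N = N, rep = rp, seed = sd,
               edges = nrow(run$network$edges),
               mean_degree = average_degree(run$network),
               diameter = graph_diameter(run$network),
               rg = radius_of_gyration(run$chain),
               lambda2 = spec$second_largest,
               fiedler = spec$fiedler)
  })
  do.call(rbind, rows)
}

#' Logarithmically spaced chain lengths
#'
#' Helper for ensemble grids: `n` unique integer lengths spaced evenly in
#' log between `from` and `to`.
#'
#' @param from,to range of chain lengths.
#' @param n number of grid points before uniqueness.
#' @return Integer vector (may be shorter than `n` after rounding).
#' @export
log_spaced_lengths <- function(from = 3, to = 398, n = 48) {
  unique(round(exp(seq(log(from), log(to), length.out = n))))
}
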