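#' Degree distribution
#'
#' Empirical distribution of node degrees, `P(k)`.
#'
#' @param net a [contact_network()].
#' @return A data frame with columns `k` (degree) and `p` (probability);
#'   probabilities sum to 1.
#' @export
degree_distribution <- function(net) {
  deg <- node_degrees(net)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), p = as.numeric(tab) / net$n_nodes)
}

#' Average node degree
#'
#' Equals `2 * edges / n_nodes`. For final model aggregates this saturates
#' around 6.8 for chain lengths in the hundreds, the value to which the
#' PRN cutoff of 6.5 Angstrom is calibrated.
#'
#' @param net a [contact_network()].
#' @return Mean degree (numeric scalar).
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  2 * nrow(net$edges) / net$n_nodes
}

#' Graph diameter
#'
#' Maximum over node pairs of the shortest-path length, counted in links.
#'
#' @param net a [contact_network()].
#' @return Integer diameter.
#' @export
graph_diameter <- function(net) {
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop("diameter undefined: network has ", comp$no,
         " connected components (sizes ", paste(comp$csize, collapse = ", "), ")")
  }
  as.integer(igraph::diameter(g, directed = FALSE, weights = NA))
}

#' Radius of gyration
#'
#' Root-mean-square distance of the units from their center of mass:
#' `R_g = sqrt(mean(|x_i - x_bar|^2))`, in the units of the coordinates.
#'
#' @param chain a [bead_chain()], [residue_trace] or coordinate matrix.
#' @return Numeric scalar (0 for a single point).
#' @export
radius_of_gyration <- function(chain) {
  pos <- if (is.matrix(chain) || is.data.frame(chain)) {
    m <- as.matrix(chain); storage.mode(m) <- "double"; m
  } else coords_of(chain)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums((pos - rep(ctr, each = nrow(pos)))^2)))
}

#' Graph-Laplacian spectrum
#'
#' Eigenvalues of the combinatorial Laplacian `L = diag(k) - A`, sorted
#' ascending. `second_largest` is the eigenvalue at descending rank 2 (the
#' quantity whose saturation near 15 is tracked for large aggregates);
#' the Fiedler value (smallest nonzero eigenvalue, governing the slowest
#' relaxation mode) is exposed separately because the two differ for a
#' Laplacian.
#'
#' @param net a [contact_network()] with at least 2 nodes.
#' @return An object of class `laplacian_spectrum`: list with `values`
#'   (ascending), `second_largest`, `fiedler` and `n`.
#' @export
laplacian_spectrum <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  if (net$n_nodes < 2L) stop("need at least 2 nodes")
  A <- adjacency_matrix(net)
  L <- diag(node_degrees(net)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev[abs(ev) < 1e-9] <- pmax(ev[abs(ev) < 1e-9], 0)
  nz <- ev[ev > 1e-9]
  structure(
    list(values = ev,
         second_largest = ev[length(ev) - 1L],
         fiedler = if (length(nz)) nz[1] else 0,
         n = net$n_nodes),
    class = "laplacian_spectrum")
}

#' @export
print.laplacian_spectrum <- function(x, ...) {
  cat("Laplacian spectrum of", x$n, "nodes\n")
  cat("  range [", format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]  second largest:",
      format(x$second_largest, digits = 4), "  Fiedler:",
      format(x$fiedler, digits = 4), "\n")
  invisible(x)
}

#' Pooled eigenvalue histogram
#'
#' Pools all eigenvalues of one or more spectra into a histogram `P(EV)`
#' with fixed-width bins `[k*w, (k+1)*w)` and reports the center of the
#' maximal bin (ties broken toward smaller eigenvalue).
#'
#' @param spectra a `laplacian_spectrum` or list of them (numeric vectors
#'   also accepted).
#' @param bin_width positive bin width (default 0.5).
#' @return An object of class `spectrum_histogram`: list with `mids`
#'   (bin centers), `p` (probabilities summing to 1), `bin_width`,
#'   `peak` (center of the maximal bin) and `n_values`.
#' @export
spectrum_histogram <- function(spectra, bin_width = 0.5) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a positive number")
  if (inherits(spectra, "laplacian_spectrum")) spectra <- list(spectra)
  if (is.numeric(spectra)) spectra <- list(spectra)
  if (length(spectra) < 1L) stop("need at least one spectrum")
  vals <- unlist(lapply(spectra, function(s)
    if (inherits(s, "laplacian_spectrum")) s$values else as.numeric(s)))
  idx <- floor(vals / bin_width)  # right-open bins [k*w, (k+1)*w)
  tab <- table(idx)
  p <- as.numeric(tab) / length(vals)
  mids <- (as.numeric(names(tab)) + 0.5) * bin_width
  peak <- mids[which.max(p)]  # which.max takes the first (smallest) maximal bin
  structure(list(mids = mids, p = p, bin_width = bin_width,
                 peak = peak, n_values = length(vals)),
            class = "spectrum_histogram")
}

#' @export
print.spectrum_histogram <- function(x, ...) {
  cat("Pooled eigenvalue histogram:", x$n_values, "values, bin width",
      x$bin_width, "\n  peak bin center:", format(x$peak, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.spectrum_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$p, type = "h", lwd = 3,
                 xlab = expression(lambda), ylab = "P(EV)", ...)
  graphics::abline(v = x$peak, lty = 2, col = "grey50")
  invisible(x)
}
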