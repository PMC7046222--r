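#' Chain of spheres
#'
#' A `bead_chain` holds the positions and radii of `N` spheres together with
#' their backbone order (the row order of `positions`). Coordinates are in
#' model units (unit mean diameter) or in Angstrom when built from PDB
#' coordinates; `unit_scale` records the physical length of one model unit
#' (set it to the mean PRN link length, 5.066 Angstrom, when comparing model
#' aggregates to residue networks).
#'
#' @param positions numeric matrix with one row per bead and 3 columns.
#' @param radii numeric vector of sphere radii, one per bead (default 0.5
#'   each, i.e. unit diameter).
#' @param unit_scale physical length per model unit (default 1).
#' @param validate check the excluded-volume invariant (default `TRUE`).
#' @param tol_overlap relative overlap tolerated by validation.
#' @return An object of class `bead_chain` with elements `positions`,
#'   `radii`, `n` and `unit_scale`.
#' @seealso [make_straight_chain()], [violates_exclusion()],
#'   [radius_of_gyration()]
#' @export
bead_chain <- function(positions, radii = NULL, unit_scale = 1,
                       validate = TRUE, tol_overlap = 1e-3) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns")
  n <- nrow(positions)
  if (n < 2L) stop("a bead chain needs at least 2 beads")
  if (!all(is.finite(positions))) stop("'positions' must be finite")
  if (is.null(radii)) radii <- rep(0.5, n)
  radii <- as.numeric(radii)
  if (length(radii) != n) stop("'radii' must have one entry per bead")
  if (any(!is.finite(radii)) || any(radii <= 0)) stop("all radii must be positive")
  obj <- structure(
    list(positions = unname(positions), radii = radii, n = n,
         unit_scale = as.numeric(unit_scale)),
    class = "bead_chain")
  if (validate) {
    v <- violates_exclusion(obj, tol_overlap = tol_overlap)
    if (v$violated) {
      stop("excluded volume violated for ", nrow(v$pairs), " pair(s), e.g. (",
           v$pairs[1, 1], ", ", v$pairs[1, 2], ")")
    }
  }
  obj
}

#' @export
print.bead_chain <- function(x, ...) {
  cat("Bead chain with", x$n, "spheres\n")
  cat("  mean diameter:", format(mean(2 * x$radii), digits = 4),
      " unit_scale:", format(x$unit_scale, digits = 4), "\n")
  cat("  radius of gyration:", format(radius_of_gyration(x), digits = 4),
      "(model units)\n")
  invisible(x)
}

#' Straight initial chain
#'
#' Builds the simulator's initial state: a collinear chain of `N` touching
#' spheres along the x axis. With heterogeneity `a > 0`, sphere diameters
#' are drawn uniformly from `[1 - a, 1 + a]` (mean diameter 1) and
#' consecutive beads still touch, so bond lengths equal the sums of the
#' adjacent radii; with `a = 0` every bond has unit length.
#'
#' @param N integer chain length, at least 2.
#' @param a diameter heterogeneity in `[0, 0.5]`.
#' @param seed integer seed for the radii draw (ignored when `a = 0`).
#' @return A [bead_chain()].
#' @examples
#' make_straight_chain(5)
#' make_straight_chain(10, a = 0.3, seed = 1)
#' @export
make_straight_chain <- function(N, a = 0, seed = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2")
  if (!is.numeric(a) || length(a) != 1L || a < 0 || a > 0.5)
    stop("'a' must lie in [0, 0.5]")
  radii <- if (a > 0) {
    with_seed(seed, runif(N, 1 - a, 1 + a)) / 2
  } else {
    rep(0.5, N)
  }
  x <- c(0, cumsum(radii[-N] + radii[-1]))
  bead_chain(cbind(x, 0, 0), radii = radii)
}

#' Pairwise Euclidean distances
#'
#' @param chain a [bead_chain()] or a numeric matrix of coordinates.
#' @return A symmetric `N x N` matrix of Euclidean distances with zero
#'   diagonal.
#' @export
pairwise_distances <- function(chain) {
  pos <- coords_of(chain)
  as.matrix(dist(pos))
}

# accept bead_chain, residue_trace or bare coordinate matrix
coords_of <- function(x) {
  if (inherits(x, "bead_chain")) return(x$positions)
  if (inherits(x, "residue_trace")) return(x$coordinates)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("coordinates must have 3 columns")
  storage.mode(m) <- "double"
  unname(m)
}

#' Check excluded volume
#'
#' Tests whether any two spheres interpenetrate beyond tolerance: pair
#' `(i, j)` offends when `d_ij < (r_i + r_j) * (1 - tol_overlap)`.
#'
#' @param chain a [bead_chain()].
#' @param tol_overlap relative overlap tolerance (>= 0).
#' @return A list with `violated` (logical) and `pairs` (two-column integer
#'   matrix of offending pairs, zero rows when none).
#' @export
violates_exclusion <- function(chain, tol_overlap = 1e-3) {
  if (!inherits(chain, "bead_chain")) stop("'chain' must be a bead_chain")
  if (tol_overlap < 0) stop("'tol_overlap' must be >= 0")
  d <- pairwise_distances(chain)
  lim <- outer(chain$radii, chain$radii, "+") * (1 - tol_overlap)
  bad <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  dimnames(bad) <- list(NULL, c("i", "j"))
  list(violated = nrow(bad) > 0L, pairs = bad)
}

#' Write / read bead coordinates in XYZ format
#'
#' Plain XYZ: first line the number of beads, second a comment, then one
#' `C x y z` line per bead in backbone order. Radii and `unit_scale` are
#' stored on the comment line so that the round trip is lossless.
#'
#' @param chain a [bead_chain()].
#' @param file path to write to / read from.
#' @param comment optional comment (prepended to the stored metadata).
#' @return `write_xyz` returns `file` invisibly; `read_xyz` returns a
#'   [bead_chain()].
#' @export
write_xyz <- function(chain, file, comment = "geofold") {
  if (!inherits(chain, "bead_chain")) stop("'chain' must be a bead_chain")
  meta <- sprintf("%s | unit_scale=%.17g | radii=%s", comment, chain$unit_scale,
                  paste(sprintf("%.17g", chain$radii), collapse = ","))
  lines <- c(as.character(chain$n), meta,
             sprintf("C %.17g %.17g %.17g",
                     chain$positions[, 1], chain$positions[, 2], chain$positions[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2L) stop("malformed XYZ file: ", file)
  meta <- lines[2]
  fields <- strsplit(lines[3:(n + 2)], "[[:space:]]+")
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  radii <- NULL
  unit_scale <- 1
  if (grepl("radii=", meta)) {
    radii <- as.numeric(strsplit(sub(".*radii=", "", meta), ",")[[1]])
  }
  if (grepl("unit_scale=", meta)) {
    unit_scale <- as.numeric(sub(" \\|.*", "", sub(".*unit_scale=", "", meta)))
  }
  bead_chain(pos, radii = radii, unit_scale = unit_scale, validate = FALSE)
}
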