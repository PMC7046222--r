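#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one coordinate per residue from the `CA` ATOM records of a
#' standard PDB file, in file order: first model only, and for alternate
#' locations only the highest-occupancy one (ties go to the first record).
#' Multi-chain files are concatenated in file order with a warning.
#' Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param file path to a PDB file, or a character string/vector of PDB
#'   content (detected by the presence of newlines or multiple elements).
#' @param source_label label stored on the trace (defaults to the file
#'   name).
#' @return An object of class `residue_trace`: list with `coordinates`
#'   (N x 3 matrix, Angstrom), `chain` and `resno` identifiers and
#'   `source_label`.
#' @export
read_calpha <- function(file, source_label = NULL) {
  txt_input <- length(file) > 1L || grepl("\n", file[1], fixed = TRUE)
  if (txt_input) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    if (is.null(source_label)) source_label <- "inline"
  } else {
    path <- file
    if (!file.exists(path)) stop("no such PDB file: ", path)
    if (is.null(source_label)) source_label <- basename(path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", source_label,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no CA ATOM records in '", source_label, "'")
  # highest-occupancy alternate location per residue, file order preserved
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keep <- rep(TRUE, nrow(at))
  if (anyDuplicated(key)) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) > 1L)
    warning("'", source_label, "' has ", length(chains),
            " chains; concatenating in file order")
  coords <- cbind(at$x, at$y, at$z)
  if (!all(is.finite(coords))) stop("non-finite CA coordinates in '", source_label, "'")
  if (nrow(coords) < 2L) stop("fewer than 2 residues in '", source_label, "'")
  structure(list(coordinates = unname(coords), chain = at$chain,
                 resno = at$resno, source_label = source_label),
            class = "residue_trace")
}

#' Construct a residue trace from raw coordinates
#'
#' @param coordinates N x 3 matrix of C-alpha coordinates in Angstrom.
#' @param source_label text label.
#' @return A `residue_trace`.
#' @export
residue_trace <- function(coordinates, source_label = "synthetic") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L) stop("'coordinates' must have 3 columns")
  if (nrow(coordinates) < 2L) stop("need at least 2 residues")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  structure(list(coordinates = unname(coordinates),
                 chain = rep("A", nrow(coordinates)),
                 resno = seq_len(nrow(coordinates)),
                 source_label = source_label),
            class = "residue_trace")
}

#' @export
print.residue_trace <- function(x, ...) {
  cat("Residue trace '", x$source_label, "': ", nrow(x$coordinates),
      " C-alpha coordinates\n", sep = "")
  invisible(x)
}

#' Build a protein residue network
#'
#' Distance-threshold graph on C-alpha (or bead) coordinates: nodes `i` and
#' `j` are connected iff `0 < d_ij <= d_c`. The default cutoff of 6.5
#' Angstrom calibrates the PRN mean degree to that of large simulated
#' aggregates; cutoffs between 4 (peptide-bond length) and 8 Angstrom
#' (upper bound for significant interaction) are conventional.
#'
#' @param trace a `residue_trace`, [bead_chain()] or coordinate matrix.
#' @param d_c positive distance cutoff, Angstrom (default 6.5).
#' @return A [contact_network()].
#' @examples
#' tr <- residue_trace(cbind(c(0, 5, 10), 0, 0))
#' build_prn(tr)          # path: edges (1,2), (2,3)
#' build_prn(tr, d_c = 12)  # adds (1,3)
#' @export
build_prn <- function(trace, d_c = 6.5) {
  if (!is.numeric(d_c) || length(d_c) != 1L || d_c <= 0)
    stop("'d_c' must be a positive cutoff in Angstrom")
  pos <- if (is.matrix(trace) || is.data.frame(trace)) {
    m <- as.matrix(trace); storage.mode(m) <- "double"; m
  } else coords_of(trace)
  n <- nrow(pos)
  if (n < 2L) stop("need at least 2 residues to build a network")
  d <- as.matrix(dist(pos))
  sel <- which(d <= d_c & d > 0 & upper.tri(d), arr.ind = TRUE)
  contact_network(n, sel)
}

#' Mean link length of a network
#'
#' Arithmetic mean of the Euclidean distances spanned by the network's
#' edges. For the reference protein ensemble at a 6.5 Angstrom cutoff this
#' is about 5.066 Angstrom, the length substituted for the model unit when
#' comparing simulated aggregates with residue networks.
#'
#' @param trace coordinates the network was built from.
#' @param net the [contact_network()].
#' @return Mean edge length (same units as the coordinates).
#' @export
mean_link_length <- function(trace, net) {
  stopifnot(inherits(net, "contact_network"))
  pos <- if (is.matrix(trace) || is.data.frame(trace)) {
    m <- as.matrix(trace); storage.mode(m) <- "double"; m
  } else coords_of(trace)
  if (nrow(pos) != net$n_nodes) stop("network and trace sizes differ")
  if (nrow(net$edges) == 0L) stop("mean link length undefined: network has no edges")
  d <- sqrt(rowSums((pos[net$edges[, 1], , drop = FALSE] -
                     pos[net$edges[, 2], , drop = FALSE])^2))
  mean(d)
}
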