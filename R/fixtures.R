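#' Deterministic toy PDB fixtures
#'
#' Generates minimal, valid PDB text with CA ATOM records at analytically
#' known coordinates, for tests and demos of the PRN builder.
#'
#' * `collinear`: `n` residues on the x axis at multiples of `spacing`.
#' * `square`: the 4 corners of a square of side `spacing` (`n` must be 4).
#' * `helix-like`: a regular helix with 100 degrees rotation and constant
#'   rise per residue, scaled so consecutive residues are `spacing` apart.
#' * `random-coil`: a seeded self-avoiding walk with step `spacing`; new
#'   residues keep at least `0.9 * spacing` from all previous ones.
#'
#' @param kind one of `"collinear"`, `"square"`, `"helix-like"`,
#'   `"random-coil"`.
#' @param n number of residues (>= 2).
#' @param spacing consecutive C-alpha distance, Angstrom (> 0).
#' @param seed integer seed (used by `random-coil`).
#' @param file optional path; when given the text is also written there.
#' @return PDB-format text as a single character scalar (invisibly the
#'   file path when `file` is given).
#' @examples
#' txt <- generate_toy_pdb("collinear", n = 3, spacing = 5)
#' read_calpha(txt)
#' @export
generate_toy_pdb <- function(kind = c("collinear", "square", "helix-like",
                                      "random-coil"),
                             n = 4L, spacing = 5, seed = 1L, file = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  xyz <- switch(kind,
    collinear = cbind((seq_len(n) - 1) * spacing, 0, 0),
    square = {
      if (n != 4L) stop("'square' requires n = 4")
      spacing * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
    },
    `helix-like` = {
      theta <- (seq_len(n) - 1) * 100 * pi / 180
      rise <- 1.5; rad <- 2.3
      step <- sqrt(rise^2 + (2 * rad * sin(50 * pi / 180))^2)
      s <- spacing / step
      cbind(s * rad * cos(theta), s * rad * sin(theta), s * rise * (seq_len(n) - 1))
    },
    `random-coil` = with_seed(seed, {
      pos <- matrix(0, n, 3)
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:1000) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- pos[i - 1, ] + spacing * u
          prev <- pos[seq_len(i - 2), , drop = FALSE]
          if (nrow(prev) == 0L ||
              min(sqrt(rowSums((prev - rep(cand, each = nrow(prev)))^2))) >
                0.9 * spacing) {
            pos[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("self-avoiding walk failed to place residue ", i)
      }
      pos
    }))
  rec <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3])
  txt <- paste(c(rec, "TER", "END", ""), collapse = "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(file))
  }
  txt
}

#' Random synthetic residue traces
#'
#' Short random C-alpha-like traces with consecutive spacing `spacing`
#' (a free random walk, no self-avoidance), used as test inputs with
#' known pairwise distances.
#'
#' @param n number of residues.
#' @param spacing consecutive spacing in Angstrom.
#' @param seed integer seed.
#' @return A [residue_trace()].
#' @export
random_trace <- function(n, spacing = 3.8, seed = 1L) {
  pos <- with_seed(seed, {
    steps <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * spacing
    rbind(0, apply(steps, 2, cumsum))
  })
  if (n == 2L) pos <- matrix(pos, 2, 3)
  residue_trace(pos, source_label = sprintf("random_trace(n=%d, seed=%d)", n, seed))
}
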