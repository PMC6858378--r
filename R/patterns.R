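#' Seven-class ASE pattern of a gene across cells
#'
#' Classifies each gene's population-level profile — the proportions of
#' cells in the P, B, and M allelic states, `(pi_g.^P, pi_g.^B, pi_g.^M)`
#' — into one of seven regions of the ternary simplex. If a single state
#' holds a strict majority (`> 0.7`) the gene is assigned that singleton
#' class (`P`, `B`, `M`); otherwise, if a pair of states together exceeds
#' `0.9` the gene is assigned the pair class (`PB`, `BM`, or `MP`);
#' otherwise all three states are represented (`PBM`). Boundary values
#' fall through to the next rule (strict inequalities). At most one pair
#' can exceed 0.9 when no singleton exceeds 0.7, so the assignment is
#' unambiguous.
#'
#' @param pi Simplex triple `(P, B, M)`, or a genes x 3 matrix of them.
#' @param singleton,pair Classification thresholds.
#' @return Factor of labels with levels `P, B, M, PB, BM, MP, PBM`.
#' @export
classify_gene_pattern <- function(pi, singleton = 0.7, pair = 0.9) {
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1)
  stopifnot(ncol(pi) == 3)
  if (any(abs(rowSums(pi) - 1) > 1e-6) || any(pi < -1e-12))
    stop("each row must be a probability triple summing to 1")
  lev <- c("P", "B", "M", "PB", "BM", "MP", "PBM")
  lab <- rep("PBM", nrow(pi))
  pairsum <- cbind(PB = pi[, 1] + pi[, 2],
                   BM = pi[, 2] + pi[, 3],
                   MP = pi[, 3] + pi[, 1])
  best_pair <- c("PB", "BM", "MP")[max.col(pairsum, ties.method = "first")]
  has_pair <- apply(pairsum, 1, max) > pair
  lab[has_pair] <- best_pair[has_pair]
  best_single <- c("P", "B", "M")[max.col(pi, ties.method = "first")]
  has_single <- apply(pi, 1, max) > singleton
  lab[has_single] <- best_single[has_single]
  factor(lab, levels = lev)
}

# equilateral-triangle vertices used for ternary plots: P bottom-left,
# M bottom-right, B apex
.tern_vertices <- matrix(c(0, 0, 0.5, sqrt(3) / 2, 1, 0), ncol = 2,
                         byrow = TRUE, dimnames = list(STATES, c("tx", "ty")))

#' Ternary plot coordinates
#'
#' Maps simplex triples `(P, B, M)` to Cartesian coordinates in an
#' equilateral triangle (P at the origin, M at (1, 0), B at the apex);
#' `simplex_from_ternary` inverts the map.
#'
#' @param pi Simplex triple or genes x 3 matrix.
#' @return Matrix with columns `tx`, `ty`.
#' @export
ternary_coordinates <- function(pi) {
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1)
  stopifnot(ncol(pi) == 3)
  out <- pi %*% .tern_vertices
  colnames(out) <- c("tx", "ty")
  out
}

#' @param xy Matrix with columns `tx`, `ty` (or a length-2 point).
#' @rdname ternary_coordinates
#' @export
simplex_from_ternary <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, nrow = 1)
  b <- xy[, 2] / .tern_vertices["B", "ty"]
  m <- xy[, 1] - 0.5 * b
  cbind(P = 1 - b - m, B = b, M = m)
}

#' Gene-pattern table from a mixture fit
#'
#' Convenience wrapper: takes per-gene state weights (e.g. `params$pi`
#' from [em_fit()] or [mcmc_fit()]) and returns labels plus simplex and
#' ternary coordinates.
#'
#' @param fit A `scase_fit` object, or a genes x 3 weight matrix.
#' @param ... Passed to [classify_gene_pattern()].
#' @return data.frame `gene, label, pi_P, pi_B, pi_M, tx, ty`.
#' @export
gene_patterns <- function(fit, ...) {
  pi <- if (inherits(fit, "scase_fit")) fit$params$pi else as.matrix(fit)
  xy <- ternary_coordinates(pi)
  data.frame(gene = rownames(pi) %||% paste0("g", seq_len(nrow(pi))),
             label = classify_gene_pattern(pi, ...),
             pi_P = pi[, 1], pi_B = pi[, 2], pi_M = pi[, 3],
             tx = xy[, 1], ty = xy[, 2], row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
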