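#' Allele-specific count matrices
#'
#' Container for paired maternal/paternal gene-by-cell count matrices.
#' Counts may be fractional (expected counts from weighted allocation).
#'
#' @param x Maternal counts, genes x cells (matrix or vector).
#' @param y Paternal counts, same shape as `x`.
#' @param genes,cells Optional dimnames; taken from `x` when present.
#'
#' @return An object of class `allele_counts` with matrices `x`, `y` and
#'   `n = x + y`.
#' @export
allele_counts <- function(x, y, genes = NULL, cells = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y)))
    stop("maternal and paternal matrices must have identical dimensions")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (is.null(genes)) genes <- rownames(x)
  if (is.null(cells)) cells <- colnames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(x)))
  dimnames(x) <- dimnames(y) <- list(genes, cells)
  structure(list(x = x, y = y, n = x + y), class = "allele_counts")
}

#' @export
dim.allele_counts <- function(x) dim(x$x)

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d genes x %d cells (%.1f reads total)\n",
              nrow(x$x), ncol(x$x), sum(x$n)))
  invisible(x)
}

#' Maternal allelic proportions from counts
#'
#' `p_hat = x / n` where `n > 0`, `NA` otherwise.
#'
#' @param counts An [allele_counts()] object.
#' @return Matrix of proportions, genes x cells.
#' @export
allelic_proportion <- function(counts) {
  p <- counts$x / counts$n
  p[counts$n == 0] <- NA_real_
  p
}

# single-cell allele_counts from a per-target count vector
counts_from_targets <- function(cnt, targets, cell, genes = NULL) {
  if (is.null(genes)) genes <- unique(targets$gene)
  x <- y <- setNames(numeric(length(genes)), genes)
  im <- targets$allele == "M"
  xm <- tapply(cnt[im], targets$gene[im], sum)
  yp <- tapply(cnt[!im], targets$gene[!im], sum)
  x[names(xm)] <- xm
  y[names(yp)] <- yp
  allele_counts(matrix(x, ncol = 1), matrix(y, ncol = 1),
                genes = genes, cells = cell)
}

#' Unique-reads counting
#'
#' Counts only reads that map to a single (gene, allele) target; all
#' genomic and allelic multi-reads are discarded.
#'
#' @param inc An [alignment_incidence()] object.
#' @param genes Optional character vector fixing the gene universe (and
#'   row order) of the result.
#' @return A one-column [allele_counts()] object with integer counts.
#' @export
unique_read_counts <- function(inc, genes = NULL) {
  m <- inc$membership
  uniq <- Matrix::rowSums(m) == 1
  cnt <- Matrix::colSums(m[uniq, , drop = FALSE])
  counts_from_targets(cnt, inc$targets, inc$cell, genes)
}

#' EM weighted allocation of multi-mapping reads
#'
#' Fractionally assigns each read across its alignment target set in
#' proportion to the current estimate of allele-specific expression, then
#' re-estimates expression as the per-target sum of weights, iterating to
#' a fixed point. Weights are initialised uniformly over each read's
#' target set. The total read count is conserved at every iteration. A
#' target whose count reaches exactly zero keeps weight zero (absorbing
#' state of the EM).
#'
#' @param inc An [alignment_incidence()] object.
#' @param tol Convergence tolerance: maximum absolute change in any target
#'   count, in reads.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @param genes Optional gene universe for the output matrix.
#' @param length_weights Optional per-target positive weights (an
#'   effective-length hook); default 1 for every target, i.e. equal
#'   effective lengths.
#'
#' @return A one-column [allele_counts()] object with attributes
#'   `converged`, `iterations`, `loglik` (multinomial log-likelihood
#'   trace), and `p_hat` (maternal proportion per gene where `n > 0`).
#' @export
weighted_allocation_em <- function(inc, tol = 1e-6, max_iter = 1000L,
                                   genes = NULL, length_weights = NULL) {
  stopifnot(tol > 0)
  m <- inc$membership
  n_reads <- nrow(m)
  if (n_reads < 1) stop("weighted_allocation_em requires at least one read")
  lw <- if (is.null(length_weights)) rep(1, ncol(m)) else length_weights
  if (any(lw <= 0)) stop("length_weights must be positive")
  rs <- Matrix::rowSums(m)
  cnt <- as.vector(Matrix::crossprod(m, 1 / rs))   # uniform initial weights
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- cnt / lw
    s <- as.vector(m %*% theta)                    # per-read normaliser
    zero <- s <= 0
    ll <- sum(log(s[!zero] / sum(theta))) + sum(zero) * log(1e-300)
    loglik <- c(loglik, ll)
    newcnt <- theta * as.vector(Matrix::crossprod(m[!zero, , drop = FALSE],
                                                  1 / s[!zero]))
    if (any(zero))                                  # dead rows: keep uniform
      newcnt <- newcnt + as.vector(Matrix::crossprod(m[zero, , drop = FALSE],
                                                     1 / rs[zero]))
    if (max(abs(newcnt - cnt)) < tol) {
      cnt <- newcnt
      converged <- TRUE
      break
    }
    cnt <- newcnt
  }
  out <- counts_from_targets(cnt, inc$targets, inc$cell, genes)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "loglik") <- loglik
  attr(out, "p_hat") <- allelic_proportion(out)
  out
}

#' Count a set of single-cell incidences into one matrix
#'
#' Applies unique-reads or weighted-allocation counting to each cell's
#' incidence and binds the columns into a gene-by-cell [allele_counts()]
#' object over the union of genes.
#'
#' @param incs List of [alignment_incidence()] objects (one per cell).
#' @param mode `"unique"` or `"weighted"`.
#' @param ... Passed to [weighted_allocation_em()].
#' @return An [allele_counts()] object.
#' @export
count_cells <- function(incs, mode = c("unique", "weighted"), ...) {
  mode <- match.arg(mode)
  genes <- sort(unique(unlist(lapply(incs, function(i) i$targets$gene))))
  cols <- lapply(incs, function(inc) {
    if (mode == "unique") unique_read_counts(inc, genes = genes)
    else weighted_allocation_em(inc, genes = genes, ...)
  })
  cells <- vapply(incs, function(i) i$cell, "")
  if (anyDuplicated(cells)) cells <- make.unique(cells)
  allele_counts(do.call(cbind, lapply(cols, function(co) co$x)),
                do.call(cbind, lapply(cols, function(co) co$y)),
                genes = genes, cells = cells)
}
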