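#' Down-sample reads or counts
#'
#' Thins data to a fraction `rate`. On an [alignment_incidence()] every
#' read is retained independently with probability `rate`; on an
#' [allele_counts()] object each maternal/paternal count is binomially
#' thinned (the integer part binomially, any fractional remainder as a
#' Bernoulli trial, so the expectation is exactly `rate` times the
#' input). The two operations are approximations of one another: read
#' thinning also shrinks multi-read ambiguity jointly, count thinning
#' acts on the already-resolved counts.
#'
#' @param x Object to thin.
#' @param rate Retention probability in (0, 1].
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @export
downsample <- function(x, rate, seed = NULL, ...) {
  stopifnot(rate > 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  UseMethod("downsample")
}

#' @export
downsample.alignment_incidence <- function(x, rate, seed = NULL, ...) {
  if (rate == 1) return(x)
  keep <- runif(nrow(x$membership)) < rate
  m <- x$membership[keep, , drop = FALSE]
  used <- Matrix::colSums(m) > 0
  alignment_incidence(m[, used, drop = FALSE],
                      genes = x$targets$gene[used],
                      alleles = x$targets$allele[used],
                      reads = x$reads[keep], cell = x$cell)
}

#' @export
downsample.allele_counts <- function(x, rate, seed = NULL, ...) {
  if (rate == 1) return(x)
  thin <- function(m) {
    base <- floor(m)
    frac <- m - base
    out <- rbinom(length(m), base, rate) +
      (runif(length(m)) < rate * frac)
    matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  allele_counts(thin(x$x), thin(x$y))
}

#' Per-gene mean squared error of allelic proportions
#'
#' Mean over cells of `(p_ref - p_est)^2`, restricted to entries selected
#' by `mask` (by default, entries where both proportions are defined —
#' cells with zero coverage in either matrix drop out). Genes with no
#' usable cell get `NA`.
#'
#' @param p_ref,p_est Genes x cells proportion matrices.
#' @param mask Optional logical matrix selecting entries to compare.
#' @return Named per-gene MSE vector.
#' @export
allelic_mse <- function(p_ref, p_est, mask = NULL) {
  stopifnot(identical(dim(p_ref), dim(p_est)))
  if (is.null(mask)) mask <- is.finite(p_ref) & is.finite(p_est)
  se <- (p_ref - p_est)^2
  se[!mask] <- NA_real_
  out <- rowMeans(se, na.rm = TRUE)
  out[rowSums(mask) == 0] <- NA_real_
  out
}

#' MSE difference before minus after partial pooling
#'
#' @param mse_before,mse_after Per-gene MSE vectors on the same gene set
#'   (e.g. no-pooling vs partial-pooling estimates against the same
#'   reference).
#' @return List with per-gene `difference` (positive means pooling
#'   improved the estimate), `mean_difference`, and the counts of genes
#'   improved/worsened.
#' @export
mse_difference <- function(mse_before, mse_after) {
  stopifnot(length(mse_before) == length(mse_after))
  d <- mse_before - mse_after
  list(difference = d,
       mean_difference = mean(d, na.rm = TRUE),
       n_improved = sum(d > 0, na.rm = TRUE),
       n_worsened = sum(d < 0, na.rm = TRUE))
}
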