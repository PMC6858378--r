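#' Read and write paired allele-specific count matrices
#'
#' Two on-disk layouts are supported. `"tsv"`: two tab-separated files
#' (`<prefix>.maternal.tsv`, `<prefix>.paternal.tsv`), genes as rows with
#' a `gene_id` first column, cells as columns, `NA` for missing.
#' `"mtx"`: a MatrixMarket triple per allele
#' (`<prefix>.maternal.mtx` / `.paternal.mtx`) with shared sidecar name
#' files `<prefix>.genes.txt` and `<prefix>.cells.txt`.
#'
#' @param counts An [allele_counts()] object.
#' @param prefix Path prefix for the file set.
#' @param format `"tsv"` or `"mtx"`.
#' @param header Optional comment lines written atop TSV outputs (each
#'   prefixed `# `).
#' @return `write_counts` returns `prefix` invisibly; `read_counts`
#'   returns an [allele_counts()] object.
#' @export
write_counts <- function(counts, prefix, format = c("tsv", "mtx"),
                         header = character()) {
  format <- match.arg(format)
  if (format == "tsv") {
    for (side in c("maternal", "paternal")) {
      m <- if (side == "maternal") counts$x else counts$y
      path <- paste0(prefix, ".", side, ".tsv")
      con <- file(path, "w")
      if (length(header)) writeLines(paste("#", header), con)
      df <- data.frame(gene_id = rownames(m),
                       signif(m, 6), check.names = FALSE)
      suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                   row.names = FALSE, na = "NA"))
      close(con)
    }
  } else {
    Matrix::writeMM(as(counts$x, "CsparseMatrix"),
                    paste0(prefix, ".maternal.mtx"))
    Matrix::writeMM(as(counts$y, "CsparseMatrix"),
                    paste0(prefix, ".paternal.mtx"))
    writeLines(rownames(counts$x), paste0(prefix, ".genes.txt"))
    writeLines(colnames(counts$x), paste0(prefix, ".cells.txt"))
  }
  invisible(prefix)
}

#' @rdname write_counts
#' @export
read_counts <- function(prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rd <- function(side) {
      df <- read.delim(paste0(prefix, ".", side, ".tsv"),
                       comment.char = "#", check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$gene_id
      m
    }
    x <- rd("maternal"); y <- rd("paternal")
  } else {
    x <- as.matrix(Matrix::readMM(paste0(prefix, ".maternal.mtx")))
    y <- as.matrix(Matrix::readMM(paste0(prefix, ".paternal.mtx")))
    genes <- readLines(paste0(prefix, ".genes.txt"))
    cells <- readLines(paste0(prefix, ".cells.txt"))
    dimnames(x) <- dimnames(y) <- list(genes, cells)
  }
  if (!identical(dim(x), dim(y)))
    stop("maternal and paternal matrices at '", prefix,
         "' have inconsistent dimensions")
  allele_counts(x, y)
}

#' Long-format table of per-cell fit results
#'
#' @param fit A `scase_fit` object.
#' @return data.frame `gene, cell, pi_P, pi_B, pi_M, p_hat, p_tilde`
#'   (plus `p_sd` for MCMC fits).
#' @export
fit_table <- function(fit) {
  w <- unclass(fit$probs)
  g <- dim(w)[1]; k <- dim(w)[2]
  genes <- dimnames(w)[[1]] %||% paste0("g", seq_len(g))
  cells <- dimnames(w)[[2]] %||% paste0("cell", seq_len(k))
  out <- data.frame(gene = rep(genes, k),
                    cell = rep(cells, each = g),
                    pi_P = as.vector(matrix(w[, , 1], g, k)),
                    pi_B = as.vector(matrix(w[, , 2], g, k)),
                    pi_M = as.vector(matrix(w[, , 3], g, k)),
                    p_hat = as.vector(fit$estimates$p_hat),
                    p_tilde = as.vector(fit$estimates$p_tilde))
  if (!is.null(fit$estimates$p_sd))
    out$p_sd <- as.vector(fit$estimates$p_sd)
  out
}

#' Per-gene table of mixture parameters
#'
#' @param fit A `scase_fit` object.
#' @return data.frame of gene-level weights and beta shapes.
#' @export
gene_param_table <- function(fit) {
  p <- fit$params
  data.frame(gene = rownames(p$pi) %||% paste0("g", seq_len(nrow(p$pi))),
             pi_gdot_P = p$pi[, 1], pi_gdot_B = p$pi[, 2],
             pi_gdot_M = p$pi[, 3],
             alpha_P = p$alpha[, 1], beta_P = p$beta[, 1],
             alpha_B = p$alpha[, 2], beta_B = p$beta[, 2],
             alpha_M = p$alpha[, 3], beta_M = p$beta[, 3],
             low_information = fit$low_information,
             row.names = NULL)
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value` (or `key value`); `#` starts a
#' comment. Values are returned as character and coerced by the caller.
#'
#' @param path File path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)[ =\t]+(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, `[`, "", 2))
}
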