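#' Joint allelic expression-state table for one gene
#'
#' Tallies cells into the 2x2 table of joint maternal/paternal expression
#' states. An allele counts as expressed in a cell when its (possibly
#' fractional) estimated count is strictly greater than `threshold`
#' (default 1 read).
#'
#' @param counts An [allele_counts()] object.
#' @param gene Gene id or row index.
#' @param threshold Expression threshold (reads), `>= 0`.
#' @return An object of class `state_table`: counts `silent`,
#'   `maternal_only`, `paternal_only`, `biallelic`, plus the threshold.
#' @export
expression_state_table <- function(counts, gene, threshold = 1) {
  stopifnot(threshold >= 0)
  if (is.character(gene)) {
    gi <- match(gene, rownames(counts$x))
    if (is.na(gi)) stop("gene '", gene, "' not found")
  } else {
    gi <- gene
    if (gi < 1 || gi > nrow(counts$x)) stop("gene index out of range")
  }
  mat <- counts$x[gi, ] > threshold
  pat <- counts$y[gi, ] > threshold
  state_table(silent = sum(!mat & !pat),
              maternal_only = sum(mat & !pat),
              paternal_only = sum(!mat & pat),
              biallelic = sum(mat & pat),
              threshold = threshold,
              gene = if (is.character(gene)) gene else rownames(counts$x)[gi])
}

#' @param silent,maternal_only,paternal_only,biallelic Cell counts.
#' @param gene Optional gene id carried along.
#' @rdname expression_state_table
#' @export
state_table <- function(silent, maternal_only, paternal_only, biallelic,
                        threshold = 1, gene = NA_character_) {
  cnt <- c(silent = silent, maternal_only = maternal_only,
           paternal_only = paternal_only, biallelic = biallelic)
  if (any(cnt < 0)) stop("state counts must be non-negative")
  structure(list(counts = cnt, threshold = threshold, gene = gene),
            class = "state_table")
}

#' @export
print.state_table <- function(x, ...) {
  cat(sprintf("state_table (%s): silent=%g mat-only=%g pat-only=%g bi=%g (threshold %g)\n",
              x$gene, x$counts[1], x$counts[2], x$counts[3], x$counts[4],
              x$threshold))
  invisible(x)
}

#' Cells with monoallelic expression
#'
#' @param table A [state_table()].
#' @return Number of maternal-only plus paternal-only cells.
#' @export
monoallelic_cells <- function(table) {
  unname(table$counts["maternal_only"] + table$counts["paternal_only"])
}

as_2x2 <- function(table) {
  matrix(table$counts[c("silent", "maternal_only",
                        "paternal_only", "biallelic")],
         2, 2, dimnames = list(paternal = c("off", "on"),
                               maternal = c("off", "on")))
}

#' Log-odds ratio of a 2x2 expression-state table
#'
#' `log((silent * biallelic) / (maternal_only * paternal_only))`: zero
#' when maternal and paternal bursting are independent, positive when
#' bursts are synchronised. The Haldane-Anscombe correction adds 0.5 to
#' every cell; with `correction = "auto"` (default) it is applied exactly
#' when some cell is zero.
#'
#' @param table A [state_table()].
#' @param correction `"auto"`, `"none"`, or `"haldane"`.
#' @return The log-odds ratio; attribute `infinite` flags an uncorrected
#'   zero cell.
#' @export
log_odds_ratio <- function(table, correction = c("auto", "none", "haldane")) {
  correction <- match.arg(correction)
  cnt <- table$counts
  apply_h <- correction == "haldane" ||
    (correction == "auto" && any(cnt == 0))
  if (apply_h) cnt <- cnt + 0.5
  lor <- log(cnt["silent"] * cnt["biallelic"]) -
    log(cnt["maternal_only"] * cnt["paternal_only"])
  structure(unname(lor), infinite = !is.finite(lor))
}

#' Exact test of allelic-bursting independence
#'
#' Two-sided Fisher exact test on the 2x2 expression-state table
#' (`method = "chisq"` gives the chi-square test as an alternative).
#'
#' @param table A [state_table()].
#' @param method `"fisher"` or `"chisq"`.
#' @return P-value.
#' @export
independence_test <- function(table, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  m <- as_2x2(table)
  if (method == "fisher") fisher.test(round(m))$p.value
  else suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
}

#' Benjamini-Hochberg FDR control
#'
#' @param p P-values.
#' @param q Target false discovery rate.
#' @return List with `qvalues` and logical `significant` (q-value below
#'   `q`).
#' @export
bh_fdr <- function(p, q = 0.05) {
  qv <- p.adjust(p, method = "BH")
  list(qvalues = qv, significant = qv < q)
}

#' 4D simplex proportions and the bi-allelic/silent projection
#'
#' Proportions of cells in the four joint allelic states; the projection
#' keeps the bi-allelic and silent proportions, the 2D representation of
#' Deng-style bursting plots.
#'
#' @param table A [state_table()] with at least one cell.
#' @return List with `proportions` (silent, maternal_only, paternal_only,
#'   biallelic; sums to 1) and `projection` (`prop_bi`, `prop_silent`).
#' @export
simplex_coordinates <- function(table) {
  tot <- sum(table$counts)
  if (tot <= 0) stop("empty state table")
  pr <- table$counts / tot
  list(proportions = pr,
       projection = c(prop_bi = unname(pr["biallelic"]),
                      prop_silent = unname(pr["silent"])))
}

#' Per-gene allelic-bursting independence analysis
#'
#' Builds the expression-state table of every gene, computes the log-odds
#' ratio (Haldane-corrected when zeros occur), the Fisher exact p-value,
#' BH q-values, and the simplex projection.
#'
#' @param counts An [allele_counts()] object.
#' @param threshold Expression threshold in reads.
#' @param fdr Target false discovery rate.
#' @param method Test passed to [independence_test()].
#' @return data.frame `gene, n_silent, n_mat, n_pat, n_bi, logOR, pvalue,
#'   qvalue, significant, prop_bi, prop_silent`.
#' @export
independence_analysis <- function(counts, threshold = 1, fdr = 0.05,
                                  method = "fisher") {
  genes <- rownames(counts$x)
  rows <- lapply(seq_along(genes), function(gi) {
    tb <- expression_state_table(counts, gi, threshold)
    sc <- simplex_coordinates(tb)
    data.frame(gene = genes[gi],
               n_silent = tb$counts[["silent"]],
               n_mat = tb$counts[["maternal_only"]],
               n_pat = tb$counts[["paternal_only"]],
               n_bi = tb$counts[["biallelic"]],
               logOR = as.numeric(log_odds_ratio(tb)),
               pvalue = independence_test(tb, method),
               prop_bi = sc$projection[["prop_bi"]],
               prop_silent = sc$projection[["prop_silent"]])
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$pvalue, fdr)
  out$qvalue <- adj$qvalues
  out$significant <- adj$significant
  out[, c("gene", "n_silent", "n_mat", "n_pat", "n_bi", "logOR",
          "pvalue", "qvalue", "significant", "prop_bi", "prop_silent")]
}

#' Simulate expression-state tables under perfect independence
#'
#' For each gene, marginal expression probabilities `p_M` and `p_P` are
#' drawn uniformly on (0, 1) and cells are assigned to the four joint
#' states by a multinomial with probabilities `{p_M p_P, p_M (1 - p_P),
#' (1 - p_M) p_P, (1 - p_M) (1 - p_P)}` for bi-allelic, maternal-only,
#' paternal-only and silent cells — the product form that makes the true
#' log-odds ratio zero.
#'
#' @param n_genes Number of genes (tables).
#' @param n_cells Cells per table.
#' @param seed Integer seed.
#' @return List with `tables` (list of [state_table()]) and the true
#'   `p_M`, `p_P` vectors.
#' @export
simulate_independent_tables <- function(n_genes, n_cells = 122L,
                                        seed = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_M <- runif(n_genes); p_P <- runif(n_genes)
  tables <- lapply(seq_len(n_genes), function(g) {
    pr <- c(p_M[g] * p_P[g], p_M[g] * (1 - p_P[g]),
            (1 - p_M[g]) * p_P[g], (1 - p_M[g]) * (1 - p_P[g]))
    cnt <- as.vector(rmultinom(1, n_cells, pr))
    state_table(silent = cnt[4], maternal_only = cnt[2],
                paternal_only = cnt[3], biallelic = cnt[1],
                gene = paste0("sim", g))
  })
  list(tables = tables, p_M = p_M, p_P = p_P)
}
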