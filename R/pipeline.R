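#' End-to-end estimation pipeline
#'
#' Runs one of the four estimation modes — unique reads, weighted
#' allocation, unique reads with partial pooling, weighted allocation
#' with partial pooling — from alignment inputs (or a pre-made count
#' pair) through counting, mixture fitting, gene patterns, and the
#' independence analysis, writing all result tables under `out_dir`.
#' Output files carry a header recording package version, a hash of the
#' configuration, and the seed, and reruns with the same configuration
#' and seed are reproducible.
#'
#' @param input Either a character vector of alignment files (one cell
#'   each; SAM/BAM or EC-TSV, see [read_alignments()]) or an
#'   [allele_counts()] object.
#' @param out_dir Output directory (created if needed).
#' @param mode `"unique"`, `"weighted"`, `"unique+pool"`, or
#'   `"weighted+pool"`.
#' @param engine `"em"` or `"mcmc"` for the pooling fit.
#' @param seed Integer seed; mandatory when `engine = "mcmc"`.
#' @param threshold Expression threshold for state tables.
#' @param fdr False discovery rate for the independence analysis.
#' @param priors A [prior_spec()].
#' @param ... Extra arguments to [em_fit()] / [mcmc_fit()].
#' @return Invisible list with `counts`, `fit` (or `NULL` without
#'   pooling), `patterns`, `independence`, and the output paths.
#' @export
run_pipeline <- function(input, out_dir,
                         mode = c("weighted+pool", "unique", "weighted",
                                  "unique+pool"),
                         engine = c("em", "mcmc"), seed = 1L,
                         threshold = 1, fdr = 0.05,
                         priors = prior_spec(), ...) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  pooled <- grepl("pool", mode)
  count_mode <- if (startsWith(mode, "unique")) "unique" else "weighted"
  if (engine == "mcmc" && pooled && is.null(seed))
    stop("engine 'mcmc' requires a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (inherits(input, "allele_counts")) {
    counts <- input
  } else {
    incs <- lapply(input, read_alignments)
    counts <- count_cells(incs, mode = count_mode)
  }
  cfg <- list(mode = mode, engine = engine, seed = seed,
              threshold = threshold, fdr = fdr)
  hdr <- c(paste("scase version", as.character(utils::packageVersion("scase"))),
           paste("config", config_hash(cfg)),
           paste("seed", seed))

  fit <- NULL
  if (pooled) {
    fit <- if (engine == "em") em_fit(counts, priors = priors, ...)
    else mcmc_fit(counts, priors = priors, seed = seed, ...)
    est_counts <- allele_counts(fit$estimates$p_tilde * counts$n,
                                (1 - fit$estimates$p_tilde) * counts$n)
    write_tsv_hdr(fit_table(fit), file.path(out_dir, "fit.tsv"), hdr)
    write_tsv_hdr(gene_param_table(fit),
                  file.path(out_dir, "gene_params.tsv"), hdr)
    pat <- gene_patterns(fit)
  } else {
    est_counts <- counts
    p <- allelic_proportion(counts)
    pat <- NULL
  }
  write_counts(est_counts, file.path(out_dir, "counts"), header = hdr)
  if (!is.null(pat))
    write_tsv_hdr(pat, file.path(out_dir, "patterns.tsv"), hdr)
  indep <- independence_analysis(est_counts, threshold = threshold,
                                 fdr = fdr)
  write_tsv_hdr(indep, file.path(out_dir, "independence.tsv"), hdr)
  invisible(list(counts = counts, fit = fit, patterns = pat,
                 independence = indep, out_dir = out_dir))
}

write_tsv_hdr <- function(df, path, header = character()) {
  con <- file(path, "w")
  if (length(header)) writeLines(paste("#", header), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  close(con)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), "")), tmp)
  unname(tools::md5sum(tmp))
}
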