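#' Configuration for the synthetic ASE generator
#'
#' Describes the generative model used to produce ground-truthed
#' gene-by-cell allele-specific counts and read-level incidence. Per gene,
#' state weights are drawn from a Dirichlet; per cell a latent state
#' (P/B/M) is drawn; the maternal proportion comes from the state's beta
#' distribution (constant across cells for the monoallelic states,
#' cell-varying for the bi-allelic state); total counts are
#' negative-binomial with a log-normal gene-level mean (overdispersed
#' coverage); maternal counts are binomial. Reads are single-end, one
#' cell per incidence, as in SMART-seq protocols.
#'
#' @param n_genes,n_cells Dimensions of the simulated matrix.
#' @param dirichlet Dirichlet concentration for the per-gene state
#'   weights `(P, B, M)`.
#' @param state_beta Named list of `c(mean, conc)` for each state's beta
#'   distribution of maternal proportions.
#' @param depth_mean Mean total coverage per gene per cell (reads).
#' @param depth_sdlog Log-normal spread of gene-level mean coverage.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param fixed_n Optional fixed total count for every gene/cell
#'   (overrides the negative-binomial model).
#' @param read_mix Fractions of `unique`, `genomic`, `allelic`, `complex`
#'   reads emitted by [simulate_incidence()]; must sum to 1. The default
#'   is the composition observed in F1-hybrid mouse embryo data (14.9%
#'   unique, 2.5% genomic, 59.3% allelic, 23.3% complex).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L, n_cells = 200L,
                       dirichlet = c(1, 1, 1),
                       state_beta = list(P = c(mean = 0.05, conc = 20),
                                         B = c(mean = 0.5, conc = 8),
                                         M = c(mean = 0.95, conc = 20)),
                       depth_mean = 20, depth_sdlog = 0.7,
                       dispersion = 2, fixed_n = NULL,
                       read_mix = c(unique = 0.149, genomic = 0.025,
                                    allelic = 0.593, complex = 0.233)) {
  stopifnot(n_genes >= 1, n_cells >= 1, all(dirichlet > 0),
            abs(sum(read_mix) - 1) < 1e-6, all(read_mix >= 0),
            all(STATES %in% names(state_beta)))
  for (s in STATES)
    stopifnot(state_beta[[s]]["mean"] > 0, state_beta[[s]]["mean"] < 1,
              state_beta[[s]]["conc"] > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 dirichlet = dirichlet, state_beta = state_beta[STATES],
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 dispersion = dispersion, fixed_n = fixed_n,
                 read_mix = read_mix[c("unique", "genomic",
                                       "allelic", "complex")]),
            class = "sim_config")
}

#' Simulate allele-specific counts with known truth
#'
#' Draws a full realisation of the three-state mixture model described in
#' [sim_config()] and returns both the counts and every latent quantity.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (same seed, same output).
#' @return An object of class `synthetic_truth`: `counts`
#'   ([allele_counts()]), `z` (true states, genes x cells, values 1=P,
#'   2=B, 3=M), `p` (true maternal proportions), `pi` (true state
#'   weights, genes x 3), `shape` (true per-state `(alpha, beta)`),
#'   `config`.
#' @export
simulate_counts <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- config$n_genes; k <- config$n_cells
  genes <- sprintf("g%03d", seq_len(g))
  cells <- sprintf("cell%03d", seq_len(k))
  pi <- t(vapply(seq_len(g), function(i) rdirichlet1(config$dirichlet),
                 numeric(3)))
  colnames(pi) <- STATES; rownames(pi) <- genes
  shp <- lapply(config$state_beta, function(mc)
    c(alpha = unname(mc["mean"] * mc["conc"]),
      beta = unname((1 - mc["mean"]) * mc["conc"])))
  z <- matrix(0L, g, k, dimnames = list(genes, cells))
  for (i in seq_len(g))
    z[i, ] <- sample.int(3, k, replace = TRUE, prob = pi[i, ])
  # monoallelic-state proportions constant across cells, bi-allelic varies
  pP <- rbeta(g, shp$P["alpha"], shp$P["beta"])
  pM <- rbeta(g, shp$M["alpha"], shp$M["beta"])
  pB <- matrix(rbeta(g * k, shp$B["alpha"], shp$B["beta"]), g, k)
  p <- matrix(pP, g, k)
  p[z == 2L] <- pB[z == 2L]
  p[z == 3L] <- matrix(pM, g, k)[z == 3L]
  dimnames(p) <- list(genes, cells)
  if (!is.null(config$fixed_n)) {
    n <- matrix(config$fixed_n, g, k)
  } else {
    mu <- rlnorm(g, log(config$depth_mean) - config$depth_sdlog^2 / 2,
                 config$depth_sdlog)
    n <- matrix(rnbinom(g * k, mu = rep(mu, k), size = config$dispersion),
                g, k)
  }
  x <- matrix(rbinom(g * k, n, p), g, k)
  structure(list(counts = allele_counts(x, n - x, genes = genes,
                                        cells = cells),
                 z = z, p = p, pi = pi, shape = shp, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes x %d cells, mean coverage %.1f\n",
              x$config$n_genes, x$config$n_cells, mean(x$counts$n)))
  invisible(x)
}

#' Simulate read-level alignment incidence from a truth object
#'
#' Emits one [alignment_incidence()] per cell whose reads realise the
#' counts in `truth` and whose alignment target sets follow the
#' configured multi-read composition: a *unique* read keeps only its true
#' (gene, allele) target; an *allelic* multi-read adds the other allele
#' of its gene; a *genomic* multi-read adds the same allele of another
#' gene; a *complex* multi-read spans both alleles of its gene plus one
#' allele of another gene. The category of every emitted read is
#' recoverable by [classify_reads()].
#'
#' @param truth A [simulate_counts()] result.
#' @param seed Integer seed.
#' @param read_mix Optional override of the truth config's category
#'   fractions.
#' @return List of [alignment_incidence()], one per cell.
#' @export
simulate_incidence <- function(truth, seed = NULL, read_mix = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mix <- read_mix %||% truth$config$read_mix
  stopifnot(abs(sum(mix) - 1) < 1e-6)
  g <- truth$config$n_genes
  if (g < 2 && sum(mix[c("genomic", "complex")]) > 0)
    stop("genomic/complex multi-reads require at least 2 genes")
  genes <- rownames(truth$counts$x)
  lapply(seq_len(truth$config$n_cells), function(ci) {
    x <- truth$counts$x[, ci]; y <- truth$counts$y[, ci]
    src_gene <- rep(rep(genes, 2), c(x, y))
    src_allele <- rep(rep(ALLELES, each = g), c(x, y))
    nr <- length(src_gene)
    if (nr == 0) return(empty_incidence(colnames(truth$counts$x)[ci]))
    cat_i <- sample.int(4, nr, replace = TRUE, prob = mix)
    other <- vapply(match(src_gene, genes), function(gi) {
      j <- sample.int(g - 1L, 1L)
      genes[if (j >= gi) j + 1L else j]
    }, "")
    other_allele <- sample(ALLELES, nr, replace = TRUE)
    rid <- sprintf("r%06d", seq_len(nr))
    # per-category target sets
    hit_read <- c(rid,                                   # own target
                  rid[cat_i >= 3],                       # other allele, own gene
                  rid[cat_i == 2 | cat_i == 4])          # second gene
    hit_gene <- c(src_gene,
                  src_gene[cat_i >= 3],
                  other[cat_i == 2 | cat_i == 4])
    hit_allele <- c(src_allele,
                    flip_allele(src_allele[cat_i >= 3]),
                    ifelse(cat_i[cat_i == 2 | cat_i == 4] == 2,
                           src_allele[cat_i == 2 | cat_i == 4],
                           other_allele[cat_i == 2 | cat_i == 4]))
    inc <- incidence_from_hits(hit_read, hit_gene, hit_allele,
                               cell = colnames(truth$counts$x)[ci])
    attr(inc, "category") <- factor(
      c("unique", "genomic_multi", "allelic_multi", "complex_multi")[cat_i],
      levels = c("unique", "genomic_multi", "allelic_multi",
                 "complex_multi"))
    inc
  })
}

flip_allele <- function(a) ifelse(a == "M", "P", "M")

#' Write an incidence structure as a SAM file
#'
#' Emits a minimal coordinate-free SAM: one `@SQ` line per (gene, allele)
#' reference (named `<gene><suffix>`) and one alignment record per
#' read-target pair; secondary alignments carry flag 256. Useful for
#' round-tripping synthetic data through [read_alignments()].
#'
#' @param inc An [alignment_incidence()].
#' @param path Output path (`.sam`).
#' @param allele_suffix Suffix convention, as in [read_alignments()].
#' @return `path`, invisibly.
#' @export
write_sam <- function(inc, path, allele_suffix = c(M = "_M", P = "_P")) {
  refs <- paste0(inc$targets$gene, allele_suffix[inc$targets$allele])
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", refs, "\tLN:1000"))
  mm <- as(inc$membership, "TsparseMatrix")
  ord <- order(mm@i, mm@j)
  i <- mm@i[ord] + 1L; j <- mm@j[ord] + 1L
  primary <- !duplicated(i)
  rec <- paste(inc$reads[i],
               ifelse(primary, 0L, 256L),
               refs[j], 1L, 255L, "10M", "*", 0L, 0L,
               "ACGTACGTAC", "*", sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
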