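# scase — allele-specific expression states in single cells

`scase` estimates and classifies allele-specific expression (ASE) from
single-cell RNA-seq reads aligned to a diploid (maternal/paternal)
transcriptome, for experiments such as F1-hybrid crosses where every
transcript has a distinguishable maternal and paternal copy. It is aimed
at analysts who want per-cell allelic proportions and expression-state
calls that are robust to the two dominant artefacts at single-cell
depth: loss of multi-mapping reads and sampling zeros.

## What it computes

**Counting.** Reads are represented as a sparse incidence over
(gene, allele) targets and classified as unique, allelic, genomic, or
complex multi-reads. Counts come either from unique reads only or from
EM weighted allocation, which splits each multi-read across its targets
in proportion to current expression estimates and iterates to a fixed
point (total reads conserved at every step).

**Classification and partial pooling.** A three-state beta-binomial
mixture assigns each gene in each cell a posterior probability of
paternal-monoallelic (P), bi-allelic (B), or maternal-monoallelic (M)
expression:

    pi_gk^s  ∝  pi_g.^s · BetaBin(x_gk | n_gk, alpha_g^s, beta_g^s)

and the partial-pooling allelic proportion is the convex combination

    p_gk = pi_gk^P p_g^P + pi_gk^B p_gk^B + pi_gk^M p_g^M

which shrinks each cell toward the cells in the same allelic state.
Fitting is by EM (`em_fit()`, point estimates) or Gibbs sampling
(`mcmc_fit()`, full posteriors with Monte-Carlo standard errors), plus a
two-stage route for grouped cells (`two_stage_fit()`).

**Downstream.** Seven-class ASE patterns on the ternary simplex
(`gene_patterns()`), allelic-bursting independence per gene via the
log-odds ratio of the 2×2 expression-state table with Fisher exact tests
and BH FDR (`independence_analysis()`), down-sampling MSE evaluation
(`downsample()`, `allelic_mse()`), and a ground-truthed synthetic
generator at both count and read level (`simulate_counts()`,
`simulate_incidence()`).

## Worked example

Five reads from one cell: three maternal-unique, one paternal-unique,
and one allelic multi-read mapping to both alleles of the same gene.

```r
library(scase)
tf <- tempfile(fileext = ".tsv")
writeLines(c("r1\tGnai3:M", "r2\tGnai3:M", "r3\tGnai3:M", "r4\tGnai3:P",
             "r5\tGnai3:M,Gnai3:P"), tf)
inc <- read_ec_table(tf, cell = "cell1")
classify_reads(inc)$fractions
#>        unique genomic_multi allelic_multi complex_multi
#>           0.8           0.0           0.2           0.0
wa <- weighted_allocation_em(inc)
c(maternal = wa$x[1, 1], paternal = wa$y[1, 1])
#> maternal paternal
#>     3.75     1.25
```

The ambiguous read is split 3:1 — the fixed point of allocating it by
the current allele counts — so the maternal proportion is 0.75 with all
five reads retained, where unique-read counting would report 3:1 from
four reads.

A full simulated analysis:

```r
truth <- simulate_counts(sim_config(n_genes = 50, n_cells = 120), seed = 1)
fit <- em_fit(truth$counts, max_iter = 50)
table(gene_patterns(fit)$label)
#>   P   B   M  PB  BM  MP PBM
#>   7   1   3   4   8   1  26
mean(abs(fit$params$pi - truth$pi))
#> 0.062
head(independence_analysis(truth$counts)[, c("gene", "n_mat", "n_pat",
                                             "n_bi", "logOR", "qvalue")], 2)
#>   gene n_mat n_pat n_bi      logOR       qvalue
#> 1 g001    58     2   59 -0.6760527 1.000000e+00
#> 2 g002    44    34   39 -2.5483762 1.338175e-05
```

The pattern table summarises each gene's population profile (most genes
here mix all three states); the recovered mixture weights are within
0.06 of the generating truth on average; and the independence table
flags genes whose maternal/paternal bursting departs from independence
at 5% FDR.

A thin command-line front end over the same functions is installed at
`inst/cli/scase.R` with subcommands `count`, `fit`, `patterns`,
`independence`, `simulate`, `simulate-independence`, `downsample`, and
`evaluate`.

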