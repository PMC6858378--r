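---
title: "Allele-specific expression states in single cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific expression states in single cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scase)
```

## The problem

In an F1 hybrid, every transcript can be assigned — when the read overlaps
a distinguishing polymorphism — to its maternal or paternal copy. At
single-cell resolution the allelic proportion
$p_{gk} = x_{gk} / (x_{gk} + y_{gk})$ of gene $g$ in cell $k$ (maternal
reads $x$, paternal reads $y$) is informative about transcriptional
bursting, imprinting, and X inactivation, but it is estimated from very
few reads. Two statistical problems dominate:

1. **Multi-mapping reads.** Most reads do not overlap a polymorphism and
   align equally well to both allelic copies; others align to several
   genes. Discarding them throws away the bulk of the data and inflates
   sampling noise, producing spurious monoallelic calls.
2. **Sampling zeros.** A zero count for one allele in one cell often
   reflects shallow sequencing, not absence of the transcript.

`scase` addresses the first problem by EM weighted allocation of
multi-reads and the second by a hierarchical three-state mixture model
that pools information across cells in the same allelic state.

## Read counting

Each read's equally-best alignments form a row of a sparse incidence
matrix over (gene, allele) targets. Reads fall into four mutually
exclusive categories: *unique* (one allele of one gene), *allelic*
multi-reads (both alleles of one gene), *genomic* multi-reads (several
genes, one allele each), and *complex* multi-reads (several genes, both
alleles of at least one). `unique_read_counts()` keeps only the first
category. `weighted_allocation_em()` instead iterates

* weights: read $r$ is split over its target set proportionally to the
  current count of each target;
* counts: each target's count is the sum of its read weights;

from uniform starting weights until the largest count change is below
`tol` (default $10^{-6}$ reads, cap 1000 iterations). The total read
count is conserved exactly at every iteration, and the multinomial
log-likelihood of the allocation is non-decreasing. A target whose count
reaches zero keeps zero weight (the absorbing state of this EM); the
convergence tolerance therefore governs how closely slowly-decaying
targets approach their limit. Allocation is flat over (gene, allele)
targets — we do not reproduce a transcript-level hierarchy; transcripts
of one gene and allele are collapsed before allocation, and equal
effective lengths are assumed (a `length_weights` hook exists, default
1).

## The three-state mixture

Given counts, each gene-in-cell is modelled as being in one of three
latent allelic states $z_{gk} \in \{P, B, M\}$ — paternal monoallelic,
bi-allelic, maternal monoallelic. Conditional on the state, the maternal
count follows a beta-binomial:

$$x_{gk} \mid n_{gk}, z_{gk} = s \sim \mathrm{BetaBin}(n_{gk},
\alpha_g^s, \beta_g^s),$$

with mixture weights $\pi_{g\cdot}^s$. The monoallelic-state proportions
$p_g^P, p_g^M$ are constant across cells (their betas concentrate near 0
and 1), while the bi-allelic proportion $p_{gk}^B$ varies from cell to
cell. There is no "silent" state: a cell with $n_{gk} = 0$ is classified
from the gene-level weights alone, which is what allows expression-state
estimates for cells with no reads. Fractional counts from weighted
allocation enter through the log-gamma continuous extension of the
beta-binomial; no rounding is applied.

The per-cell posterior state probabilities are

$$\pi_{gk}^s \propto \pi_{g\cdot}^s \,
\mathrm{BetaBin}(x_{gk} \mid n_{gk}, \alpha_g^s, \beta_g^s),$$

and the partial-pooling estimate of the allelic proportion is the convex
combination

$$p_{gk} = \pi_{gk}^P\, p_g^P + \pi_{gk}^B\, p_{gk}^B +
\pi_{gk}^M\, p_g^M .$$

Because the state proportions are estimated from all cells carrying that
state, cell-level estimates are shrunk toward cells in the same state —
not toward a global mean — which is how pooling preserves genuine
cell-to-cell heterogeneity while suppressing sampling noise.

### Priors

Hyperparameters live in `prior_spec()`:

* $\pi_{g\cdot} \sim \mathrm{Dirichlet}(1, 1, 1)$;
* each state beta is parameterised by mean $\mu$ and concentration
  $\kappa = \alpha + \beta$, with $\mu^P$ uniform on $(0, 0.2)$,
  $\mu^B$ on $(0.2, 0.8)$, $\mu^M$ on $(0.8, 1)$ (uniformity enforced by
  a standard-logistic prior on the logit-scale parameter), and a weak
  log-normal prior on $\kappa$ (meanlog $\log 4$, sdlog 1.5).

The defaults are symmetric under swapping maternal and paternal labels,
and they reproduce the expected degenerate behaviour: for a single gene
and single cell with zero reads, class probabilities are exactly
$(\tfrac13, \tfrac13, \tfrac13)$ and the posterior of the allelic
proportion is nearly uniform (mean 0.5, standard deviation about 0.2).
The concentration prior matters for that width; a much tighter prior
would narrow the degenerate posterior artificially.

### Fitting

`em_fit()` alternates classification and maximum-a-posteriori parameter
updates until the log posterior changes by less than `tol` (default
$10^{-6}$, cap 500 iterations). The shape update per gene and state is a
bounded quasi-Newton step on (logit-mean, log-concentration), warm
started and capped at `optim_maxit` inner iterations — a generalised EM,
so the log-posterior trace is still monotone. Genes or states with no
informative reads retain their prior-mean shapes; optimiser failures
retain previous values and flag the gene. Because the absolute
log-posterior tolerance is strict, large problems are usually run with a
smaller `max_iter`; parameter estimates stabilise long before the trace
meets the tolerance, and the fit reports `converged = FALSE` honestly
when capped.

`mcmc_fit()` is a Gibbs sampler over $(z, p, \pi, \alpha, \beta)$ with a
Metropolis-within-Gibbs random walk (proposal SD 0.3) for the shape
parameters; defaults are 2,000 sweeps, 500 burn-in, thinning 2, and a
mandatory seed. It reports posterior means, the posterior standard
deviation of $p_{gk}$, and batch-means Monte-Carlo standard errors
(`mcse()`). Cells not currently assigned to a state draw that state's
proportion from its prior, which keeps the pooled estimator defined for
every cell at every sweep. The sampler errors out if no shape proposal
is ever accepted (a degenerate chain).

`two_stage_fit()` implements grouped estimation: the gene-level shapes
$\alpha_g^s, \beta_g^s$ are common across cells and estimated once from
all cells by MCMC, then the group-specific weights and state
probabilities are re-fitted per cell group by EM with the shapes held
fixed. This is the recommended route when groups are small.

## Downstream summaries

**Seven ASE patterns.** A gene's population profile
$(\pi_{g\cdot}^P, \pi_{g\cdot}^B, \pi_{g\cdot}^M)$ is classified by
strict thresholds: any single state above 0.7 gives the singleton class
(P, B, M); otherwise a pair summing above 0.9 gives the pair class (PB,
BM, MP); otherwise PBM. Boundary values fall through to the next rule.
When no singleton exceeds 0.7, at most one pair can exceed 0.9 (two such
pairs would force a component above 0.8), so the rule order is
unambiguous. `ternary_coordinates()` maps profiles onto the standard
equilateral triangle for plotting and `simplex_from_ternary()` inverts
the map.

**Bursting independence.** For each gene, cells are cross-tabulated by
whether each allele's estimated count exceeds the expression threshold
(strictly greater than 1 read, applied to possibly fractional
estimates). Under independent maternal and paternal bursting the
log-odds ratio
$\log(n_\text{silent} n_\text{bi} / (n_\text{mat} n_\text{pat}))$
is zero. We use the two-sided Fisher exact test per gene (the exact
choice for small cells; chi-square is available) with
Benjamini–Hochberg FDR control, the Haldane–Anscombe $+0.5$ correction
applied automatically when a cell is zero, and report the 4-simplex
proportions plus the (bi-allelic, silent) projection.
`simulate_independent_tables()` draws per-gene marginal probabilities
$p_M, p_P \sim U(0,1)$ and multinomial cells with the product-form
probabilities, the null reference for these analyses.

**Down-sampling evaluation.** `downsample()` thins reads (Bernoulli per
read) or counts (binomial thinning; fractional parts as Bernoulli
remainders), and `allelic_mse()` / `mse_difference()` compare estimates
against a reference, excluding gene-cells without reference coverage
(mask rule: where full-data estimates exist).

## The synthetic generator

`simulate_counts()` inverts the mixture model as a generator: per gene,
weights from a Dirichlet; per cell, a state; proportions from the state
betas (gene-constant for P/M, cell-varying for B); totals from a
negative binomial whose gene-level means are log-normal; maternal counts
binomial. Defaults — 100 genes, 200 cells, Dirichlet(1,1,1), P/M betas
with mean 0.05/0.95 and concentration 20, B beta with mean 0.5 and
concentration 8, mean depth 20 with lognormal sdlog 0.7 and NB size 2 —
describe a moderately-covered SMART-seq-like experiment in which all
three states are common; they are the conditions used by the recovery
tests. `simulate_incidence()` turns the counts into per-cell read-level
incidence with a configurable category mix whose default is the
composition observed in F1 mouse embryo data (14.9% unique / 2.5%
genomic / 59.3% allelic / 23.3% complex).

### What the generator does not emulate

Cross-gene multi-reads pick their second gene uniformly at random. Real
genomic and complex multi-reads arise from homologous gene families:
the same few partners recur, and allocation can exploit their expression
differences. The uniformly random version instead sprays small amounts
of mass across unrelated genes. Two measurable consequences, worth
knowing when interpreting test results:

* On allelic proportions, weighted allocation *ties* unique-read
  counting under pure within-gene ambiguity (allelic multi-reads carry no
  allele information, and the EM fixed-point proportion equals the
  unique-read proportion), and random cross-gene contamination makes
  weighted allocation worse, not better. The recovery tests therefore
  assert a tie-or-better on proportions, strict improvement on count
  magnitudes, and strictly fewer spurious monoallelic calls.
* The direction "discarding multi-reads inflates monoallelic calls"
  holds when coverage is deep enough that the unique-reads method still
  detects the major allele (the full-data regime of the real
  comparison). At low coverage the direction reverses, because unique
  counting converts would-be monoallelic cells into silent ones. The
  directional test is accordingly run at mean depth 30 with a
  0.3/0.7 unique/allelic mix.

Passing tests on this generator show that the estimators behave as
designed under the model's own assumptions; they do not certify
behaviour under real homology structure, isoform-level ambiguity, UMI
protocols, or empty-droplet artefacts.

## Numerical choices

* Beta-binomial and binomial likelihoods are evaluated through
  `lgamma`; $n = 0$ contributes log-probability 0.
* Classification is computed in log space with max-subtraction;
  state probabilities are normalised to $10^{-12}$.
* Mixture-weight updates floor at $10^{-8}$ before renormalising, so a
  state is never annihilated exactly.
* Sampled proportions are clamped to $[10^{-9}, 1 - 10^{-9}]$ before
  beta density evaluation.
* The expression threshold is strictly `> 1` read on estimated counts;
  equality falls below the threshold.
* Fisher tests round fractional state tables to integers; the log-odds
  ratio does not.
* Problem sizes in the test-suite simulations (tens of genes, tens to
  hundreds of cells) were chosen so that directional effects are
  resolved with comfortable margins at a fixed seed.

## Known limitations

* Under the diffuse concentration prior, the mixture is weakly
  identified between a monoallelic state and a bi-allelic state whose
  mean has drifted to the edge of its support with low concentration:
  the Gibbs sampler can trade posterior mass between them. The pooled
  allelic proportions are stable under this trade (the states involved
  describe the same proportions), but posterior state weights from
  `mcmc_fit()` can differ noticeably from the EM maximum-a-posteriori
  weights on small datasets. Tighter `mu_range`/concentration priors in
  `prior_spec()` suppress this at the cost of widening the degenerate
  no-data posterior beyond its intended near-uniform shape.

* Flat allocation over (gene, allele) targets, without transcript-level
  structure or effective-length correction.
* The monoallelic-state proportions are strictly cell-constant; if the
  truth has cell-varying monoallelic leakage, it is absorbed by the
  B state.
* The number of states is fixed at three; there is no explicit
  "not expressed" state (absence is handled by the expression threshold
  downstream, not by the mixture).
* Real-data scale analyses (thousands of genes) should prefer
  `em_fit()` or the two-stage route; the gene-by-gene Gibbs sampler is
  the reference implementation and uncertainty quantifier, not the fast
  path.
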