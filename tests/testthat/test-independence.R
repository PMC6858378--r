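test_that("expression-state tables threshold fractional counts correctly", {
  counts <- allele_counts(matrix(c(3.2, 0, 1.0, 5), 1),
                          matrix(c(0.4, 0, 0.9, 5), 1))
  tb <- expression_state_table(counts, 1)
  # (3.2, 0.4) maternal-only; (0,0) silent; (1.0, 0.9) silent at the
  # strict > 1 threshold; (5, 5) bi-allelic
  expect_equal(unname(tb$counts),
               c(silent = 2, maternal_only = 1, paternal_only = 0,
                 biallelic = 1), ignore_attr = TRUE)
  expect_error(expression_state_table(counts, "nope"), "not found")

  zero <- allele_counts(matrix(0, 1, 4), matrix(0, 1, 4))
  expect_equal(unname(expression_state_table(zero, 1)$counts[1]), 4)
})

test_that("monoallelic cell totals reproduce the worked 2x2 tables", {
  unique_tab <- state_table(silent = 56, maternal_only = 39,
                            paternal_only = 49, biallelic = 142)
  expect_equal(monoallelic_cells(unique_tab), 88)
  weighted_tab <- state_table(silent = 0, maternal_only = 5,
                              paternal_only = 2, biallelic = 279)
  expect_equal(monoallelic_cells(weighted_tab), 7)
  # the same totals via counting a 286-cell matrix
  counts <- counts_from_state_table(56, 39, 49, 142)
  expect_equal(monoallelic_cells(expression_state_table(counts, 1)), 88)
})

test_that("log odds ratios match direct arithmetic and handle zeros", {
  expect_equal(log_odds_ratio(state_table(10, 10, 10, 10)), 0,
               ignore_attr = TRUE)
  tb1 <- state_table(56, 39, 49, 142)
  expect_equal(as.numeric(log_odds_ratio(tb1)),
               log(56 * 142 / (39 * 49)))
  # Haldane correction engages automatically on a zero cell
  tb2 <- state_table(0, 5, 2, 279)
  expect_equal(as.numeric(log_odds_ratio(tb2)),
               log(0.5 * 279.5 / (5.5 * 2.5)))
  expect_true(attr(log_odds_ratio(tb2, "none"), "infinite"))
  # transposing the table (relabelling M and P) leaves logOR unchanged;
  # swapping the diagonal with the off-diagonal flips its sign
  tb3 <- state_table(9, 3, 17, 41)
  expect_equal(as.numeric(log_odds_ratio(state_table(9, 17, 3, 41))),
               as.numeric(log_odds_ratio(tb3)))
  expect_equal(as.numeric(log_odds_ratio(state_table(3, 9, 41, 17))),
               -as.numeric(log_odds_ratio(tb3)))
})

test_that("the exact test matches hypergeometric enumeration", {
  expect_equal(independence_test(state_table(10, 10, 10, 10)), 1)
  tb1 <- state_table(56, 39, 49, 142)
  expect_equal(independence_test(tb1),
               fisher_oracle(c(56, 39, 49, 142)), tolerance = 1e-9)
  set.seed(20)
  for (i in 1:10) {
    cnt <- as.vector(rmultinom(1, 60, rep(0.25, 4)))
    expect_equal(independence_test(state_table(cnt[1], cnt[2], cnt[3],
                                               cnt[4])),
                 fisher_oracle(cnt), tolerance = 1e-9)
  }
})

test_that("BH control keeps the false positive fraction near the target", {
  set.seed(7)
  sim <- simulate_independent_tables(800, 122, seed = 70)
  p <- vapply(sim$tables, independence_test, 0)
  res <- bh_fdr(p, 0.05)
  expect_lte(mean(res$significant), 0.05)
  expect_true(all(res$qvalues >= pmin(p, 1) - 1e-12))
})

test_that("independence simulation follows the product-form multinomial", {
  sim <- simulate_independent_tables(5, n_cells = 10000, seed = 14)
  for (g in 1:5) {
    pr_true <- c(sim$p_M[g] * sim$p_P[g],
                 sim$p_M[g] * (1 - sim$p_P[g]),
                 (1 - sim$p_M[g]) * sim$p_P[g],
                 (1 - sim$p_M[g]) * (1 - sim$p_P[g]))
    emp <- sim$tables[[g]]$counts[c("biallelic", "maternal_only",
                                    "paternal_only", "silent")] / 10000
    expect_lt(max(abs(unname(emp) - pr_true)), 0.02)
  }
})

test_that("simplex proportions and the bi-allelic/silent projection", {
  allbi <- state_table(0, 0, 0, 25)
  sc <- simplex_coordinates(allbi)
  expect_equal(unname(sc$proportions), c(0, 0, 0, 1))
  expect_equal(sc$projection, c(prop_bi = 1, prop_silent = 0))
  tb <- state_table(56, 39, 49, 142)
  expect_equal(unname(simplex_coordinates(tb)$proportions),
               c(56, 39, 49, 142) / 286)
  expect_error(simplex_coordinates(state_table(0, 0, 0, 0)), "empty")
})

test_that("the per-gene analysis table is coherent", {
  set.seed(9)
  truth <- simulate_counts(sim_config(n_genes = 15, n_cells = 50), seed = 90)
  res <- independence_analysis(truth$counts)
  expect_equal(nrow(res), 15)
  expect_equal(res$n_silent + res$n_mat + res$n_pat + res$n_bi,
               rep(50, 15))
  expect_equal(res$qvalue, p.adjust(res$pvalue, "BH"))
  expect_equal(res$prop_bi, res$n_bi / 50)
})
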