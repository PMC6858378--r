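toy_params <- function(g = 1) {
  mixture_params(pi = matrix(1 / 3, g, 3),
                 alpha = matrix(c(1, 4, 19), g, 3, byrow = TRUE),
                 beta = matrix(c(19, 4, 1), g, 3, byrow = TRUE))
}

test_that("cells with no reads are classified by the prior weights alone", {
  params <- mixture_params(pi = matrix(c(0.2, 0.5, 0.3), 1),
                           alpha = matrix(c(1, 4, 19), 1),
                           beta = matrix(c(19, 4, 1), 1))
  probs <- classify_cells(allele_counts(matrix(0), matrix(0)), params)
  expect_equal(unclass(probs)[1, 1, ], c(P = 0.2, B = 0.5, M = 0.3))
})

test_that("classification is symmetric and picks the concentrated state", {
  # all-maternal counts with an M-state beta massed near one
  probs <- classify_cells(allele_counts(matrix(10), matrix(0)),
                          toy_params())
  expect_equal(which.max(unclass(probs)[1, 1, ]), c(M = 3L))
  # mirrored counts under symmetric parameters swap P and M exactly
  pr_m <- classify_cells(allele_counts(matrix(7), matrix(3)), toy_params())
  pr_p <- classify_cells(allele_counts(matrix(3), matrix(7)), toy_params())
  expect_equal(unname(unclass(pr_m)[1, 1, c("P", "M")]),
               unname(unclass(pr_p)[1, 1, c("M", "P")]))
  expect_equal(sum(unclass(pr_m)[1, 1, ]), 1, tolerance = 1e-12)
})

test_that("classify_cells matches brute-force weighted beta-binomial masses", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(0:30, 1)
    x <- if (n > 0) sample(0:n, 1) else 0
    pi <- as.vector(rgamma(3, 1)); pi <- pi / sum(pi)
    av <- runif(3, 0.2, 10); bv <- runif(3, 0.2, 10)
    params <- mixture_params(matrix(pi, 1), matrix(av, 1), matrix(bv, 1))
    got <- unclass(classify_cells(allele_counts(matrix(x), matrix(n - x)),
                                  params))[1, 1, ]
    expect_equal(unname(got), classify_oracle(x, n, pi, av, bv),
                 tolerance = 1e-9)
  }
})

test_that("responsibility updates recover weights and beta parameters", {
  set.seed(4)
  k <- 500
  x <- rbinom(k, 50, rbeta(k, 4, 4))
  counts <- allele_counts(matrix(x, 1), matrix(50 - x, 1))
  params <- toy_params()
  # hard-assign everything to the bi-allelic state
  hard <- array(rep(c(0, 1, 0), each = k), c(1, k, 3))
  up <- update_params(counts, structure(hard, class = "cell_state_probs"),
                      prior_spec(), params)
  expect_equal(up$params$pi[1, ], c(P = 0, B = 1, M = 0), tolerance = 1e-6)
  bmean <- up$params$alpha[1, 2] /
    (up$params$alpha[1, 2] + up$params$beta[1, 2])
  expect_lt(abs(bmean - 0.5), 0.05)
  # uniform responsibilities leave the weights at the prior mean
  unif <- array(1 / 3, c(1, k, 3))
  up2 <- update_params(counts, structure(unif, class = "cell_state_probs"),
                       prior_spec(), params)
  expect_equal(unname(up2$params$pi[1, ]), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("EM on a single empty cell returns uniform class probabilities", {
  fit <- em_fit(allele_counts(matrix(0), matrix(0)))
  expect_equal(unname(unclass(fit$probs)[1, 1, ]), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_equal(unname(fit$estimates$p_tilde[1, 1]), 0.5, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the EM log-posterior trace is non-decreasing", {
  truth <- simulate_counts(sim_config(n_genes = 8, n_cells = 40), seed = 2)
  fit <- em_fit(truth$counts, max_iter = 40)
  expect_true(all(diff(fit$logpost) > -1e-6))
  # state probabilities normalised everywhere
  expect_equal(apply(unclass(fit$probs), c(1, 2), sum),
               matrix(1, 8, 40, dimnames = dimnames(truth$counts$x)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$params$pi)), rep(1, 8),
               tolerance = 1e-12)
})

test_that("swapping maternal and paternal counts mirrors the fit", {
  truth <- simulate_counts(sim_config(n_genes = 5, n_cells = 30), seed = 9)
  fit <- em_fit(truth$counts, max_iter = 30)
  swapped <- allele_counts(truth$counts$y, truth$counts$x)
  fit_sw <- em_fit(swapped, max_iter = 30)
  expect_equal(fit$params$pi[, c("P", "B", "M")],
               fit_sw$params$pi[, c("M", "B", "P")],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$estimates$p_tilde, 1 - fit_sw$estimates$p_tilde,
               tolerance = 1e-6)
})

test_that("pooled proportions are the stated convex combinations", {
  expect_equal(pooled_proportion(c(0, 1, 0), 0.1, 0.37, 0.9), 0.37)
  expect_equal(pooled_proportion(rep(1 / 3, 3), 0.0, 0.5, 1.0), 0.5)
  expect_equal(pooled_proportion(c(0.2, 0.5, 0.3), 0.05, 0.6, 0.95), 0.595)
  # result bounded by the state proportions
  set.seed(1)
  for (i in 1:10) {
    w <- rgamma(3, 1); w <- w / sum(w)
    ps <- sort(runif(3))
    p <- pooled_proportion(w, ps[1], ps[2], ps[3])
    expect_gte(p, ps[1]); expect_lte(p, ps[3])
  }
})

test_that("partial pooling shrinks toward the within-state mean", {
  # all cells genuinely bi-allelic around p = 0.5
  set.seed(12)
  k <- 120
  p_true <- rbeta(k, 6, 6)
  n <- rep(8, k)
  x <- rbinom(k, n, p_true)
  counts <- allele_counts(matrix(x, 1), matrix(n - x, 1))
  fit <- em_fit(counts, max_iter = 60)
  p_hat <- fit$estimates$p_hat[1, ]
  p_tilde <- fit$estimates$p_tilde[1, ]
  centre <- mean(p_hat)
  expect_lt(mean(abs(p_tilde - centre)), mean(abs(p_hat - centre)))
})

test_that("two-stage fitting degenerates gracefully and uses fixed shapes", {
  truth <- simulate_counts(sim_config(n_genes = 4, n_cells = 20), seed = 3)
  res <- two_stage_fit(truth$counts, rep("all", 20), seed = 5,
                       stage1 = list(n_iter = 400, burn_in = 100),
                       max_iter = 30)
  direct <- em_fit(truth$counts, fixed_shapes = res$shapes, max_iter = 30)
  expect_equal(res$fits$all$params$pi, direct$params$pi, tolerance = 1e-9)
  expect_equal(res$fits$all$params$alpha, direct$params$alpha)
  expect_error(two_stage_fit(truth$counts, rep("a", 5), seed = 1),
               "label every cell")
})

test_that("group-specific weights beat a pooled fit on two-group data", {
  set.seed(8)
  cfgA <- sim_config(n_genes = 12, n_cells = 40,
                     dirichlet = c(8, 1, 1), depth_mean = 15)
  cfgB <- sim_config(n_genes = 12, n_cells = 40,
                     dirichlet = c(1, 1, 8), depth_mean = 15)
  tA <- simulate_counts(cfgA, seed = 81)
  tB <- simulate_counts(cfgB, seed = 82)
  counts <- allele_counts(cbind(tA$counts$x, tB$counts$x),
                          cbind(tA$counts$y, tB$counts$y))
  groups <- rep(c("A", "B"), each = 40)
  res <- two_stage_fit(counts, groups, seed = 9,
                       stage1 = list(n_iter = 400, burn_in = 100,
                                     keep_draws = FALSE),
                       max_iter = 30)
  pooled <- em_fit(counts, max_iter = 30)
  errA_group <- mean(abs(res$fits$A$params$pi - tA$pi))
  errA_pooled <- mean(abs(pooled$params$pi - tA$pi))
  expect_lt(errA_group, errA_pooled)
})

test_that("a single-cell group with no reads falls back to gene-level weights", {
  counts <- allele_counts(matrix(c(5, 0), 1), matrix(c(5, 0), 1))
  res <- two_stage_fit(counts, c("big", "solo"), seed = 2,
                       stage1 = list(n_iter = 300, burn_in = 100),
                       max_iter = 20)
  probs_solo <- unclass(res$fits$solo$probs)[1, 1, ]
  # no within-group data: class probabilities stay essentially uniform
  expect_equal(unname(probs_solo), rep(1 / 3, 3), tolerance = 0.05)
})
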