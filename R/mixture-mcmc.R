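#' Fit the mixture by Gibbs sampling
#'
#' Markov chain Monte Carlo for the three-state beta-binomial mixture with
#' partial pooling. Each sweep, per gene: (1) sample the latent allelic
#' state `z_gk` of every cell from its conditional given the current
#' parameters; (2) sample the state proportions from their beta full
#' conditionals — `p_g^P` and `p_g^M` are constant across cells and pool
#' the counts of cells assigned to that state, `p_gk^B` is cell-specific
#' (cells not assigned to B draw from the state's beta prior);
#' (3) sample the mixture weights from their Dirichlet full conditional;
#' (4) update the state beta parameters `(alpha, beta)` by a
#' Metropolis-within-Gibbs random walk on (logit-mean, log-concentration);
#' (5) recompute the classification probabilities and record the pooled
#' proportion `p_gk = pi_gk^P p_g^P + pi_gk^B p_gk^B + pi_gk^M p_g^M`.
#'
#' Reported estimates are means over retained draws; `p_sd` is the
#' posterior standard deviation of the pooled allelic proportion.
#'
#' @param counts An [allele_counts()] object (fractional counts allowed).
#' @param priors A [prior_spec()].
#' @param n_iter Total sweeps. @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer seed; required (the chain is otherwise
#'   irreproducible).
#' @param proposal_sd Random-walk proposal standard deviation for the
#'   shape updates.
#' @param keep_draws Keep the retained draws of the pooled proportions
#'   (default: when `genes * cells <= 5000`). Needed for [mcse()].
#'
#' @return An object of class `scase_fit` (`engine = "mcmc"`) whose
#'   `params`, `probs` and `estimates` are posterior means; additional
#'   elements: `draws` (retained pooled-proportion draws, iterations x
#'   (gene, cell), when kept), `acceptance` (per-state MH acceptance
#'   rates), `n_draws`.
#' @export
mcmc_fit <- function(counts, priors = prior_spec(), n_iter = 2000L,
                     burn_in = 500L, thin = 2L, seed = NULL,
                     proposal_sd = 0.3, keep_draws = NULL) {
  if (is.null(seed)) stop("mcmc_fit requires an integer seed")
  stopifnot(n_iter > burn_in, thin >= 1)
  set.seed(seed)
  g <- nrow(counts$x); k <- ncol(counts$x)
  if (is.null(keep_draws)) keep_draws <- g * k <= 5000
  keep_at <- seq.int(burn_in + thin, n_iter, by = thin)
  nd <- length(keep_at)

  pi_mean <- matrix(0, g, 3, dimnames = list(rownames(counts$x), STATES))
  alpha_mean <- beta_mean <- pi_mean
  w_mean <- array(0, c(g, k, 3),
                  dimnames = list(rownames(counts$x), colnames(counts$x), STATES))
  p_sum <- p_sumsq <- matrix(0, g, k,
                             dimnames = dimnames(counts$x))
  draws <- if (keep_draws) matrix(NA_real_, nd, g * k) else NULL
  acc <- matrix(0, g, 3); prop_n <- 0

  th0 <- init_theta(priors)
  for (gi in seq_len(g)) {
    x <- counts$x[gi, ]; n <- counts$n[gi, ]
    theta <- th0
    ab <- shapes_from_theta(theta, priors)
    pP <- ab$alpha[1] / (ab$alpha[1] + ab$beta[1])
    pM <- ab$alpha[3] / (ab$alpha[3] + ab$beta[3])
    pB <- rep(ab$alpha[2] / (ab$alpha[2] + ab$beta[2]), k)
    pi_g <- rep(1 / 3, 3)
    W <- class_probs_given_p(x, n, pi_g, pP, pB, pM)
    di <- 0L
    for (it in seq_len(n_iter)) {
      # 1. latent states
      z <- sample_states(W)
      # 2. state proportions from beta full conditionals
      selP <- z == 1L; selB <- z == 2L; selM <- z == 3L
      pP <- rbeta(1, ab$alpha[1] + sum(x[selP]),
                  ab$beta[1] + sum(n[selP] - x[selP]))
      pM <- rbeta(1, ab$alpha[3] + sum(x[selM]),
                  ab$beta[3] + sum(n[selM] - x[selM]))
      pB <- rbeta(k, ab$alpha[2] + ifelse(selB, x, 0),
                  ab$beta[2] + ifelse(selB, n - x, 0))
      pP <- clamp01(pP); pM <- clamp01(pM); pB <- clamp01(pB)
      # 3. mixture weights
      pi_g <- rdirichlet1(priors$dirichlet + tabulate(z, 3))
      # 4. shape parameters, Metropolis within Gibbs
      for (si in 1:3) {
        pdat <- switch(si, pP, pB[selB], pM)
        cur <- theta[si, ]
        prop <- cur + rnorm(2, 0, proposal_sd)
        lcur <- shape_logpost(cur, pdat, priors, si)
        lprop <- shape_logpost(prop, pdat, priors, si)
        if (is.finite(lprop) && log(runif(1)) < lprop - lcur) {
          theta[si, ] <- prop
          acc[gi, si] <- acc[gi, si] + 1
        }
      }
      ab <- shapes_from_theta(theta, priors)
      # 5. classification probabilities and pooled proportion
      W <- class_probs_given_p(x, n, pi_g, pP, pB, pM)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        di <- di + 1L
        p_now <- W[, 1] * pP + W[, 2] * pB + W[, 3] * pM
        p_sum[gi, ] <- p_sum[gi, ] + p_now
        p_sumsq[gi, ] <- p_sumsq[gi, ] + p_now^2
        pi_mean[gi, ] <- pi_mean[gi, ] + pi_g
        alpha_mean[gi, ] <- alpha_mean[gi, ] + ab$alpha
        beta_mean[gi, ] <- beta_mean[gi, ] + ab$beta
        w_mean[gi, , ] <- w_mean[gi, , ] + W
        if (keep_draws) draws[di, (gi - 1) * k + seq_len(k)] <- p_now
      }
    }
    if (all(acc[gi, ] == 0))
      stop("degenerate chain for gene ", gi,
           ": no shape proposal was ever accepted")
  }
  prop_n <- n_iter
  pi_mean <- pi_mean / nd
  pi_mean <- pi_mean / rowSums(pi_mean)
  alpha_mean <- alpha_mean / nd; beta_mean <- beta_mean / nd
  w_mean <- w_mean / nd
  p_tilde <- p_sum / nd
  p_var <- pmax(p_sumsq / nd - p_tilde^2, 0) * nd / max(nd - 1, 1)
  params <- mixture_params(pi_mean, alpha_mean, beta_mean)
  probs <- structure(w_mean, class = "cell_state_probs")
  est <- list(p_hat = allelic_proportion(counts), p_tilde = p_tilde,
              p_sd = sqrt(p_var))
  structure(list(params = params, probs = probs, estimates = est,
                 draws = draws, n_draws = nd,
                 acceptance = acc / prop_n,
                 priors = priors, converged = TRUE,
                 low_information = rowSums(counts$n) == 0,
                 logpost = numeric(0), engine = "mcmc"),
            class = "scase_fit")
}

clamp01 <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)

rdirichlet1 <- function(a) {
  x <- rgamma(length(a), shape = a)
  if (sum(x) <= 0) return(rep(1 / length(a), length(a)))
  x / sum(x)
}

# K x 3 classification probabilities given current state proportions
class_probs_given_p <- function(x, n, pi_g, pP, pB, pM) {
  lw <- cbind(log(pi_g[1]) + binom_loglik(x, n, pP),
              log(pi_g[2]) + binom_loglik(x, n, pB),
              log(pi_g[3]) + binom_loglik(x, n, pM))
  mx <- pmax(lw[, 1], lw[, 2], lw[, 3])
  w <- exp(lw - mx)
  w / rowSums(w)
}

sample_states <- function(W) {
  u <- runif(nrow(W))
  1L + (u > W[, 1]) + (u > W[, 1] + W[, 2])
}

# target for the MH shape update: beta likelihood of the sampled state
# proportions plus the priors expressed in the transformed space — the
# standard-logistic density on t1 makes the state mean exactly uniform on
# its support, and the normal on t2 is the log-normal concentration prior
shape_logpost <- function(theta, pdat, priors, si) {
  ab <- theta_to_shape(theta, priors$mu_range[[si]])
  ll <- if (length(pdat)) sum(dbeta(clamp01(pdat), ab[1], ab[2], log = TRUE)) else 0
  ll + stats::dlogis(theta[1], log = TRUE) +
    dnorm(theta[2], priors$kappa_meanlog, priors$kappa_sdlog, log = TRUE)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' Batch-means estimate: the retained draws are split into consecutive
#' batches and the standard error of the batch means is reported, which
#' accounts for autocorrelation in the chain.
#'
#' @param x Numeric vector of draws.
#' @param n_batches Number of consecutive batches.
#' @return Standard error of `mean(x)`.
#' @export
mcse <- function(x, n_batches = 25L) {
  x <- x[is.finite(x)]
  n_batches <- min(n_batches, max(2L, length(x) %/% 2L))
  bm <- tapply(x, cut(seq_along(x), n_batches, labels = FALSE), mean)
  sd(bm) / sqrt(length(bm))
}
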