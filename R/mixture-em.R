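#' Prior specification for the three-state mixture
#'
#' The mixture weights of the P (paternal monoallelic), B (bi-allelic) and
#' M (maternal monoallelic) states get a Dirichlet prior; each state's
#' beta distribution is parameterised by mean `mu` and concentration
#' `kappa = alpha + beta`, with `mu` uniform on a state-specific interval
#' (mass near zero for P, near one for M) and a log-normal prior on
#' `kappa`. Defaults are symmetric under swapping maternal and paternal
#' labels.
#'
#' @param dirichlet Length-3 Dirichlet concentration for `(P, B, M)`
#'   mixture weights.
#' @param mu_range Named list of `(lo, hi)` supports for the state beta
#'   means, states `P`, `B`, `M`.
#' @param kappa_meanlog,kappa_sdlog Parameters of the log-normal prior on
#'   the beta concentration.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(dirichlet = c(1, 1, 1),
                       mu_range = list(P = c(0, 0.2),
                                       B = c(0.2, 0.8),
                                       M = c(0.8, 1)),
                       kappa_meanlog = log(4), kappa_sdlog = 1.5) {
  stopifnot(length(dirichlet) == 3, all(dirichlet > 0),
            all(STATES %in% names(mu_range)), kappa_sdlog > 0)
  for (s in STATES) {
    r <- mu_range[[s]]
    stopifnot(length(r) == 2, r[1] >= 0, r[2] <= 1, r[1] < r[2])
  }
  structure(list(dirichlet = setNames(dirichlet, STATES),
                 mu_range = mu_range[STATES],
                 kappa_meanlog = kappa_meanlog,
                 kappa_sdlog = kappa_sdlog),
            class = "prior_spec")
}

# (t1, t2) -> (alpha, beta): mu = logistic map into the state's support,
# kappa = exp(t2)
theta_to_shape <- function(theta, range) {
  mu <- range[1] + (range[2] - range[1]) * plogis(theta[1])
  kappa <- exp(theta[2])
  c(alpha = mu * kappa, beta = (1 - mu) * kappa)
}

init_theta <- function(priors) {
  matrix(c(0, 0, 0, rep(priors$kappa_meanlog, 3)), nrow = 3,
         dimnames = list(STATES, c("t1", "t2")))
}

shapes_from_theta <- function(theta, priors) {
  ab <- vapply(STATES, function(s)
    theta_to_shape(theta[s, ], priors$mu_range[[s]]), numeric(2))
  list(alpha = ab[1, ], beta = ab[2, ])
}

#' Construct mixture parameters
#'
#' Per-gene state weights and beta shape parameters for the three-state
#' beta-binomial mixture.
#'
#' @param pi Genes x 3 matrix of state weights (rows on the simplex),
#'   columns ordered `P`, `B`, `M`.
#' @param alpha,beta Genes x 3 matrices of positive beta shapes.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi, alpha, beta) {
  pi <- as.matrix(pi); alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  colnames(pi) <- colnames(alpha) <- colnames(beta) <- STATES
  if (any(abs(rowSums(pi) - 1) > 1e-8) || any(pi < -1e-12))
    stop("mixture weights must lie on the simplex")
  if (any(alpha <= 0) || any(beta <= 0))
    stop("beta shape parameters must be strictly positive")
  structure(list(pi = pi, alpha = alpha, beta = beta),
            class = "mixture_params")
}

#' Posterior state probabilities for every gene and cell
#'
#' Evaluates, in log space, `pi_gk^s` proportional to
#' `pi_g.^s * BetaBin(x_gk | n_gk, alpha_g^s, beta_g^s)` and normalises
#' over the three states. Cells with `n = 0` receive the gene-level
#' weights `pi_g.` unchanged.
#'
#' @param counts An [allele_counts()] object.
#' @param params A [mixture_params()] object (one row per gene).
#' @return Genes x cells x 3 array of class `cell_state_probs`; attribute
#'   `loglik_mix` holds the per-entry mixture log-likelihood.
#' @export
classify_cells <- function(counts, params) {
  g <- nrow(counts$x); k <- ncol(counts$x)
  logw <- array(NA_real_, c(g, k, 3),
                dimnames = list(rownames(counts$x), colnames(counts$x), STATES))
  for (s in 1:3) {
    ll <- betabin_logpmf(counts$x, counts$n,
                         matrix(params$alpha[, s], g, k),
                         matrix(params$beta[, s], g, k))
    logw[, , s] <- matrix(log(params$pi[, s]), g, k) +
      matrix(ll, g, k)
  }
  mx <- pmax(logw[, , 1], logw[, , 2], logw[, , 3])
  lse <- mx + log(exp(logw[, , 1] - mx) + exp(logw[, , 2] - mx) +
                    exp(logw[, , 3] - mx))
  post <- array(exp(logw - as.vector(lse)), dim(logw), dimnames(logw))
  structure(post, loglik_mix = lse, class = "cell_state_probs")
}

#' Re-estimate mixture parameters from state responsibilities
#'
#' The maximisation step of the EM: maximum-a-posteriori update of the
#' state weights (responsibility totals plus Dirichlet prior, floored at a
#' small epsilon and renormalised) and responsibility-weighted
#' beta-binomial refitting of each state's `(alpha, beta)` by bounded
#' quasi-Newton on `(logit-mean, log-concentration)`. Genes or states with
#' no informative reads retain their previous parameters; optimizer
#' failures retain previous values and flag the gene.
#'
#' @param counts An [allele_counts()] object.
#' @param probs A [classify_cells()] result.
#' @param priors A [prior_spec()].
#' @param params Current [mixture_params()] (used as warm start and
#'   fallback).
#' @param theta Optional genes x 3 x 2 array of transformed shape
#'   parameters (warm start); reconstructed from `params` if missing.
#' @param fixed_shapes If `TRUE`, only the mixture weights are updated.
#' @param optim_maxit Inner iteration cap per state update (a generalised
#'   EM step).
#' @return List with `params`, `theta`, and `flagged` (logical per gene).
#' @export
update_params <- function(counts, probs, priors, params,
                          theta = NULL, fixed_shapes = FALSE,
                          optim_maxit = 25L) {
  g <- nrow(counts$x); k <- ncol(counts$x)
  a <- priors$dirichlet
  resp_tot <- apply(unclass(probs), c(1, 3), sum)     # G x 3
  pi_new <- resp_tot + matrix(a - 1, g, 3, byrow = TRUE)
  pi_new <- pmax(pi_new, 1e-8)
  pi_new <- pi_new / rowSums(pi_new)
  if (is.null(theta))
    theta <- array(rep(init_theta(priors), each = g), c(g, 3, 2))
  flagged <- logical(g)
  alpha_new <- params$alpha; beta_new <- params$beta
  if (!fixed_shapes) {
    for (gi in seq_len(g)) {
      xg <- counts$x[gi, ]; ng <- counts$n[gi, ]
      for (si in 1:3) {
        r <- unclass(probs)[gi, , si]
        if (sum(r * ng) <= 1e-10) next        # no data: keep prior values
        rng <- priors$mu_range[[si]]
        fn <- function(th) {
          ab <- theta_to_shape(th, rng)
          -(sum(r * betabin_logpmf(xg, ng, ab[1], ab[2])) +
              stats::dlogis(th[1], log = TRUE) +
              dnorm(th[2], priors$kappa_meanlog, priors$kappa_sdlog,
                    log = TRUE))
        }
        fit <- tryCatch(
          optim(theta[gi, si, ], fn, method = "BFGS",
                control = list(maxit = optim_maxit)),
          error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$value)) {
          flagged[gi] <- TRUE
          next
        }
        theta[gi, si, ] <- fit$par
        ab <- theta_to_shape(fit$par, rng)
        alpha_new[gi, si] <- ab[1]
        beta_new[gi, si] <- ab[2]
      }
    }
  }
  list(params = mixture_params(pi_new, alpha_new, beta_new),
       theta = theta, flagged = flagged)
}

# log posterior contributions that involve the parameters being updated
log_posterior <- function(lse, params, theta, priors) {
  a <- priors$dirichlet
  sum(lse) +
    sum((matrix(a, nrow(params$pi), 3, byrow = TRUE) - 1) *
          log(pmax(params$pi, 1e-300))) +
    sum(stats::dlogis(theta[, , 1], log = TRUE)) +
    sum(dnorm(theta[, , 2], priors$kappa_meanlog, priors$kappa_sdlog,
              log = TRUE))
}

#' Fit the mixture by expectation-maximisation
#'
#' Alternates [classify_cells()] (E step) and [update_params()] (M step)
#' until the change in log posterior falls below `tol`, then returns
#' point estimates: state probabilities per gene and cell, mixture
#' parameters, and the partial-pooling allelic proportions
#' (a convex combination of state-specific proportions weighted by the
#' state probabilities; see [pooled_proportion()]).
#'
#' @param counts An [allele_counts()] object.
#' @param priors A [prior_spec()].
#' @param tol Absolute log-posterior convergence tolerance.
#' @param max_iter Maximum EM iterations; non-convergence returns the last
#'   iterate with `converged = FALSE`.
#' @param fixed_shapes Optional list with `alpha`, `beta` (genes x 3
#'   matrices, or length-3 vectors recycled over genes): hold the beta
#'   shapes fixed and update only the mixture weights (the second stage of
#'   [two_stage_fit()]).
#' @param optim_maxit Passed to [update_params()].
#'
#' @return An object of class `scase_fit` with elements `params`, `probs`,
#'   `estimates` (`p_hat`, `p_tilde`, state proportions), `logpost`
#'   (trace), `converged`, `flagged`, `engine = "em"`.
#' @export
em_fit <- function(counts, priors = prior_spec(), tol = 1e-6,
                   max_iter = 500L, fixed_shapes = NULL,
                   optim_maxit = 25L) {
  g <- nrow(counts$x); k <- ncol(counts$x)
  stopifnot(g >= 1, k >= 1)
  theta <- array(rep(init_theta(priors), each = g), c(g, 3, 2))
  sh <- shapes_from_theta(init_theta(priors), priors)
  alpha <- matrix(sh$alpha, g, 3, byrow = TRUE)
  beta <- matrix(sh$beta, g, 3, byrow = TRUE)
  fixed <- !is.null(fixed_shapes)
  if (fixed) {
    alpha <- matrix(as.matrix(fixed_shapes$alpha), g, 3,
                    byrow = is.null(dim(fixed_shapes$alpha)))
    beta <- matrix(as.matrix(fixed_shapes$beta), g, 3,
                   byrow = is.null(dim(fixed_shapes$beta)))
  }
  params <- mixture_params(matrix(1 / 3, g, 3), alpha, beta)
  logpost <- numeric(0)
  converged <- FALSE
  flagged <- logical(g)
  probs <- NULL
  for (it in seq_len(max_iter)) {
    probs <- classify_cells(counts, params)
    lp <- log_posterior(attr(probs, "loglik_mix"), params, theta, priors)
    logpost <- c(logpost, lp)
    if (it > 1 && abs(lp - logpost[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    up <- update_params(counts, probs, priors, params, theta,
                        fixed_shapes = fixed, optim_maxit = optim_maxit)
    params <- up$params; theta <- up$theta
    flagged <- flagged | up$flagged
  }
  probs <- classify_cells(counts, params)
  est <- point_estimates(counts, params, probs)
  structure(list(params = params, probs = probs, estimates = est,
                 theta = theta, priors = priors, logpost = logpost,
                 converged = converged, flagged = flagged,
                 low_information = rowSums(counts$n) == 0,
                 engine = "em"),
            class = "scase_fit")
}

# Point estimates of state proportions and the pooled proportion.
# P/M-state proportions are gene-level beta means updated by the
# responsibility-weighted counts; the B-state proportion is the per-cell
# posterior-mean beta draw.
point_estimates <- function(counts, params, probs) {
  g <- nrow(counts$x); k <- ncol(counts$x)
  w <- unclass(probs)
  wP <- matrix(w[, , 1], g, k); wM <- matrix(w[, , 3], g, k)
  sxP <- rowSums(wP * counts$x)
  snP <- rowSums(wP * counts$n)
  sxM <- rowSums(wM * counts$x)
  snM <- rowSums(wM * counts$n)
  p_P <- (params$alpha[, 1] + sxP) / (params$alpha[, 1] + params$beta[, 1] + snP)
  p_M <- (params$alpha[, 3] + sxM) / (params$alpha[, 3] + params$beta[, 3] + snM)
  p_B <- (counts$x + params$alpha[, 2]) /
    (counts$n + params$alpha[, 2] + params$beta[, 2])
  p_tilde <- pooled_proportion(probs, p_P, p_B, p_M)
  list(p_hat = allelic_proportion(counts),
       p_tilde = p_tilde, p_P = p_P, p_B = p_B, p_M = p_M)
}

#' Partial-pooling allelic proportion
#'
#' The pooled estimate is the convex combination of the three
#' state-specific maternal proportions weighted by the posterior state
#' probabilities:
#' `p_gk = pi_gk^P p_g^P + pi_gk^B p_gk^B + pi_gk^M p_g^M`.
#'
#' @param probs Either a [classify_cells()] array (genes x cells x 3) or a
#'   numeric length-3 probability vector `(P, B, M)`.
#' @param p_P,p_M State proportions: per-gene vectors (or scalars).
#' @param p_B Bi-allelic state proportion: genes x cells matrix, per-gene
#'   vector, or scalar.
#' @return Genes x cells matrix (or a scalar for vector input).
#' @export
pooled_proportion <- function(probs, p_P, p_B, p_M) {
  if (is.numeric(probs) && is.null(dim(probs)) && length(probs) == 3) {
    stopifnot(abs(sum(probs) - 1) < 1e-8)
    return(unname(probs[1] * p_P + probs[2] * p_B + probs[3] * p_M))
  }
  w <- unclass(probs)
  g <- dim(w)[1]; k <- dim(w)[2]
  pPm <- matrix(p_P, g, k)
  pMm <- matrix(p_M, g, k)
  pBm <- if (is.matrix(p_B)) p_B else matrix(p_B, g, k)
  matrix(w[, , 1], g, k) * pPm + matrix(w[, , 2], g, k) * pBm +
    matrix(w[, , 3], g, k) * pMm
}

#' @export
print.scase_fit <- function(x, ...) {
  cat(sprintf("scase_fit (%s): %d genes x %d cells, %sconverged in %d iterations\n",
              x$engine, nrow(x$params$pi), dim(x$probs)[2],
              if (isTRUE(x$converged)) "" else "NOT ",
              length(x$logpost)))
  invisible(x)
}

#' Subset cells of an allele_counts object
#'
#' @param x An [allele_counts()] object.
#' @param i Row (gene) index. @param j Column (cell) index.
#' @param ... Ignored. @param drop Ignored (dimensions are kept).
#' @export
`[.allele_counts` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  allele_counts(x$x[i, j, drop = FALSE], x$y[i, j, drop = FALSE])
}

#' Two-stage fit for grouped cells
#'
#' Estimates the gene-level beta shape parameters once from all cells by
#' MCMC, then re-fits the mixture weights, state probabilities, and
#' pooled proportions within each cell group by EM with the shapes held
#' fixed. Recommended when groups are small: the shapes are common across
#' cells and are estimated most accurately from the full data.
#'
#' @param counts An [allele_counts()] object.
#' @param groups Character/factor vector of group labels, one per cell
#'   (all cells must be labelled).
#' @param priors A [prior_spec()].
#' @param seed Seed for the stage-1 MCMC.
#' @param stage1 List of arguments forwarded to [mcmc_fit()].
#' @param ... Forwarded to [em_fit()] in stage 2.
#' @return List with `stage1` (the MCMC fit), `shapes`, and `fits`, a
#'   named list of per-group `scase_fit` objects. Empty groups are skipped
#'   with a warning.
#' @export
two_stage_fit <- function(counts, groups, priors = prior_spec(), seed,
                          stage1 = list(), ...) {
  k <- ncol(counts$x)
  groups <- as.character(groups)
  if (length(groups) != k || anyNA(groups))
    stop("groups must label every cell")
  s1 <- do.call(mcmc_fit, c(list(counts = counts, priors = priors,
                                 seed = seed), stage1))
  shapes <- list(alpha = s1$params$alpha, beta = s1$params$beta)
  fits <- list()
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    if (length(idx) == 0) {
      warning("group '", grp, "' has no cells; skipped")
      next
    }
    fits[[grp]] <- em_fit(counts[, idx], priors = priors,
                          fixed_shapes = shapes, ...)
  }
  list(stage1 = s1, shapes = shapes, fits = fits)
}
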