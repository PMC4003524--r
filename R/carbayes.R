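#' Proper-CAR covariance structure for a mapped dataset
#'
#' Assembles the ingredients of the proper conditional autoregressive (CAR)
#' prior on the spatial effects: the diagonal scale matrix P with
#' P_ii = 1/E_i, the neighbour matrix D with D_ij = sqrt(E_j / E_i) for
#' adjacent pairs, and the admissible range of the autocorrelation
#' parameter.  The joint covariance is
#' Sigma = sigma2 * (I - lambda * D)^{-1} P, which is symmetric positive
#' definite exactly when 1/lambda lies outside the spectrum of
#' P^{-1/2} D P^{1/2}; that similarity transform equals the 0/1 adjacency
#' matrix, so the bounds are the reciprocals of its extreme eigenvalues and
#' always bracket 0.
#'
#' @param counts a [counts_data()] (E_i > 0).
#' @param map a connected [region_map()] with at least one edge.
#' @return An object of class `car_structure`: list with `P`, `D` (dense
#'   m x m), `E`, `edges` (0-based two-column matrix), `evals` (adjacency
#'   eigenvalues) and `lambda_bounds` (open interval).
#' @export
build_car_structure <- function(counts, map) {
  counts <- counts[match(map$region_id, counts$region_id), ]
  E <- counts$expected
  if (any(!is.finite(E)) || any(E <= 0)) stop("E_i must be positive finite")
  m <- map$m
  if (nrow(map$edges) == 0L) stop("CAR structure needs at least one edge")
  A <- matrix(0, m, m)
  A[map$edges] <- 1
  A[map$edges[, c(2L, 1L), drop = FALSE]] <- 1
  D <- A * sqrt(outer(1 / E, E))        # D_ij = sqrt(E_j / E_i) on edges
  evals <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda_bounds <- c(1 / min(evals), 1 / max(evals))
  structure(list(P = diag(1 / E, m), D = D, E = E,
                 edges = map$edges - 1L, evals = evals,
                 lambda_bounds = lambda_bounds, m = m,
                 region_id = map$region_id),
            class = "car_structure")
}

#' CAR covariance matrix at given parameter values
#'
#' @param structure a [build_car_structure()] result.
#' @param sigma2 spatial dispersion (> 0).
#' @param lambda spatial autocorrelation, inside `lambda_bounds` for a
#'   positive-definite result.
#' @return The m x m covariance sigma2 * (I - lambda D)^{-1} P.
#' @export
car_covariance <- function(structure, sigma2, lambda) {
  m <- structure$m
  sigma2 * solve(diag(m) - lambda * structure$D) %*% structure$P
}

#' Default vague priors for the disease-mapping model
#'
#' @param mu_mean,mu_var normal prior on the overall log relative risk.
#' @param sigma2_shape,sigma2_rate inverse-gamma prior on the spatial
#'   dispersion (shape/rate parameterization; the default is the
#'   conventional weakly-informative IG(0.5, 0.0005)).  The improper
#'   uniform-on-sigma alternative p(sigma2) proportional to 1/sigma is
#'   `sigma2_shape = -0.5, sigma2_rate = 0`; it avoids the mass near zero
#'   that makes IG(eps, eps) priors shrink weakly-identified variance
#'   components, and its conditional posterior is still proper whenever
#'   m >= 2.
#' @return A list of class `car_priors`.  The autocorrelation prior is
#'   uniform over the admissible interval.
#' @export
car_priors <- function(mu_mean = 0, mu_var = 1e4,
                       sigma2_shape = 0.5, sigma2_rate = 5e-4) {
  structure(list(mu_mean = mu_mean, mu_var = mu_var,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "car_priors")
}

#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations (adaptation happens only here).
#' @param thin thinning interval for retained draws.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4L, n_iter = 20000L, n_burn = 10000L,
                          thin = 5L) {
  stopifnot(chains >= 1, n_iter > n_burn, thin >= 1)
  structure(list(chains = as.integer(chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin)),
            class = "mcmc_settings")
}

#' Joint log posterior of the disease-mapping model
#'
#' Poisson log likelihood sum_i [C_i log(theta_i E_i) - theta_i E_i -
#' log C_i!] with log(theta_i) = mu + eta_i, plus the multivariate normal
#' log density of eta under the proper-CAR covariance, plus the log priors
#' (normal on mu, inverse-gamma on sigma2, uniform on lambda).  Returns
#' -Inf (by contract, not an error) when sigma2 <= 0 or lambda is outside
#' the admissible bounds, so samplers and optimizers can reject such
#' states.
#'
#' @param params list with `mu`, `eta` (length m), `sigma2`, `lambda`.
#' @param counts a [counts_data()].
#' @param structure a [build_car_structure()].
#' @param priors a [car_priors()].
#' @return The log posterior density (unnormalized only by the evidence).
#' @export
log_posterior <- function(params, counts, structure, priors = car_priors()) {
  counts <- counts[match(structure$region_id, counts$region_id), ]
  mu <- params$mu; eta <- params$eta
  sigma2 <- params$sigma2; lambda <- params$lambda
  b <- structure$lambda_bounds
  if (!is.finite(sigma2) || sigma2 <= 0 ||
      !is.finite(lambda) || lambda <= b[1L] || lambda >= b[2L]) {
    return(-Inf)
  }
  E <- structure$E
  theta <- exp(mu + eta)
  loglik <- sum(stats::dpois(counts$observed, theta * E, log = TRUE))
  m <- structure$m
  # MVN density via the O(m + edges) precision identities
  quad <- sum(E * eta^2)
  if (nrow(structure$edges) > 0L) {
    ei <- structure$edges[, 1L] + 1L
    ej <- structure$edges[, 2L] + 1L
    quad <- quad - 2 * lambda * sum(sqrt(E[ei] * E[ej]) * eta[ei] * eta[ej])
  }
  logdet <- m * log(sigma2) - sum(log(E)) -
    sum(log(1 - lambda * structure$evals))
  logp_eta <- -0.5 * (m * log(2 * pi) + logdet + quad / sigma2)
  logp_mu <- stats::dnorm(mu, priors$mu_mean, sqrt(priors$mu_var),
                          log = TRUE)
  # unnormalized (the shape may be non-positive for the improper
  # uniform-on-sigma option, where the IG normalizer does not exist)
  logp_sig <- -(priors$sigma2_shape + 1) * log(sigma2) -
    priors$sigma2_rate / sigma2
  logp_lam <- -log(b[2L] - b[1L])
  loglik + logp_eta + logp_mu + logp_sig + logp_lam
}

#' Fit the Bayesian disease-mapping model
#'
#' Metropolis-within-Gibbs sampling of (mu, eta, sigma2, lambda): the
#' latent spatial effects are updated site by site, mu by random walk, and
#' sigma2 and lambda by random walks on log and logit-range scales (with
#' Jacobians).  Step sizes adapt toward a 44% acceptance rate during
#' burn-in only.  Chains are initialized at mu = log(sum C / sum E) with
#' eta = 0 and dispersed sigma2, and a split-chain potential scale
#' reduction diagnostic (R-hat) is reported for the three hyperparameters;
#' values above `rhat_warn` raise a warning rather than failing silently.
#'
#' @param counts a [counts_data()].
#' @param map a connected [region_map()].
#' @param priors a [car_priors()].
#' @param mcmc an [mcmc_settings()].
#' @param seed integer seed; chain c uses seed + c - 1.
#' @param rhat_warn convergence warning threshold (default 1.1).
#' @return An object of class `bym_fit`: list with posterior draw vectors
#'   `mu`, `sigma2`, `lambda`, matrices `eta` and `theta` (draws x m, theta
#'   = exp(mu + eta) being the relative risks), `chain` index, `accept`
#'   rates per chain, `rhat`, `lambda_bounds`, `region_id`, `counts`.
#' @export
fit_bym <- function(counts, map, priors = car_priors(),
                    mcmc = mcmc_settings(), seed = 1L, rhat_warn = 1.1) {
  st <- build_car_structure(counts, map)
  cn <- counts[match(map$region_id, counts$region_id), ]
  mu_init <- log(sum(cn$observed) / sum(cn$expected))
  sig_init <- c(0.1, 0.5, 0.05, 1)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    withr::with_seed(as.integer(seed) + ch - 1L, {
      car_mcmc_cpp(
        cn$observed, cn$expected,
        st$edges[, 1L], st$edges[, 2L], st$evals,
        L = 1L,
        mu_mean = priors$mu_mean, mu_var = priors$mu_var,
        sig_shape = priors$sigma2_shape, sig_rate = priors$sigma2_rate,
        lam_lo = st$lambda_bounds[1L], lam_hi = st$lambda_bounds[2L],
        n_iter = mcmc$n_iter, n_burn = mcmc$n_burn, thin = mcmc$thin,
        update_mu = TRUE, update_sigma = TRUE, update_lambda = TRUE,
        use_data = TRUE,
        mu0 = mu_init, sigma20 = sig_init[(ch - 1L) %% 4L + 1L],
        lambda0 = 0, eta0 = numeric(map$m), save_eta = TRUE)
    })
  })
  mu <- unlist(lapply(chains, `[[`, "mu"))
  sigma2 <- unlist(lapply(chains, `[[`, "sigma2"))
  lambda <- unlist(lapply(chains, `[[`, "lambda"))
  eta <- do.call(rbind, lapply(chains, `[[`, "eta"))
  colnames(eta) <- map$region_id
  nk <- length(chains[[1L]]$mu)
  chain <- rep(seq_len(mcmc$chains), each = nk)
  rhat <- c(mu = split_rhat(mu, chain),
            sigma2 = split_rhat(sigma2, chain),
            lambda = split_rhat(lambda, chain))
  if (any(is.finite(rhat) & rhat > rhat_warn)) {
    warning(sprintf(
      "possible non-convergence: split R-hat above %.2f for %s",
      rhat_warn, paste(names(rhat)[rhat > rhat_warn], collapse = ", ")))
  }
  theta <- exp(mu + eta)
  structure(list(mu = mu, sigma2 = sigma2, lambda = lambda,
                 eta = eta, theta = theta, chain = chain,
                 accept = lapply(chains, `[[`, "accept"),
                 rhat = rhat, lambda_bounds = st$lambda_bounds,
                 region_id = map$region_id, counts = cn,
                 settings = mcmc),
            class = "bym_fit")
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the split halves.
#'
#' @param x draw vector.
#' @param chain parallel chain index.
#' @return R-hat (>= 1 in expectation; NaN for constant draws).
#' @export
split_rhat <- function(x, chain) {
  parts <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  n <- min(lengths(parts))
  parts <- lapply(parts, `[`, seq_len(n))
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf(
    "bym_fit: %d regions, %d draws (%d chains)\n  posterior means: mu=%.3f sigma2=%.3f lambda=%.3f\n  split R-hat: %s\n",
    length(x$region_id), length(x$mu), max(x$chain),
    mean(x$mu), mean(x$sigma2), mean(x$lambda),
    paste(sprintf("%s=%.3f", names(x$rhat), x$rhat), collapse = " ")))
  invisible(x)
}

#' Per-region cluster calls from relative-risk draws
#'
#' Summarizes per-region relative-risk draws into an equal-tailed interval,
#' a posterior median, and an exceedance probability Pr(RR_i > b), then
#' calls a region a potential cluster when the interval's lower bound
#' strictly exceeds `threshold` (`criterion = "interval"`; the conventional
#' thresholds are 1.0, 1.5, 2.0) or when the exceedance probability
#' strictly exceeds `exceed_c` (`criterion = "exceedance"`).  Regions are
#' ranked by descending interval lower bound — rank 1 is the strongest
#' call — with ties broken by ascending region id; uncalled regions get
#' rank NA.
#'
#' @param draws an object with elements `theta` (draws x m matrix of RR
#'   draws) and `region_id`, e.g. a [fit_bym()] or [predict_rr()] result.
#' @param criterion `"interval"` or `"exceedance"`.
#' @param threshold interval lower-bound threshold (1.0, 1.5 or 2.0 in the
#'   standard reporting).
#' @param level interval level (default 0.95, equal-tailed).
#' @param exceed_b,exceed_c exceedance rule Pr(RR > b) > c.
#' @return A data frame of class `region_calls`: columns `region_id`,
#'   `rr_median`, `lower`, `upper`, `exceedance`, `called`, `rank`.
#' @export
call_regions <- function(draws, criterion = c("interval", "exceedance"),
                         threshold = 1.0, level = 0.95,
                         exceed_b = 1, exceed_c = 0.9) {
  criterion <- match.arg(criterion)
  th <- draws$theta
  a <- (1 - level) / 2
  qs <- apply(th, 2L, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  exceed <- colMeans(th > exceed_b)
  called <- if (criterion == "interval") qs[1L, ] > threshold
            else exceed > exceed_c
  out <- data.frame(region_id = draws$region_id,
                    rr_median = qs[2L, ], lower = qs[1L, ],
                    upper = qs[3L, ], exceedance = exceed,
                    called = called, rank = NA_integer_)
  ord <- order(-out$lower, .id_rank(out$region_id))
  out$rank[ord[called[ord]]] <- seq_len(sum(called))
  rownames(out) <- NULL
  class(out) <- c("region_calls", "data.frame")
  attr(out, "criterion") <- criterion
  attr(out, "threshold") <- threshold
  attr(out, "level") <- level
  out
}

#' Signed Poisson deviance residuals at posterior-mean fitted values
#'
#' r_i = sign(C_i - mu_i) * sqrt(2 [C_i log(C_i / mu_i) - (C_i - mu_i)])
#' with mu_i = E_i * posterior mean of theta_i and 0 log 0 := 0.  Large
#' absolute residuals flag regions the smoothed model cannot accommodate.
#'
#' @param draws an object with `theta` draws and `region_id`.
#' @param counts a [counts_data()].
#' @return Named numeric vector of residuals, one per region.
#' @export
deviance_residuals <- function(draws, counts) {
  counts <- counts[match(draws$region_id, counts$region_id), ]
  mu_hat <- counts$expected * colMeans(draws$theta)
  C <- counts$observed
  term <- ifelse(C == 0, 0, C * log(C / mu_hat)) - (C - mu_hat)
  r <- sign(C - mu_hat) * sqrt(pmax(2 * term, 0))
  names(r) <- draws$region_id
  r
}
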