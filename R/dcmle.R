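#' Data-cloning configuration
#'
#' @param clone_counts strictly increasing positive integers; the number of
#'   clones L at which the cloned posterior is sampled.  The variance of
#'   the cloned posterior of the hyperparameters shrinks like 1/L, so the
#'   largest L delivers the MLE and (after rescaling by L) its asymptotic
#'   covariance.
#' @param mcmc an [mcmc_settings()] applied at every L (a single chain per
#'   L by default; chains > 1 are pooled).
#' @param fix_lambda optional value at which the spatial autocorrelation is
#'   held fixed (e.g. 0 for independent effects); `NULL` estimates it.
#' @param seed integer seed.
#' @return A list of class `dc_config`.
#' @export
dc_config <- function(clone_counts = c(1L, 2L, 4L, 8L, 16L),
                      mcmc = mcmc_settings(chains = 1L, n_iter = 12000L,
                                           n_burn = 4000L, thin = 2L),
                      fix_lambda = NULL, seed = 1L) {
  cc <- as.integer(clone_counts)
  if (any(cc <= 0) || any(diff(cc) <= 0)) {
    stop("clone_counts must be strictly increasing positive integers")
  }
  structure(list(clone_counts = cc, mcmc = mcmc, fix_lambda = fix_lambda,
                 seed = as.integer(seed)),
            class = "dc_config")
}

#' Maximum likelihood for the disease-mapping model by data cloning
#'
#' Runs the Metropolis-within-Gibbs sampler on the cloned posterior: L
#' conditionally independent latent spatial-effect vectors, each attached
#' to its own copy of the count vector, sharing the hyperparameters
#' alpha = (mu, lambda, sigma2).  As L grows the marginal posterior of
#' alpha converges to a normal centred at the MLE with covariance 1/L
#' times the inverse Fisher information, so the point estimate is the
#' posterior mean at the largest L and the asymptotic covariance is L
#' times the posterior covariance there.  The convergence diagnostic is
#' the largest eigenvalue of the alpha posterior covariance at each L,
#' scaled by its value at the smallest L; when cloning is working it
#' tracks L_min / L.  Adequacy requires the scaled variance at the top L
#' to be below 1.5 * L_min / L_top and the sequence to be non-increasing.
#'
#' @param counts a [counts_data()].
#' @param map a connected [region_map()].
#' @param priors a [car_priors()] (their influence vanishes as L grows).
#' @param config a [dc_config()].
#' @return An object of class `mle_result`: `alpha_hat` (named vector),
#'   `vcov` (asymptotic covariance), `convergence` (data frame L, eigen,
#'   scaled), `adequate`, `alpha_draws` (draws at the top L),
#'   `lambda_bounds`, `fixed_lambda`, `region_id`, `counts`, `priors`.
#' @export
fit_dc <- function(counts, map, priors = car_priors(),
                   config = dc_config()) {
  st <- build_car_structure(counts, map)
  cn <- counts[match(map$region_id, counts$region_id), ]
  mu_init <- log(sum(cn$observed) / sum(cn$expected))
  est_lambda <- is.null(config$fix_lambda)
  lam0 <- if (est_lambda) 0 else config$fix_lambda
  mcmc <- config$mcmc
  fits <- lapply(seq_along(config$clone_counts), function(k) {
    Lk <- config$clone_counts[k]
    runs <- lapply(seq_len(mcmc$chains), function(ch) {
      withr::with_seed(config$seed + 97L * k + ch - 1L, {
        car_mcmc_cpp(
          cn$observed, cn$expected,
          st$edges[, 1L], st$edges[, 2L], st$evals,
          L = Lk,
          mu_mean = priors$mu_mean, mu_var = priors$mu_var,
          sig_shape = priors$sigma2_shape, sig_rate = priors$sigma2_rate,
          lam_lo = st$lambda_bounds[1L], lam_hi = st$lambda_bounds[2L],
          n_iter = mcmc$n_iter, n_burn = mcmc$n_burn, thin = mcmc$thin,
          update_mu = TRUE, update_sigma = TRUE, update_lambda = est_lambda,
          use_data = TRUE,
          mu0 = mu_init, sigma20 = 0.2, lambda0 = lam0,
          eta0 = numeric(map$m), save_eta = FALSE)
      })
    })
    a <- cbind(mu = unlist(lapply(runs, `[[`, "mu")),
               lambda = unlist(lapply(runs, `[[`, "lambda")),
               sigma2 = unlist(lapply(runs, `[[`, "sigma2")))
    if (!est_lambda) a <- a[, c("mu", "sigma2"), drop = FALSE]
    a
  })
  evs <- vapply(fits, function(a) max(eigen(stats::cov(a),
                                            symmetric = TRUE,
                                            only.values = TRUE)$values), 0)
  L <- config$clone_counts
  scaled <- evs / evs[1L]
  top <- length(L)
  # non-increasing up to 10% Monte Carlo slack, and near-1/L at the top
  adequate <- all(scaled[-1L] <= 1.1 * scaled[-top]) &&
    scaled[top] < 1.5 * L[1L] / L[top]
  a_top <- fits[[top]]
  alpha_hat <- colMeans(a_top)
  vcov <- L[top] * stats::cov(a_top)
  structure(list(alpha_hat = alpha_hat, vcov = vcov,
                 convergence = data.frame(L = L, eigen = evs,
                                          scaled = scaled),
                 adequate = adequate, alpha_draws = a_top,
                 lambda_bounds = st$lambda_bounds,
                 fixed_lambda = config$fix_lambda,
                 region_id = map$region_id, counts = cn, priors = priors),
            class = "mle_result")
}

#' @export
print.mle_result <- function(x, ...) {
  cat("mle_result (data cloning)\n  alpha_hat:",
      paste(sprintf("%s=%.4f", names(x$alpha_hat), x$alpha_hat),
            collapse = " "),
      sprintf("\n  adequate: %s (scaled variance at L=%d: %.4f)\n",
              x$adequate, max(x$convergence$L),
              x$convergence$scaled[nrow(x$convergence)]))
  invisible(x)
}

#' Relative-risk prediction by composite sampling
#'
#' Frequentist prediction of the latent region-level relative risks that
#' propagates the sampling variability of the hyperparameter estimates:
#' draw alpha* from a multivariate normal centred at the MLE with the
#' asymptotic covariance (draws outside the admissible domain — sigma2 <=
#' 0 or lambda beyond its bounds — are rejected and redrawn), then sample
#' the conditional posterior of the relative risks given the data and
#' alpha* by MCMC with the hyperparameters held fixed; the pooled draws
#' define prediction intervals.  With a degenerate (zero) covariance this
#' reduces to the naive plug-in conditional at the MLE.
#'
#' @param counts a [counts_data()].
#' @param map a connected [region_map()].
#' @param mle an [fit_dc()] result; if `mle$adequate` is FALSE an error is
#'   raised unless `override = TRUE`.
#' @param n_alpha number of hyperparameter draws.
#' @param n_burn,n_keep,thin conditional-chain settings per alpha draw.
#' @param seed integer seed.
#' @param override proceed despite an inadequate clone diagnostic.
#' @return An object of class `rr_prediction`: `theta` (pooled draws x m),
#'   `region_id`, `alpha_draws`, `rejection_rate`, `counts`.
#' @export
predict_rr <- function(counts, map, mle, n_alpha = 200L, n_burn = 300L,
                       n_keep = 5L, thin = 10L, seed = 1L,
                       override = FALSE) {
  if (!isTRUE(mle$adequate) && !override) {
    stop("clone diagnostic is inadequate; rerun fit_dc with larger clone_counts or set override = TRUE")
  }
  st <- build_car_structure(counts, map)
  cn <- counts[match(map$region_id, counts$region_id), ]
  p <- length(mle$alpha_hat)
  ev <- eigen(mle$vcov, symmetric = TRUE)
  rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  est_lambda <- is.null(mle$fixed_lambda)
  lamfix <- if (est_lambda) NA_real_ else mle$fixed_lambda
  b <- mle$lambda_bounds

  withr::with_seed(seed, {
    alphas <- matrix(NA_real_, n_alpha, p,
                     dimnames = list(NULL, names(mle$alpha_hat)))
    tries <- 0L
    got <- 0L
    while (got < n_alpha && tries < 40L * n_alpha) {
      tries <- tries + 1L
      a <- mle$alpha_hat + as.numeric(rot %*% stats::rnorm(p))
      lam <- if (est_lambda) a[["lambda"]] else lamfix
      if (a[["sigma2"]] > 0 && lam > b[1L] && lam < b[2L]) {
        got <- got + 1L
        alphas[got, ] <- a
      }
    }
    if (got < n_alpha) stop("could not draw admissible hyperparameters")
    rej <- 1 - n_alpha / tries
    if (rej > 0.5) {
      warning(sprintf(
        "%.0f%% of hyperparameter draws fell outside the admissible (lambda, sigma2) domain; the MLE is near a boundary",
        100 * rej))
    }
    theta <- do.call(rbind, lapply(seq_len(n_alpha), function(k) {
      a <- alphas[k, ]
      lam <- if (est_lambda) a[["lambda"]] else lamfix
      run <- car_mcmc_cpp(
        cn$observed, cn$expected,
        st$edges[, 1L], st$edges[, 2L], st$evals,
        L = 1L,
        mu_mean = 0, mu_var = 1, sig_shape = 1, sig_rate = 1,
        lam_lo = b[1L], lam_hi = b[2L],
        n_iter = n_burn + n_keep * thin, n_burn = n_burn, thin = thin,
        update_mu = FALSE, update_sigma = FALSE, update_lambda = FALSE,
        use_data = TRUE,
        mu0 = a[["mu"]], sigma20 = a[["sigma2"]], lambda0 = lam,
        eta0 = numeric(map$m), save_eta = TRUE)
      exp(a[["mu"]] + run$eta)
    }))
  })
  colnames(theta) <- map$region_id
  structure(list(theta = theta, region_id = map$region_id,
                 alpha_draws = alphas, rejection_rate = rej, counts = cn),
            class = "rr_prediction")
}

#' Cross-method concordance on a common dataset
#'
#' Assembles the ranked-region comparison across the four methods on one
#' dataset: for the scan statistics, each region's cluster rank (the rank
#' of the reported non-overlapping cluster containing it, provided that
#' cluster is significant at `scan_alpha`); for the model-based methods,
#' the per-region rank under each interval lower-bound threshold.  Also
#' reports the Spearman correlation between the Bayesian and MLE interval
#' lower bounds over all regions (the rank-concordance the two methods are
#' expected to share) and the Jaccard overlap of their called sets at each
#' threshold.
#'
#' @param css,fss [scan()] results (either may be NULL).
#' @param bym a [fit_bym()] result.
#' @param mle an [rr_prediction] from [predict_rr()].
#' @param thresholds interval lower-bound thresholds.
#' @param level interval level.
#' @param scan_alpha significance level for counting a scan cluster.
#' @return An object of class `method_comparison`: list with `table` (one
#'   row per region), `spearman`, `overlap` (per threshold), `calls`
#'   (the underlying region_calls per method and threshold).
#' @export
compare_methods <- function(css = NULL, fss = NULL, bym, mle,
                            thresholds = c(1, 1.5, 2), level = 0.95,
                            scan_alpha = 0.05) {
  ids <- bym$region_id
  if (!setequal(ids, mle$region_id)) stop("mismatched region sets")
  tab <- data.frame(region_id = ids)
  scan_rank <- function(sc) {
    r <- rep(NA_integer_, length(ids))
    if (is.null(sc)) return(r)
    for (k in seq_len(nrow(sc))) {
      if (sc$p_value[k] <= scan_alpha) {
        reg <- strsplit(sc$regions[k], ";", fixed = TRUE)[[1L]]
        r[match(reg, ids)] <- sc$rank[k]
      }
    }
    r
  }
  tab$css <- scan_rank(css)
  tab$fss <- scan_rank(fss)
  calls <- list()
  for (th in thresholds) {
    cb <- call_regions(bym, threshold = th, level = level)
    cm <- call_regions(mle, threshold = th, level = level)
    tab[[sprintf("bym_rr_gt_%.1f", th)]] <- cb$rank[match(ids, cb$region_id)]
    tab[[sprintf("mle_rr_gt_%.1f", th)]] <- cm$rank[match(ids, cm$region_id)]
    calls[[sprintf("rr_gt_%.1f", th)]] <- list(bym = cb, mle = cm)
  }
  cb1 <- calls[[1L]]$bym
  cm1 <- calls[[1L]]$mle
  lw2 <- cm1$lower[match(cb1$region_id, cm1$region_id)]
  spearman <- if (stats::sd(cb1$lower) == 0 || stats::sd(lw2) == 0) {
    NA_real_   # a constant ranking has no rank correlation
  } else {
    stats::cor(cb1$lower, lw2, method = "spearman")
  }
  overlap <- vapply(calls, function(cl) {
    a <- cl$bym$region_id[cl$bym$called]
    b <- cl$mle$region_id[cl$mle$called]
    if (length(a) == 0L && length(b) == 0L) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  structure(list(table = tab, spearman = spearman, overlap = overlap,
                 calls = calls),
            class = "method_comparison")
}
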