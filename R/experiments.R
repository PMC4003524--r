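#' Simulation experiments
#'
#' The `experiment_*` functions run the package's calibration, power,
#' correctness and recovery studies end to end from a single seed.  They
#' back the analysis scripts and the acceptance checks; each returns the
#' headline quantity plus the per-replicate detail.
#'
#' @name experiments
NULL

# deterministic contiguous cluster: breadth-first growth from the region
# closest to the map's centroid (or from `start`)
.contiguous_cluster <- function(map, size, start = NULL) {
  if (is.null(start)) {
    ctr <- colMeans(map$xy)
    start <- which.min((map$xy[, 1L] - ctr[1L])^2 +
                         (map$xy[, 2L] - ctr[2L])^2)
  }
  sel <- start
  while (length(sel) < size) {
    fringe <- setdiff(sort(unique(unlist(map$adj[sel]))), sel)
    if (length(fringe) == 0L) break
    sel <- c(sel, fringe[seq_len(min(length(fringe), size - length(sel)))])
  }
  map$region_id[sort(sel)]
}

# fresh sub-seeds derived inside a seeded context
.subseeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Null calibration of the circular scan statistic
#'
#' Simulates null datasets (C_i ~ Poisson(E_i), no cluster anywhere) on a
#' jittered-lattice map with fixed expected counts, scans each with the
#' circular statistic, and reports the fraction of datasets whose
#' most-likely-cluster Monte Carlo p-value falls at or below `alpha`.
#' Under a well-calibrated test this fraction matches `alpha` up to
#' binomial error (the Monte Carlo p-value is slightly super-uniform by
#' construction, pulling the rate marginally below `alpha`).
#'
#' @param n_datasets number of simulated null datasets.
#' @param n_mc Monte Carlo null replicates per scan.
#' @param m number of regions.
#' @param e_range range of the per-region expected counts (drawn uniformly
#'   once and held fixed across datasets).
#' @param J maximum window size.
#' @param alpha nominal test level.
#' @param seed integer seed.
#' @return List with `reject_rate`, `p_values`, `alpha`, `n_datasets`.
#' @export
experiment_scan_calibration <- function(n_datasets = 500L, n_mc = 999L,
                                        m = 30L, e_range = c(20, 200),
                                        J = 15L, alpha = 0.05, seed = 1L) {
  seeds <- .subseeds(seed, 2L * n_datasets + 2L)
  map <- make_map(m, "jittered_lattice", seed = seeds[1L])
  E <- withr::with_seed(seeds[2L],
                        stats::runif(m, e_range[1L], e_range[2L]))
  ord <- nearest_neighbour_order(map)
  cfg0 <- scan_config("circular", J = J, n_monte_carlo = n_mc)
  wins <- circular_windows(map, ord, cfg0)
  pv <- vapply(seq_len(n_datasets), function(i) {
    C <- withr::with_seed(seeds[2L + i], stats::rpois(m, E))
    if (sum(C) == 0L) return(1)
    # the Monte Carlo reference stream must be independent of the data
    cfg <- scan_config("circular", J = J, n_monte_carlo = n_mc,
                       seed = seeds[2L + n_datasets + i])
    res <- scan(counts_data(map$region_id, C, E), map, cfg, windows = wins)
    res$p_value[1L]
  }, 0)
  list(reject_rate = mean(pv <= alpha), p_values = pv, alpha = alpha,
       n_datasets = n_datasets)
}

#' Scan power under a planted contiguous cluster
#'
#' Plants a contiguous cluster of `cluster_size` regions at relative risk
#' `rr` on a jittered-lattice map with expected counts near `e_level`,
#' simulates Poisson counts, and scans with both the circular and flexible
#' statistics.  A dataset counts as a success for a method when its rank-1
#' window overlaps the true cluster and its p-value is at most `alpha`.
#'
#' @param n_datasets number of simulated datasets.
#' @param n_mc Monte Carlo replicates per scan.
#' @param m number of regions.
#' @param cluster_size planted cluster size.
#' @param rr within-cluster relative risk.
#' @param e_range range of per-region expected counts.
#' @param J maximum window size for both statistics.
#' @param alpha significance level for a success.
#' @param seed integer seed.
#' @return List with `power_css`, `power_fss`, `truth` (region ids),
#'   per-dataset logical vectors `hit_css`, `hit_fss`, and the window
#'   counts used.
#' @export
experiment_scan_power <- function(n_datasets = 100L, n_mc = 999L, m = 30L,
                                  cluster_size = 7L, rr = 3,
                                  e_range = c(40, 60), J = 10L,
                                  alpha = 0.05, seed = 2L) {
  seeds <- .subseeds(seed, 2L * n_datasets + 2L)
  map <- make_map(m, "jittered_lattice", seed = seeds[1L])
  E <- withr::with_seed(seeds[2L],
                        stats::runif(m, e_range[1L], e_range[2L]))
  truth <- .contiguous_cluster(map, cluster_size)
  rr_vec <- ifelse(map$region_id %in% truth, rr, 1)
  ord <- nearest_neighbour_order(map)
  cfgc <- scan_config("circular", J = J, n_monte_carlo = n_mc)
  cfgf <- scan_config("flexible", J = J, n_monte_carlo = n_mc)
  win_c <- circular_windows(map, ord, cfgc)
  win_f <- flexible_windows(map, ord, cfgf)
  hit <- function(res) {
    top <- strsplit(res$regions[1L], ";", fixed = TRUE)[[1L]]
    length(intersect(top, truth)) > 0L && res$p_value[1L] <= alpha
  }
  hit_css <- logical(n_datasets)
  hit_fss <- logical(n_datasets)
  for (i in seq_len(n_datasets)) {
    C <- withr::with_seed(seeds[2L + i], stats::rpois(m, E * rr_vec))
    cd <- counts_data(map$region_id, C, E)
    cfgc$seed <- cfgf$seed <- seeds[2L + n_datasets + i]
    hit_css[i] <- hit(scan(cd, map, cfgc, windows = win_c))
    hit_fss[i] <- hit(scan(cd, map, cfgf, windows = win_f))
  }
  list(power_css = mean(hit_css), power_fss = mean(hit_fss),
       truth = truth, hit_css = hit_css, hit_fss = hit_fss,
       n_windows = c(circular = length(win_c), flexible = length(win_f)))
}

# brute-force flexible-window oracle: every subset of the anchor's
# J-nearest-neighbour set that contains the anchor and is connected
.brute_force_flexible <- function(map, ord, J) {
  g <- igraph::graph_from_edgelist(map$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, map$m - igraph::vcount(g)))
  keys <- character(0)
  for (i in seq_len(map$m)) {
    cand <- ord[i, seq_len(min(J, map$m))]
    others <- setdiff(cand, i)
    for (sz in 0:length(others)) {
      combos <- if (sz == 0L) list(integer(0)) else
        lapply(utils::combn(seq_along(others), sz, simplify = FALSE),
               function(ix) others[ix])   # combn(x, m) mis-handles scalar x
      for (cs in combos) {
        if (length(cs) + 1L > J) next
        sub <- c(i, cs)
        if (igraph::is_connected(igraph::induced_subgraph(g, sub))) {
          keys <- c(keys, paste(sort(sub), collapse = ","))
        }
      }
    }
  }
  sort(unique(keys))
}

#' Flexible-window enumeration against the brute-force oracle
#'
#' For random small connected maps, compares [flexible_windows()] with
#' exhaustive subset enumeration filtered by anchor membership and graph
#' connectivity.  Agreement must be exact (set-of-sets equality).
#'
#' @param n_maps number of random maps.
#' @param m_range,J_range ranges to draw the map size and J from.
#' @param seed integer seed.
#' @return List with `n_agree`, `n_maps`, `all_equal`.
#' @export
experiment_fss_oracle <- function(n_maps = 50L, m_range = c(6L, 12L),
                                  J_range = c(2L, 6L), seed = 3L) {
  n_maps <- as.integer(n_maps)
  seeds <- .subseeds(seed, n_maps)
  agree <- logical(n_maps)
  for (k in seq_len(n_maps)) {
    pars <- withr::with_seed(seeds[k], {
      m <- sample(m_range[1L]:m_range[2L], 1L)
      J <- sample(J_range[1L]:J_range[2L], 1L)
      extra <- sample.int(m, 2L * m, replace = TRUE)
      list(m = m, J = J, extra = extra)
    })
    map <- make_map(pars$m, "jittered_lattice", seed = seeds[k])
    # densify with a few random chords so shapes beyond the lattice occur
    ex <- matrix(pars$extra, ncol = 2L)
    ex <- ex[ex[, 1L] != ex[, 2L], , drop = FALSE]
    map <- region_map(map$region_id, map$xy,
                      rbind(matrix(map$region_id[map$edges], ncol = 2L),
                            matrix(map$region_id[ex], ncol = 2L)))
    ord <- nearest_neighbour_order(map)
    cfg <- scan_config("flexible", J = pars$J)
    got <- vapply(flexible_windows(map, ord, cfg),
                  function(w) paste(w, collapse = ","), "")
    want <- .brute_force_flexible(map, ord, pars$J)
    agree[k] <- identical(sort(got), want)
  }
  list(n_agree = sum(agree), n_maps = n_maps, all_equal = all(agree))
}

#' Log likelihood-ratio statistic against a Poisson-density oracle
#'
#' Checks [log_likelihood_ratio()] on random (C_in, E_in, N, E_total)
#' configurations against an independent evaluation built from Poisson log
#' densities: the statistic equals the log-likelihood difference between
#' the two-cell model with rates fitted inside/outside the window and the
#' single-rate null, so it can be recomputed with `dpois` at the fitted
#' rates.  Also verifies the indicator: 0 whenever C_in <= E_in.
#'
#' @param n number of random configurations.
#' @param seed integer seed.
#' @return List with `max_rel_err`, `indicator_ok`, `n`.
#' @export
experiment_lr_check <- function(n = 1000L, seed = 4L) {
  cfg <- withr::with_seed(seed, {
    N <- sample(50:5000, n, replace = TRUE)
    Etot <- N * stats::runif(n, 0.8, 1.25)
    Ein <- Etot * stats::runif(n, 0.02, 0.9)
    Cin <- vapply(seq_len(n), function(i) {
      stats::rbinom(1L, N[i], min(0.95, Ein[i] / Etot[i] *
                                    stats::runif(1L, 0.5, 3)))
    }, 0L)
    list(N = N, Etot = Etot, Ein = Ein, Cin = Cin)
  })
  got <- log_likelihood_ratio(cfg$Cin, cfg$Ein, cfg$N, cfg$Etot)
  # direct term-by-term arithmetic through a different numerical path
  # (expanded log differences rather than logs of ratios)
  direct <- vapply(seq_len(n), function(i) {
    C <- cfg$Cin[i]; E <- cfg$Ein[i]; N <- cfg$N[i]; Et <- cfg$Etot[i]
    if (C <= E) return(0)
    t_in <- C * (log(C) - log(E))
    t_out <- if (C == N) 0 else (N - C) * (log(N - C) - log(Et - E))
    t_in + t_out - N * (log(N) - log(Et))
  }, 0)
  # second, structurally independent route: log-likelihood difference of
  # the fitted two-rate model vs the single-rate null via dpois
  dpois_oracle <- vapply(seq_len(n), function(i) {
    C <- cfg$Cin[i]; E <- cfg$Ein[i]; N <- cfg$N[i]; Et <- cfg$Etot[i]
    if (C <= E) return(0)
    r1 <- C / E; r0 <- (N - C) / (Et - E); r <- N / Et
    alt <- stats::dpois(C, r1 * E, log = TRUE) +
      stats::dpois(N - C, r0 * (Et - E), log = TRUE)
    null <- stats::dpois(C, r * E, log = TRUE) +
      stats::dpois(N - C, r * (Et - E), log = TRUE)
    alt - null
  }, 0)
  # relative error with a unit floor on the denominator: statistics near
  # zero arise from near-total cancellation of thousand-sized terms and
  # no two evaluation orders agree to a strict relative tolerance there
  relerr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1))
  list(max_rel_err = relerr(got, direct),
       max_rel_err_dpois = relerr(got, dpois_oracle),
       indicator_ok = all(got[cfg$Cin <= cfg$Ein] == 0), n = n)
}

#' Positive definiteness of the CAR covariance across its admissible range
#'
#' On random small maps, draws autocorrelation values strictly inside the
#' eigenvalue-derived bounds and checks that
#' sigma2 (I - lambda D)^{-1} P is symmetric positive definite; values 5%
#' beyond either bound must fail the check.
#'
#' @param n_checks number of (map, lambda) draws inside the bounds.
#' @param m regions per random map.
#' @param seed integer seed.
#' @return List with `n_inside_pd`, `n_checks`, `n_outside_fail`,
#'   `n_outside`.
#' @export
experiment_car_pd <- function(n_checks = 50L, m = 10L, seed = 5L) {
  n_checks <- as.integer(n_checks)
  seeds <- .subseeds(seed, n_checks)
  inside_pd <- logical(n_checks)
  outside_fail <- logical(2L * n_checks)
  is_pd <- function(S) {
    asym <- max(abs(S - t(S))) / max(abs(S))
    if (asym > 1e-8) return(FALSE)
    min(eigen((S + t(S)) / 2, symmetric = TRUE,
              only.values = TRUE)$values) > 0
  }
  for (k in seq_len(n_checks)) {
    map <- make_map(m, "jittered_lattice", seed = seeds[k])
    prep <- withr::with_seed(seeds[k], {
      E <- stats::runif(m, 5, 500)
      u <- stats::runif(1L, 0.02, 0.98)
      list(E = E, u = u)
    })
    st <- build_car_structure(
      counts_data(map$region_id, rep(1L, m), prep$E), map)
    b <- st$lambda_bounds
    lam_in <- b[1L] + prep$u * (b[2L] - b[1L])
    inside_pd[k] <- is_pd(car_covariance(st, 0.7, lam_in))
    outside_fail[2L * k - 1L] <- !is_pd(car_covariance(st, 0.7, 1.05 * b[1L]))
    outside_fail[2L * k] <- !is_pd(car_covariance(st, 0.7, 1.05 * b[2L]))
  }
  list(n_inside_pd = sum(inside_pd), n_checks = n_checks,
       n_outside_fail = sum(outside_fail), n_outside = 2L * n_checks)
}

# simulate (eta, C) from the disease-mapping model on a prepared structure
.simulate_car_data <- function(st, mu, sigma2, lambda, seed) {
  S <- car_covariance(st, sigma2, lambda)
  R <- chol((S + t(S)) / 2)
  withr::with_seed(seed, {
    eta <- as.numeric(t(R) %*% stats::rnorm(st$m))
    C <- stats::rpois(st$m, st$E * exp(mu + eta))
  })
  list(eta = eta, C = C)
}

#' Parameter recovery for the Bayesian disease-mapping model
#'
#' Simulates datasets from the Poisson / proper-CAR model at known
#' (mu, sigma2, lambda) and refits each with [fit_bym()]; reports the
#' coverage of the 95% equal-tailed credible interval for mu and the mean
#' relative bias of the posterior mean of sigma2.
#'
#' @param n_datasets number of simulated datasets.
#' @param m number of regions.
#' @param mu,sigma2 true values.
#' @param lambda_frac true lambda as a fraction of the upper bound.
#' @param e_range range of the fixed expected counts.
#' @param mcmc an [mcmc_settings()] (reduced lengths are adequate here).
#' @param priors a [car_priors()]; the default is the uniform-on-sigma
#'   dispersion prior, under which the posterior mean of a
#'   weakly-identified variance component is approximately unbiased (the
#'   IG(eps, eps) alternative concentrates near zero and drags it down).
#' @param seed integer seed.
#' @return List with `coverage_mu`, `sigma2_rel_bias`, and per-dataset
#'   vectors `covered`, `sigma2_mean`, `mu_mean`.
#' @export
experiment_bym_recovery <- function(n_datasets = 100L, m = 30L, mu = 0.2,
                                    sigma2 = 0.3, lambda_frac = 0.5,
                                    e_range = c(50, 150),
                                    mcmc = mcmc_settings(chains = 2L,
                                                         n_iter = 4000L,
                                                         n_burn = 2000L,
                                                         thin = 2L),
                                    priors = car_priors(sigma2_shape = -0.25,
                                                        sigma2_rate = 0),
                                    seed = 6L) {
  seeds <- .subseeds(seed, 3L * n_datasets)
  covered <- logical(n_datasets)
  s2_mean <- mu_mean <- numeric(n_datasets)
  lambda <- NA_real_
  for (i in seq_len(n_datasets)) {
    # a fresh design per dataset, so the study averages over maps and
    # expected-count configurations instead of inheriting one draw
    map <- make_map(m, "jittered_lattice", seed = seeds[i])
    E <- withr::with_seed(seeds[n_datasets + i],
                          stats::runif(m, e_range[1L], e_range[2L]))
    st <- build_car_structure(counts_data(map$region_id, rep(1L, m), E),
                              map)
    lambda <- lambda_frac * st$lambda_bounds[2L]
    sim <- .simulate_car_data(st, mu, sigma2, lambda, seeds[n_datasets + i])
    cd <- counts_data(map$region_id, sim$C, E)
    fit <- suppressWarnings(
      fit_bym(cd, map, priors = priors, mcmc = mcmc,
              seed = seeds[2L * n_datasets + i]))
    ci <- stats::quantile(fit$mu, c(0.025, 0.975), names = FALSE)
    covered[i] <- ci[1L] <= mu && mu <= ci[2L]
    s2_mean[i] <- mean(fit$sigma2)
    mu_mean[i] <- mean(fit$mu)
  }
  list(coverage_mu = mean(covered),
       sigma2_rel_bias = mean(s2_mean) / sigma2 - 1,
       covered = covered, sigma2_mean = s2_mean, mu_mean = mu_mean,
       truth = c(mu = mu, sigma2 = sigma2, lambda = lambda))
}

#' Data-cloning degeneracy: posterior variance shrinks like 1/L
#'
#' On one dataset simulated from the disease-mapping model, fits the
#' cloned posterior at each clone count and regresses the log of the
#' scaled largest-eigenvalue posterior variance of the hyperparameters on
#' log L; the cloned posterior collapses onto the MLE at rate 1/L, so the
#' slope should be close to -1.
#'
#' @param clone_counts clone counts to fit.
#' @param m number of regions.
#' @param mu,sigma2,lambda_frac,e_range simulation truth as in
#'   [experiment_bym_recovery()].
#' @param mcmc per-L [mcmc_settings()].
#' @param priors a [car_priors()] (uniform-on-sigma by default, so the
#'   L = 1 reference posterior that the variance sequence is scaled by is
#'   likelihood- rather than prior-shaped).
#' @param seed integer seed.
#' @return List with `slope`, `convergence` (per-L table), `fit` (the
#'   [fit_dc()] result).
#' @export
experiment_dc_degeneracy <- function(clone_counts = c(1L, 2L, 4L, 8L, 16L),
                                     m = 100L, mu = 0.2, sigma2 = 2,
                                     lambda_frac = 0.5,
                                     e_range = c(50, 150),
                                     mcmc = mcmc_settings(chains = 1L,
                                                          n_iter = 14000L,
                                                          n_burn = 4000L,
                                                          thin = 2L),
                                     priors = car_priors(sigma2_shape = -0.25,
                                                         sigma2_rate = 0),
                                     seed = 7L) {
  seeds <- .subseeds(seed, 3L)
  map <- make_map(m, "jittered_lattice", seed = seeds[1L])
  E <- withr::with_seed(seeds[2L],
                        stats::runif(m, e_range[1L], e_range[2L]))
  st <- build_car_structure(counts_data(map$region_id, rep(1L, m), E), map)
  sim <- .simulate_car_data(st, mu, sigma2,
                            lambda_frac * st$lambda_bounds[2L], seeds[3L])
  cd <- counts_data(map$region_id, sim$C, E)
  fit <- fit_dc(cd, map, priors = priors,
                config = dc_config(clone_counts, mcmc = mcmc,
                                   seed = seeds[3L]))
  cv <- fit$convergence
  slope <- unname(stats::coef(stats::lm(log(cv$scaled) ~ log(cv$L)))[2L])
  list(slope = slope, convergence = cv, fit = fit)
}

# marginal log-likelihood of the lambda = 0 model with the latent effects
# integrated out by adaptive quadrature (oracle for the data-cloning MLE)
.quadrature_loglik <- function(par, C, E) {
  mu <- par[1L]
  sigma2 <- exp(par[2L])
  sum(vapply(seq_along(C), function(i) {
    sd_i <- sqrt(sigma2 / E[i])
    logf <- function(eta) {
      stats::dpois(C[i], E[i] * exp(mu + eta), log = TRUE) +
        stats::dnorm(eta, 0, sd_i, log = TRUE)
    }
    # integrate in log space with an offset so the integrand never
    # underflows while the optimizer explores poor parameter values
    K <- max(logf(seq(-8 * sd_i, 8 * sd_i, length.out = 65L)))
    val <- stats::integrate(function(e) exp(logf(e) - K),
                            -8 * sd_i, 8 * sd_i, rel.tol = 1e-10)$value
    K + log(val)
  }, 0))
}

#' Data-cloning MLE against a quadrature oracle
#'
#' On a small dataset with the spatial autocorrelation fixed at 0 (so the
#' latent effects are independent and the marginal likelihood factorizes
#' into one-dimensional integrals), compares the data-cloning estimates of
#' (mu, sigma2) with direct numerical maximization of the
#' quadrature-integrated likelihood.  Differences are reported in units of
#' the combined standard error sqrt(se_dc^2 + se_quad^2).
#'
#' @param m number of regions in the toy map.
#' @param mu,sigma2 simulation truth.
#' @param E expected counts of the toy regions.
#' @param clone_counts clone counts for [fit_dc()].
#' @param mcmc per-L [mcmc_settings()].
#' @param seed integer seed.
#' @return List with `z_mu`, `z_sigma2` (absolute standardized
#'   differences), `dc` (estimates + SEs), `quad` (oracle estimates +
#'   SEs), `fit`.
#' @export
experiment_dc_oracle <- function(m = 4L, mu = 0.3, sigma2 = 0.4,
                                 E = c(30, 50, 80, 120),
                                 clone_counts = c(1L, 2L, 4L, 8L, 16L),
                                 mcmc = mcmc_settings(chains = 1L,
                                                      n_iter = 16000L,
                                                      n_burn = 4000L,
                                                      thin = 2L),
                                 seed = 8L) {
  stopifnot(length(E) == m)
  map <- make_map(m, "lattice", seed = 1L)
  sim <- withr::with_seed(seed, {
    eta <- stats::rnorm(m, 0, sqrt(sigma2 / E))
    stats::rpois(m, E * exp(mu + eta))
  })
  cd <- counts_data(map$region_id, sim, E)
  fit <- fit_dc(cd, map,
                priors = car_priors(sigma2_shape = -0.25, sigma2_rate = 0),
                config = dc_config(clone_counts, mcmc = mcmc,
                                   fix_lambda = 0, seed = seed))
  opt <- stats::optim(c(0, log(0.2)), function(p) {
    -.quadrature_loglik(p, cd$observed, cd$expected)
  }, method = "L-BFGS-B", lower = c(-5, -12), upper = c(5, 5),
  hessian = TRUE)
  vc <- solve(opt$hessian)            # (mu, log sigma2) scale
  q_mu <- opt$par[1L]
  q_s2 <- exp(opt$par[2L])
  q_se <- c(mu = sqrt(vc[1L, 1L]),
            sigma2 = q_s2 * sqrt(vc[2L, 2L]))  # delta method
  d_se <- sqrt(diag(fit$vcov))
  z_mu <- abs(fit$alpha_hat[["mu"]] - q_mu) /
    sqrt(d_se[["mu"]]^2 + q_se[["mu"]]^2)
  z_s2 <- abs(fit$alpha_hat[["sigma2"]] - q_s2) /
    sqrt(d_se[["sigma2"]]^2 + q_se[["sigma2"]]^2)
  list(z_mu = z_mu, z_sigma2 = z_s2,
       dc = list(estimate = fit$alpha_hat, se = d_se),
       quad = list(estimate = c(mu = q_mu, sigma2 = q_s2), se = q_se),
       fit = fit)
}

#' Concordance of the Bayesian and data-cloning cluster rankings
#'
#' On planted-cluster datasets, fits both the Bayesian model and the
#' data-cloning MLE with relative-risk prediction, and measures the
#' Spearman correlation between their per-region interval lower bounds
#' (the statistic both methods rank by).  Also records, per dataset and
#' method, whether the number of called regions is non-increasing across
#' the thresholds 1.0, 1.5, 2.0 — which it must be, since raising the bar
#' can only drop calls.
#'
#' @param n_datasets number of planted-cluster datasets.
#' @param m number of regions.
#' @param cluster_size,rr planted cluster size and relative risk.
#' @param e_range range of the fixed expected counts.
#' @param mcmc [mcmc_settings()] for the Bayesian fit.
#' @param clone_counts clone counts for the MLE fit.
#' @param dc_mcmc per-L [mcmc_settings()] for cloning.
#' @param n_alpha hyperparameter draws in [predict_rr()].
#' @param seed integer seed.
#' @return List with `spearman_mean`, `spearman` (per dataset),
#'   `monotone_fraction`, `overlap_mean` (Jaccard at threshold 1.0) and
#'   the planted truth.
#' @export
experiment_concordance <- function(n_datasets = 20L, m = 30L,
                                   cluster_size = 7L, rr = 3,
                                   e_range = c(40, 60),
                                   mcmc = mcmc_settings(chains = 2L,
                                                        n_iter = 6000L,
                                                        n_burn = 3000L,
                                                        thin = 3L),
                                   clone_counts = c(1L, 2L, 4L, 8L),
                                   dc_mcmc = mcmc_settings(chains = 1L,
                                                           n_iter = 8000L,
                                                           n_burn = 3000L,
                                                           thin = 2L),
                                   n_alpha = 150L, seed = 9L) {
  seeds <- .subseeds(seed, 2L * n_datasets + 2L)
  map <- make_map(m, "jittered_lattice", seed = seeds[1L])
  E <- withr::with_seed(seeds[2L],
                        stats::runif(m, e_range[1L], e_range[2L]))
  truth <- .contiguous_cluster(map, cluster_size)
  rr_vec <- ifelse(map$region_id %in% truth, rr, 1)
  rho <- numeric(n_datasets)
  mono <- logical(2L * n_datasets)
  jac <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    C <- withr::with_seed(seeds[2L + i], stats::rpois(m, E * rr_vec))
    cd <- counts_data(map$region_id, C, E)
    fseed <- seeds[2L + n_datasets + i]
    pri <- car_priors(sigma2_shape = -0.25, sigma2_rate = 0)
    bym <- suppressWarnings(fit_bym(cd, map, priors = pri, mcmc = mcmc,
                                    seed = fseed))
    dc <- fit_dc(cd, map, priors = pri,
                 config = dc_config(clone_counts, mcmc = dc_mcmc,
                                    seed = fseed))
    mle <- predict_rr(cd, map, dc, n_alpha = n_alpha,
                      seed = fseed, override = TRUE)
    cmp <- compare_methods(bym = bym, mle = mle)
    rho[i] <- cmp$spearman
    jac[i] <- cmp$overlap[["rr_gt_1.0"]]
    n_called <- function(cl_set, method) {
      vapply(cmp$calls, function(cl) sum(cl[[method]]$called), 0L)
    }
    mono[2L * i - 1L] <- all(diff(n_called(cmp$calls, "bym")) <= 0L)
    mono[2L * i] <- all(diff(n_called(cmp$calls, "mle")) <= 0L)
  }
  list(spearman_mean = mean(rho), spearman = rho,
       monotone_fraction = mean(mono), overlap_mean = mean(jac),
       truth = truth)
}
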