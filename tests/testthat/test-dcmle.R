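test_that("clone counts must be strictly increasing", {
  expect_error(dc_config(c(1, 1, 2)), "strictly increasing")
  expect_error(dc_config(c(4, 2)), "strictly increasing")
  expect_silent(dc_config(c(1L, 2L, 8L)))
})

test_that("a single clone reproduces the Bayesian posterior of the
           hyperparameters", {
  sd <- small_dataset(m = 12, rr_regions = c("3", "8"), rr = 2.5)
  pri <- car_priors(sigma2_shape = -0.5, sigma2_rate = 0)
  bym <- suppressWarnings(
    fit_bym(sd$counts, sd$map, priors = pri,
            mcmc = mcmc_settings(chains = 2, n_iter = 10000,
                                 n_burn = 4000, thin = 2), seed = 1))
  dc <- fit_dc(sd$counts, sd$map, priors = pri,
               config = dc_config(1L,
                                  mcmc = mcmc_settings(chains = 2,
                                                       n_iter = 10000,
                                                       n_burn = 4000,
                                                       thin = 2),
                                  seed = 5))
  a <- dc$alpha_draws
  # same posterior sampled by the same kernel: means agree within a
  # generous multiple of the Monte Carlo error
  tol <- function(x) 8 * stats::sd(x) / sqrt(100)
  expect_lt(abs(mean(a[, "mu"]) - mean(bym$mu)), tol(bym$mu))
  expect_lt(abs(mean(a[, "sigma2"]) - mean(bym$sigma2)), tol(bym$sigma2))
  expect_lt(abs(mean(a[, "lambda"]) - mean(bym$lambda)), tol(bym$lambda))
})

test_that("the cloned posterior variance shrinks and flags adequacy", {
  res <- experiment_dc_degeneracy(clone_counts = c(1L, 4L, 16L), m = 60L,
                                  mcmc = mcmc_settings(chains = 1,
                                                       n_iter = 9000,
                                                       n_burn = 3000,
                                                       thin = 2),
                                  seed = 3)
  cv <- res$convergence
  expect_true(all(diff(cv$scaled) < 0))
  expect_true(res$fit$adequate)
  expect_lt(cv$scaled[3], 1.5 / 16)
  # asymptotic covariance is symmetric positive semi-definite
  expect_equal(res$fit$vcov, t(res$fit$vcov), tolerance = 1e-12)
  expect_gte(min(eigen(res$fit$vcov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("prediction with a degenerate covariance equals the plug-in
           conditional at the MLE", {
  sd <- small_dataset(m = 9, rr_regions = "5", rr = 3)
  st <- build_car_structure(sd$counts, sd$map)
  alpha <- c(mu = 0.1, lambda = 0.05, sigma2 = 2)
  mle <- structure(list(
    alpha_hat = alpha, vcov = matrix(0, 3, 3,
                                     dimnames = list(names(alpha),
                                                     names(alpha))),
    adequate = TRUE, fixed_lambda = NULL,
    lambda_bounds = st$lambda_bounds, region_id = sd$map$region_id,
    counts = sd$counts), class = "mle_result")
  pred <- predict_rr(sd$counts, sd$map, mle, n_alpha = 60, n_burn = 400,
                     n_keep = 10, thin = 10, seed = 2)
  expect_true(all(pred$alpha_draws[, "mu"] == 0.1))
  # direct conditional sampler at the same fixed hyperparameters
  run <- withr::with_seed(77, arealclust:::car_mcmc_cpp(
    sd$counts$observed, sd$counts$expected,
    st$edges[, 1], st$edges[, 2], st$evals, L = 1L,
    mu_mean = 0, mu_var = 1, sig_shape = 1, sig_rate = 1,
    lam_lo = st$lambda_bounds[1], lam_hi = st$lambda_bounds[2],
    n_iter = 30000L, n_burn = 2000L, thin = 10L,
    update_mu = FALSE, update_sigma = FALSE, update_lambda = FALSE,
    use_data = TRUE, mu0 = 0.1, sigma20 = 2, lambda0 = 0.05,
    eta0 = numeric(9), save_eta = TRUE))
  ref <- exp(0.1 + run$eta)
  for (i in c(1, 5, 9)) {
    expect_lt(abs(stats::median(pred$theta[, i]) -
                    stats::median(ref[, i])), 0.12)
    expect_lt(abs(stats::quantile(pred$theta[, i], 0.9) -
                    stats::quantile(ref[, i], 0.9)), 0.2)
  }
})

test_that("prediction intervals on null data cover RR = 1 for most
           regions", {
  m <- 20
  mp <- make_map(m, "jittered_lattice", seed = 31)
  E <- rep(60, m)
  C <- withr::with_seed(32, rpois(m, E))
  cd <- counts_data(mp$region_id, C, E)
  dc <- fit_dc(cd, mp, priors = car_priors(sigma2_shape = -0.5,
                                           sigma2_rate = 0),
               config = dc_config(c(1L, 4L, 8L),
                                  mcmc = mcmc_settings(chains = 1,
                                                       n_iter = 7000,
                                                       n_burn = 3000,
                                                       thin = 2),
                                  seed = 33))
  pred <- suppressWarnings(
    predict_rr(cd, mp, dc, n_alpha = 80, seed = 34, override = TRUE))
  ci <- apply(pred$theta, 2, stats::quantile, probs = c(0.025, 0.975))
  cover <- mean(ci[1, ] <= 1 & 1 <= ci[2, ])
  expect_gte(cover, 0.8)
})

test_that("method comparison reports perfect and empty concordance", {
  theta <- withr::with_seed(3, matrix(rlnorm(200 * 6, 0.2, 0.4), 200, 6))
  ids <- as.character(1:6)
  a <- list(theta = theta, region_id = ids)
  cmp <- compare_methods(bym = a, mle = a)
  expect_equal(cmp$spearman, 1)
  expect_true(all(cmp$overlap == 1))
  # disjoint calls: one method sees excess where the other sees deficit
  hot <- matrix(rep(c(2, 2, 2, 0.5, 0.5, 0.5), each = 50), 50, 6)
  d1 <- list(theta = hot, region_id = ids)
  d2 <- list(theta = hot[, c(4:6, 1:3)], region_id = ids)
  cmp2 <- compare_methods(bym = d1, mle = d2)
  expect_equal(cmp2$overlap[["rr_gt_1.0"]], 0)
})

test_that("scan ranks join the comparison table on the shared regions", {
  sd <- small_dataset(m = 16, rr_regions = c("6", "7", "10", "11"), rr = 4)
  css <- scan(sd$counts, sd$map,
              scan_config("circular", J = 5, n_monte_carlo = 99, seed = 1))
  pri <- car_priors(sigma2_shape = -0.5, sigma2_rate = 0)
  bym <- suppressWarnings(
    fit_bym(sd$counts, sd$map, priors = pri,
            mcmc = mcmc_settings(chains = 2, n_iter = 3000,
                                 n_burn = 1500, thin = 2), seed = 2))
  dc <- fit_dc(sd$counts, sd$map, priors = pri,
               config = dc_config(c(1L, 4L),
                                  mcmc = mcmc_settings(chains = 1,
                                                       n_iter = 5000,
                                                       n_burn = 2000,
                                                       thin = 2),
                                  seed = 3))
  mle <- suppressWarnings(
    predict_rr(sd$counts, sd$map, dc, n_alpha = 60, seed = 4,
               override = TRUE))
  cmp <- compare_methods(css = css, bym = bym, mle = mle)
  expect_setequal(cmp$table$region_id, sd$map$region_id)
  top <- strsplit(css$regions[1], ";")[[1]]
  if (css$p_value[1] <= 0.05) {
    expect_true(all(cmp$table$css[match(top, cmp$table$region_id)] == 1))
  }
  expect_error(compare_methods(bym = bym,
                               mle = list(theta = mle$theta,
                                          region_id = letters[1:16])),
               "mismatched")
})
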