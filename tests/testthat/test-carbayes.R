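test_that("the CAR structure matches hand matrix arithmetic", {
  mp <- region_map(1:2, cbind(0:1, 0), rbind(c(1, 2)))
  cd <- counts_data(1:2, c(1L, 1L), c(4, 1))
  st <- build_car_structure(cd, mp)
  expect_equal(st$D, rbind(c(0, 1 / 2), c(2, 0)))
  expect_equal(st$P, diag(c(1 / 4, 1)))
  DP <- st$D %*% st$P
  expect_equal(DP, t(DP))
  expect_equal(DP[1, 2], 1 / 2)
  # admissible interval brackets zero
  expect_lt(st$lambda_bounds[1], 0)
  expect_gt(st$lambda_bounds[2], 0)
})

test_that("lambda = 0 reduces the covariance to the independence limit", {
  sd <- small_dataset(m = 9)
  st <- build_car_structure(sd$counts, sd$map)
  expect_equal(car_covariance(st, 0.7, 0), 0.7 * st$P, tolerance = 1e-12)
})

test_that("the joint log posterior reduces to closed form for one region", {
  mp <- structure(list(region_id = "1", xy = cbind(0, 0),
                       edges = matrix(integer(0), 0, 2),
                       adj = list(integer(0)), m = 1L),
                  class = "region_map")
  # assemble the single-region structure by hand (no edges, so the CAR
  # builder cannot be used); bounds are irrelevant with no adjacency
  st <- structure(list(P = diag(1 / 5, 1), D = matrix(0, 1, 1), E = 5,
                       edges = matrix(integer(0), 0, 2), evals = 0,
                       lambda_bounds = c(-1, 1), m = 1L, region_id = "1"),
                  class = "car_structure")
  cd <- counts_data("1", 7L, 5)
  pri <- car_priors()
  par <- list(mu = 0.3, eta = 0.2, sigma2 = 0.8, lambda = 0)
  got <- log_posterior(par, cd, st, pri)
  want <- dpois(7, 5 * exp(0.5), log = TRUE) +
    dnorm(0.2, 0, sqrt(0.8 / 5), log = TRUE) +
    dnorm(0.3, 0, 100, log = TRUE) +
    (-(0.5 + 1) * log(0.8) - 5e-4 / 0.8) - log(2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("log posterior agrees with an independent dense implementation", {
  mp <- cycle4_map()
  cd <- counts_data(1:4, c(12L, 30L, 8L, 21L), c(10, 25, 10, 18))
  st <- build_car_structure(cd, mp)
  pri <- car_priors()
  for (seed in 1:5) {
    par <- withr::with_seed(seed, list(
      mu = rnorm(1, 0, 0.5), eta = rnorm(4, 0, 0.3),
      sigma2 = runif(1, 0.2, 3),
      lambda = runif(1, 0.9 * st$lambda_bounds[1],
                     0.9 * st$lambda_bounds[2])))
    expect_equal(log_posterior(par, cd, st, pri),
                 dense_log_posterior(par, cd, st, pri), tolerance = 1e-10)
  }
  # out-of-bounds states are rejected by contract, not by error
  par$lambda <- st$lambda_bounds[2] + 0.01
  expect_identical(log_posterior(par, cd, st, pri), -Inf)
  par$lambda <- 0; par$sigma2 <- -1
  expect_identical(log_posterior(par, cd, st, pri), -Inf)
})

test_that("doubling E and halving theta leaves the Poisson mean term alone", {
  E <- c(10, 20); theta <- c(1.2, 0.7)
  expect_equal(sum(theta * E), sum((theta / 2) * (2 * E)))
})

test_that("flat data concentrate the overall level near zero", {
  mp <- make_map(16, "jittered_lattice", seed = 1)
  E <- rep(50, 16)
  cd <- counts_data(mp$region_id, as.integer(E), E)
  fit <- suppressWarnings(
    fit_bym(cd, mp, mcmc = mcmc_settings(chains = 2, n_iter = 4000,
                                         n_burn = 2000, thin = 2),
            seed = 1))
  expect_lt(abs(mean(fit$mu)), 0.1)
  q <- quantile(fit$mu, c(0.025, 0.975))
  expect_true(q[1] < 0 && 0 < q[2])
})

test_that("different seeds give different draws but overlapping summaries", {
  sd <- small_dataset(m = 12, rr_regions = c("5", "6"), rr = 2)
  ms <- mcmc_settings(chains = 2, n_iter = 4000, n_burn = 2000, thin = 2)
  f1 <- suppressWarnings(fit_bym(sd$counts, sd$map, mcmc = ms, seed = 1))
  f2 <- suppressWarnings(fit_bym(sd$counts, sd$map, mcmc = ms, seed = 2))
  expect_false(identical(f1$mu, f2$mu))
  se <- sd(f1$mu) / sqrt(200)   # generous effective-sample allowance
  expect_lt(abs(mean(f1$mu) - mean(f2$mu)), 6 * se)
})

test_that("the sampler matches an independent MCMC implementation", {
  skip_if_not_installed("rjags")
  m <- 10
  mp <- make_map(m, "jittered_lattice", seed = 11)
  E <- withr::with_seed(21, runif(m, 5, 50))
  st <- build_car_structure(counts_data(mp$region_id, rep(1L, m), E), mp)
  sim <- arealclust:::.simulate_car_data(st, 0.3, 5,
                                         0.5 * st$lambda_bounds[2], 12)
  cd <- counts_data(mp$region_id, sim$C, E)
  fit <- fit_bym(cd, mp, mcmc = mcmc_settings(chains = 4, n_iter = 30000,
                                              n_burn = 10000, thin = 5),
                 seed = 1)
  A <- matrix(0, m, m)
  A[mp$edges] <- 1
  A[mp$edges[, 2:1, drop = FALSE]] <- 1
  B <- A * sqrt(outer(E, E))
  model <- "model {
    for (i in 1:m) { C[i] ~ dpois(E[i] * exp(mu + eta[i])) }
    eta[1:m] ~ dmnorm(zeros[1:m], Omega[1:m, 1:m])
    for (i in 1:m) { for (j in 1:m) {
      Omega[i, j] <- (equals(i, j) * E[i] - lambda * B[i, j]) / sigma2
    } }
    mu ~ dnorm(0, 1e-4)
    tau ~ dgamma(0.5, 5e-4)
    sigma2 <- 1 / tau
    lambda ~ dunif(lo, hi)
  }"
  # dispersed dispersion inits and a long burn-in: the sigma2 marginal is
  # heavy-tailed on this small dataset and a short reference run has not
  # yet converged
  jm <- suppressWarnings(rjags::jags.model(
    textConnection(model),
    data = list(C = cd$observed, E = E, B = B, m = m, zeros = rep(0, m),
                lo = st$lambda_bounds[1] + 1e-6,
                hi = st$lambda_bounds[2] - 1e-6),
    inits = list(list(tau = 1, .RNG.name = "base::Mersenne-Twister",
                      .RNG.seed = 7),
                 list(tau = 0.01, .RNG.name = "base::Mersenne-Twister",
                      .RNG.seed = 8)),
    n.chains = 2, quiet = TRUE))
  suppressWarnings(update(jm, 20000, progress.bar = "none"))
  samp <- rjags::coda.samples(jm, c("mu", "sigma2", "lambda", "eta"),
                              n.iter = 60000, thin = 20,
                              progress.bar = "none")
  sm <- summary(samp)$statistics
  expect_lt(abs(mean(fit$mu) - sm["mu", "Mean"]), 0.06)
  expect_lt(abs(mean(fit$sigma2) - sm["sigma2", "Mean"]),
            0.15 * sm["sigma2", "Mean"] + 0.2)
  expect_lt(abs(mean(fit$lambda) - sm["lambda", "Mean"]), 0.04)
  eta_j <- sm[sprintf("eta[%d]", 1:m), "Mean"]
  expect_lt(max(abs(colMeans(fit$eta) - eta_j)), 0.1)
})

test_that("with the data term removed the chain samples the prior of mu", {
  m <- 6
  mp <- make_map(m, "lattice", seed = 1)
  E <- rep(20, m)
  st <- build_car_structure(counts_data(mp$region_id, rep(1L, m), E), mp)
  run <- withr::with_seed(5, arealclust:::car_mcmc_cpp(
    rep(1L, m), E, st$edges[, 1], st$edges[, 2], st$evals, L = 1L,
    mu_mean = 0.5, mu_var = 1, sig_shape = 3, sig_rate = 2,
    lam_lo = st$lambda_bounds[1], lam_hi = st$lambda_bounds[2],
    n_iter = 60000L, n_burn = 5000L, thin = 25L,
    update_mu = TRUE, update_sigma = TRUE, update_lambda = TRUE,
    use_data = FALSE, mu0 = 0.5, sigma20 = 1, lambda0 = 0,
    eta0 = numeric(m), save_eta = FALSE))
  ref <- withr::with_seed(6, rnorm(length(run$mu), 0.5, 1))
  ks <- suppressWarnings(stats::ks.test(run$mu, ref))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(run$mu) - 0.5), 0.1)
  expect_lt(abs(sd(run$mu) - 1), 0.1)
})

test_that("region calls respect strict thresholds, ranking and ties", {
  theta <- cbind(matrix(2, 50, 1), matrix(c(0.8, 1.2), 50, 2),
                 matrix(3, 50, 1))
  draws <- list(theta = theta, region_id = c("a", "b", "c", "d"))
  calls <- call_regions(draws, threshold = 1.5)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$rank, c(2L, NA, NA, 1L))
  # degenerate draws at exactly 2: called under 1.5, not under 2.0
  expect_false(call_regions(draws, threshold = 2.0)$called[1])
  # exceedance criterion
  ex <- call_regions(draws, criterion = "exceedance",
                     exceed_b = 1, exceed_c = 0.9)
  expect_equal(ex$called, c(TRUE, FALSE, FALSE, TRUE))
  # ties in the lower bound rank by ascending region id
  draws2 <- list(theta = matrix(2, 40, 3), region_id = c("7", "2", "11"))
  c2 <- call_regions(draws2, threshold = 1.0)
  expect_equal(c2$rank, c(2L, 1L, 3L))
})

test_that("raising the threshold never increases the number of calls", {
  sd <- small_dataset(m = 16, rr_regions = c("6", "7", "10"), rr = 3)
  fit <- suppressWarnings(
    fit_bym(sd$counts, sd$map,
            mcmc = mcmc_settings(chains = 2, n_iter = 3000,
                                 n_burn = 1500, thin = 2), seed = 3))
  n_called <- vapply(c(1, 1.5, 2), function(th) {
    sum(call_regions(fit, threshold = th)$called)
  }, 0)
  expect_true(all(diff(n_called) <= 0))
})

test_that("exceedance calls on null data are rare", {
  mp <- make_map(16, "jittered_lattice", seed = 8)
  E <- rep(40, 16)
  hits <- vapply(1:10, function(r) {
    C <- withr::with_seed(300 + r, rpois(16, E))
    fit <- suppressWarnings(
      fit_bym(counts_data(mp$region_id, C, E), mp,
              mcmc = mcmc_settings(chains = 2, n_iter = 2500,
                                   n_burn = 1200, thin = 2),
              seed = 300 + r))
    sum(call_regions(fit, criterion = "exceedance",
                     exceed_b = 1, exceed_c = 0.9)$called)
  }, 0)
  expect_lt(mean(hits), 1)   # on average well under one region in 16
})

test_that("deviance residuals are zero at perfect fit and flag gross
           misfit", {
  cd <- counts_data(1:3, c(20L, 30L, 40L), c(20, 30, 40))
  draws <- list(theta = matrix(1, 100, 3), region_id = as.character(1:3))
  expect_equal(unname(deviance_residuals(draws, cd)), rep(0, 3))
  # a planted RR = 5 region analysed with all spatial effects forced flat
  cd2 <- counts_data(1:3, c(100L, 30L, 40L), c(20, 30, 40))
  r <- deviance_residuals(draws, cd2)
  expect_equal(names(which.max(abs(r))), "1")
  expect_gt(r[["1"]], 0)
})

test_that("residuals on model-simulated data centre near zero", {
  sd <- small_dataset(m = 20)
  fit <- suppressWarnings(
    fit_bym(sd$counts, sd$map,
            mcmc = mcmc_settings(chains = 2, n_iter = 3000,
                                 n_burn = 1500, thin = 2), seed = 4))
  r <- deviance_residuals(fit, sd$counts)
  expect_lt(abs(mean(r)), 0.5)
})
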