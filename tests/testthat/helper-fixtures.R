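# small fixtures shared across test files; everything is built in code

# 3 regions on a line with edges (1,2), (2,3)
path3_map <- function() {
  region_map(1:3, cbind(c(0, 1, 2), c(0, 0, 0)), rbind(c(1, 2), c(2, 3)))
}

# 4-cycle with square centroids
cycle4_map <- function() {
  region_map(1:4, cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
             rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
}

# a small dataset on a jittered lattice with counts drawn at given RR
small_dataset <- function(m = 16, rr_regions = character(0), rr = 3,
                          e_range = c(30, 70), seed = 42) {
  map <- make_map(m, "jittered_lattice", seed = seed)
  withr::with_seed(seed + 1L, {
    E <- stats::runif(m, e_range[1], e_range[2])
    mult <- ifelse(map$region_id %in% rr_regions, rr, 1)
    C <- stats::rpois(m, E * mult)
  })
  list(map = map, counts = counts_data(map$region_id, C, E))
}

# direct dense-matrix implementation of the joint log posterior, kept
# deliberately independent of the package's O(m + edges) identities
dense_log_posterior <- function(params, counts, structure, priors) {
  E <- structure$E
  m <- structure$m
  theta <- exp(params$mu + params$eta)
  ll <- sum(counts$observed * log(theta * E) - theta * E -
              lgamma(counts$observed + 1))
  Sigma <- params$sigma2 *
    solve(diag(m) - params$lambda * structure$D) %*% structure$P
  Sigma <- (Sigma + t(Sigma)) / 2
  logp_eta <- -0.5 * (m * log(2 * pi) +
                        determinant(Sigma, logarithm = TRUE)$modulus +
                        drop(params$eta %*% solve(Sigma, params$eta)))
  logp_mu <- stats::dnorm(params$mu, priors$mu_mean,
                          sqrt(priors$mu_var), log = TRUE)
  logp_sig <- -(priors$sigma2_shape + 1) * log(params$sigma2) -
    priors$sigma2_rate / params$sigma2
  b <- structure$lambda_bounds
  ll + as.numeric(logp_eta) + logp_mu + logp_sig - log(b[2] - b[1])
}
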