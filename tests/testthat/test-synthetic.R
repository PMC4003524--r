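test_that("lattice maps have rook adjacency and are reproducible", {
  mp <- make_map(4, "lattice", seed = 1)
  expect_equal(lengths(mp$adj), rep(2L, 4))      # 2x2 grid
  expect_error(make_map(1), "at least 2")

  m67a <- make_map(67, "jittered_lattice", seed = 1)
  m67b <- make_map(67, "jittered_lattice", seed = 1)
  expect_identical(m67a$xy, m67b$xy)
  expect_identical(m67a$edges, m67b$edges)
  expect_equal(m67a$m, 67)
  # connectivity is enforced by the region_map constructor
  g <- igraph::graph_from_edgelist(m67a$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("populations respect bounds and strata sum to region totals", {
  mp <- make_map(12, "jittered_lattice", seed = 2)
  spec <- strata_spec()
  # degenerate bounds pin every total
  p1 <- make_populations(mp, spec, min_pop = 1000, max_pop = 1000, seed = 1)
  expect_true(all(tapply(p1$population, p1$region_id, sum) == 1000))
  # default provincial-scale bounds
  p2 <- make_populations(mp, spec, seed = 3)
  tot <- tapply(p2$population, p2$region_id, sum)
  expect_true(all(tot >= 920 & tot <= 91633))
  expect_error(make_populations(mp, spec, min_pop = 0, max_pop = 10))
})

test_that("planted truth is recorded verbatim and generation is pure", {
  mp <- make_map(67, "jittered_lattice", seed = 1)
  spec <- strata_spec()
  pop <- make_populations(mp, spec, seed = 2)
  altB <- alternative_spec(canonical_clusters()$B, 3)
  d1 <- simulate_counts(mp, pop, spec, altB, seed = 3)
  expect_identical(d1$truth$cluster_regions,
                   as.character(c(31, 33, 34, 36, 38, 40, 41)))
  expect_identical(d1$truth$relative_risk, 3)
  d2 <- simulate_counts(mp, pop, spec, altB, seed = 3)
  expect_identical(d1$counts$observed, d2$counts$observed)
  expect_equal(sum(d1$counts$expected), sum(d1$counts$observed))
})

test_that("null counts have the analytic Poisson mean", {
  mp <- make_map(9, "jittered_lattice", seed = 4)
  spec <- strata_spec(years = 1:2, age_groups = c("young", "old"),
                      age_rates = c(0.05, 0.15))
  pop <- make_populations(mp, spec, seed = 5)
  cell <- merge(pop, spec, by = setdiff(names(spec), "rate"))
  mu_i <- tapply(cell$population * cell$rate, cell$region_id, sum)
  mu_i <- mu_i[mp$region_id]
  reps <- 200
  tot <- matrix(0, reps, mp$m)
  for (r in seq_len(reps)) {
    d <- simulate_counts(mp, pop, spec, alternative_spec(), seed = 1000 + r)
    tot[r, ] <- d$counts$observed
  }
  se <- sqrt(mu_i / reps)
  expect_true(all(abs(colMeans(tot) - mu_i) < 3.5 * se))
})

test_that("a global relative risk of 3 scales the total count threefold", {
  mp <- make_map(9, "jittered_lattice", seed = 4)
  spec <- strata_spec(years = 1:2, age_groups = c("young", "old"),
                      age_rates = c(0.05, 0.15))
  pop <- make_populations(mp, spec, seed = 5)
  cell <- merge(pop, spec, by = setdiff(names(spec), "rate"))
  mu_tot <- sum(cell$population * cell$rate)
  alt_all <- alternative_spec(mp$region_id, 3)
  totals <- vapply(1:200, function(r) {
    sum(simulate_counts(mp, pop, spec, alt_all, seed = 2000 + r)$counts$observed)
  }, 0)
  expect_lt(abs(mean(totals) - 3 * mu_tot), 3.5 * sqrt(3 * mu_tot / 200))
})

test_that("a synthetic dataset writes to plain-text files that re-read", {
  mp <- make_map(9, "jittered_lattice", seed = 4)
  spec <- strata_spec(years = 1:2, age_groups = c("a", "b"),
                      age_rates = c(0.05, 0.1))
  pop <- make_populations(mp, spec, seed = 5)
  d <- simulate_counts(mp, pop, spec, seed = 6)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(d, dir)
  back <- utils::read.csv(file.path(dir, "counts.csv"))
  expect_equal(back$observed, d$counts$observed)
  expect_equal(back$expected, d$counts$expected, tolerance = 1e-6)
  # re-standardizing the written stratified table reproduces the expecteds
  strat <- utils::read.csv(file.path(dir, "stratified.csv"))
  e2 <- expected_counts(strat)
  expect_equal(e2$expected[match(d$counts$region_id, e2$region_id)],
               d$counts$expected, tolerance = 1e-9)
})

test_that("rejecting invalid alternatives", {
  mp <- make_map(4, "lattice")
  spec <- strata_spec(years = 1, age_groups = "all", age_rates = 0.1)
  pop <- make_populations(mp, spec, seed = 1)
  expect_error(simulate_counts(mp, pop, spec,
                               alternative_spec("99", 3), seed = 1),
               "absent from the map")
  expect_error(alternative_spec("1", 0.5), "relative_risk")
})
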