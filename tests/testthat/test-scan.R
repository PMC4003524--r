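test_that("the log likelihood-ratio statistic matches direct arithmetic", {
  # indicator boundary: no observed excess
  expect_equal(log_likelihood_ratio(10, 10, 100, 100), 0)
  expect_equal(log_likelihood_ratio(5, 10, 100, 100), 0)
  # frozen value computed from 20*log(2) + 980*log(980/990)
  expect_equal(log_likelihood_ratio(20, 10, 1000, 1000),
               3.913619576461, tolerance = 1e-10)
  # all cases inside the window: 0*log(0) convention keeps it finite
  v <- log_likelihood_ratio(50, 10, 50, 100)
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, 50 * log(50 / 10) - 50 * log(50 / 100), tolerance = 1e-12)
  # contract violations
  expect_error(log_likelihood_ratio(20, 10, 15, 100), "exceed")
  expect_error(log_likelihood_ratio(5, 12, 100, 10), "E_in < E_total")
})

test_that("circular windows are the deduplicated nearest-neighbour discs", {
  mp <- path3_map()
  ord <- nearest_neighbour_order(mp)
  w <- circular_windows(mp, ord, scan_config("circular", J = 2))
  keys <- sort(vapply(w, paste, "", collapse = ","))
  expect_equal(keys, c("1", "1,2", "2", "2,3", "3"))
  expect_lte(length(w), 3 * 2)

  w1 <- circular_windows(mp, ord, scan_config("circular", J = 1))
  expect_equal(sort(vapply(w1, paste, "", collapse = ",")),
               c("1", "2", "3"))

  mp6 <- make_map(6, "jittered_lattice", seed = 1)
  w6 <- circular_windows(mp6, nearest_neighbour_order(mp6),
                         scan_config("circular", J = 6))
  expect_true(any(lengths(w6) == 6))
})

test_that("flexible windows on a 4-cycle match exhaustive enumeration", {
  mp <- cycle4_map()
  ord <- nearest_neighbour_order(mp)
  w <- flexible_windows(mp, ord, scan_config("flexible", J = 3))
  keys <- sort(vapply(w, paste, "", collapse = ","))
  # per anchor: itself, both edges, and the 3-paths through or ending at it;
  # globally that is all 4 singletons, 4 edges, 4 paths of length 3
  expect_equal(keys, c("1", "1,2", "1,2,3", "1,2,4", "1,3,4", "1,4",
                       "2", "2,3", "2,3,4", "3", "3,4", "4"))
  # J = 1 coincides with circular singletons
  wf1 <- flexible_windows(mp, ord, scan_config("flexible", J = 1))
  wc1 <- circular_windows(mp, ord, scan_config("circular", J = 1))
  expect_setequal(vapply(wf1, paste, "", collapse = ","),
                  vapply(wc1, paste, "", collapse = ","))
})

test_that("flexible windows contain every connected circular window", {
  for (seed in 1:5) {
    mp <- make_map(12, "jittered_lattice", seed = seed)
    ord <- nearest_neighbour_order(mp)
    J <- 4
    wc <- circular_windows(mp, ord, scan_config("circular", J = J))
    wf <- flexible_windows(mp, ord, scan_config("flexible", J = J))
    fkeys <- vapply(wf, paste, "", collapse = ",")
    g <- igraph::graph_from_edgelist(mp$edges, directed = FALSE)
    for (w in wc) {
      if (igraph::is_connected(igraph::induced_subgraph(g, w))) {
        expect_true(paste(w, collapse = ",") %in% fkeys)
      }
    }
    expect_gte(length(wf), sum(vapply(wc, function(w) {
      igraph::is_connected(igraph::induced_subgraph(g, w))
    }, TRUE)))
  }
})

test_that("the enumeration cap aborts with a sizing error", {
  mp <- make_map(25, "jittered_lattice", seed = 2)
  ord <- nearest_neighbour_order(mp)
  cfg <- scan_config("flexible", J = 10, max_windows = 50)
  expect_error(flexible_windows(mp, ord, cfg),
               class = "arealclust_window_overflow")
})

test_that("an extreme planted cluster is found at rank 1 with small p", {
  mp <- make_map(25, "jittered_lattice", seed = 7)
  E <- rep(10, 25)
  C <- ifelse(mp$region_id == "13", 100L, 10L)   # C = 10 x E in one region
  cd <- counts_data(mp$region_id, C, E)
  res <- scan(cd, mp, scan_config("circular", J = 5, n_monte_carlo = 999,
                                  seed = 1))
  expect_equal(res$regions[1], "13")
  expect_lte(res$p_value[1], 0.01)
})

test_that("the maximum statistic is invariant under region relabelling", {
  sd <- small_dataset(m = 16, rr_regions = c("3", "4"), rr = 2.5)
  res <- scan(sd$counts, sd$map, scan_config("circular", J = 6,
                                             n_monte_carlo = 99, seed = 1))
  perm <- withr::with_seed(9, sample(16))
  mp2 <- region_map(sd$map$region_id[perm], sd$map$xy[perm, ],
                    matrix(sd$map$region_id[sd$map$edges], ncol = 2))
  cd2 <- sd$counts[perm, ]
  res2 <- scan(cd2, mp2, scan_config("circular", J = 6,
                                     n_monte_carlo = 99, seed = 1))
  expect_equal(attr(res2, "max_stat"), attr(res, "max_stat"),
               tolerance = 1e-12)
})

test_that("reported clusters are ranked, non-overlapping and carry
           Monte Carlo p-values in (0, 1]", {
  sd <- small_dataset(m = 20, rr_regions = c("1", "2"), rr = 3)
  res <- scan(sd$counts, sd$map, scan_config("flexible", J = 4,
                                             n_monte_carlo = 99, seed = 2))
  expect_equal(res$rank, seq_len(nrow(res)))
  regs <- strsplit(res$regions, ";", fixed = TRUE)
  expect_equal(anyDuplicated(unlist(regs)), 0L)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(diff(res$log_lr) <= 0))
})
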