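#' Stratification scheme and baseline rates for synthetic populations
#'
#' Describes the year x age-group x sex cross-classification over which
#' synthetic populations are spread and cases arise.  The defaults emulate a
#' decade-long provincial health-survey design: 10 annual periods, the five
#' age bands 0-5, 6-20, 21-40, 41-88 and 89+, and two sexes.  The per-cell
#' disease rate is the product of an age-band rate, a sex multiplier and a
#' year multiplier; the default age rates are calibrated so that a region
#' with a log-uniform population between about 900 and 92,000 accrues an
#' expected case count in the tens-to-thousands range over the study period.
#'
#' @param years period labels.
#' @param age_groups age-band labels, parallel to `age_rates`.
#' @param sexes sex labels, parallel to `sex_effects`.
#' @param age_rates baseline per-person disease rate for each age band,
#'   aggregated over the whole study period.
#' @param sex_effects multiplicative rate modifiers per sex.
#' @param year_effects multiplicative rate modifiers per year.
#' @return An object of class `strata_spec`: a data frame with one row per
#'   (year, age_group, sex) cell and a `rate` column, plus the inputs as
#'   attributes.
#' @export
strata_spec <- function(years = 1:10,
                        age_groups = c("0-5", "6-20", "21-40", "41-88", "89+"),
                        sexes = c("F", "M"),
                        age_rates = c(0.05, 0.08, 0.10, 0.12, 0.17),
                        sex_effects = c(0.95, 1.05),
                        year_effects = rep(1, length(years))) {
  stopifnot(length(age_rates) == length(age_groups),
            length(sex_effects) == length(sexes),
            length(year_effects) == length(years))
  if (any(!is.finite(age_rates)) || any(age_rates <= 0) ||
      any(sex_effects <= 0) || any(year_effects <= 0)) {
    stop("all baseline rates and effects must be strictly positive and finite")
  }
  cells <- expand.grid(year = years, age_group = age_groups, sex = sexes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # cell populations partition each region's person-time total, so the
  # cell rate is the full study-period rate, not an annual one
  cells$rate <- age_rates[match(cells$age_group, age_groups)] *
    sex_effects[match(cells$sex, sexes)] *
    year_effects[match(cells$year, years)]
  structure(cells, class = c("strata_spec", "data.frame"))
}

#' Planted-cluster alternative hypothesis
#'
#' Specifies the alternative under which synthetic counts are drawn: a set
#' of cluster regions X and the within-cluster relative risk, with RR = 1
#' outside X.  An empty X is the null.  The canonical alternatives of the
#' emulated 67-region design plant seven northern regions (`cluster_b`),
#' seven south-central regions (`cluster_c`) or the twelve urban-centre
#' regions (`cluster_d`), each at RR = 3.
#'
#' @param cluster_regions region ids forming the cluster (possibly empty).
#' @param relative_risk relative risk inside the cluster, >= 1.
#' @return An object of class `alternative_spec`.
#' @export
alternative_spec <- function(cluster_regions = character(0),
                             relative_risk = 3) {
  if (!is.finite(relative_risk) || relative_risk < 1) {
    stop("relative_risk must be finite and >= 1")
  }
  structure(list(cluster_regions = as.character(cluster_regions),
                 relative_risk = as.numeric(relative_risk)),
            class = "alternative_spec")
}

#' Canonical planted-cluster region sets of the emulated 67-region design
#'
#' @return A named list of character vectors `B`, `C`, `D`.
#' @export
canonical_clusters <- function() {
  list(B = as.character(c(31, 33, 34, 36, 38, 40, 41)),
       C = as.character(c(27, 28, 29, 30, 50, 51, 52)),
       D = as.character(56:67))
}

#' Generate a synthetic region map
#'
#' Lays m regions out on a near-square grid (row-major fill) with
#' rook-contiguity adjacency; `jittered_lattice` perturbs each centroid with
#' a uniform jitter so that nearest-neighbour orderings are generic
#' (distance ties essentially never occur).  The grid graph is always
#' connected.
#'
#' @param m number of regions (>= 2); regions are labelled 1..m.
#' @param layout `"lattice"` or `"jittered_lattice"`.
#' @param seed integer RNG seed; the map is a pure function of
#'   (m, layout, seed).
#' @return A [region_map()].
#' @export
make_map <- function(m, layout = c("jittered_lattice", "lattice"), seed = 1L) {
  layout <- match.arg(layout)
  if (m < 2) stop("m must be at least 2")
  m <- as.integer(m)
  nc <- ceiling(sqrt(m))
  row <- (seq_len(m) - 1L) %/% nc
  col <- (seq_len(m) - 1L) %% nc
  xy <- cbind(col, row)
  if (layout == "jittered_lattice") {
    xy <- xy + withr::with_seed(seed, matrix(stats::runif(2L * m, -0.3, 0.3),
                                             m, 2L))
  }
  # rook contiguity on the (partial) grid
  e <- NULL
  for (k in seq_len(m)) {
    if (col[k] < nc - 1L && k + 1L <= m) e <- rbind(e, c(k, k + 1L))
    if (k + nc <= m) e <- rbind(e, c(k, k + nc))
  }
  region_map(seq_len(m), xy, e)
}

#' Draw stratified synthetic populations
#'
#' Per-region person-time totals are drawn log-uniformly between `min_pop`
#' and `max_pop` (for the default bounds 920 and 91,633 this gives a median
#' near 9,200 and a mean near 19,700, the right-skewed profile of the
#' emulated design) and then split across the strata cells of `spec` by a
#' symmetric Dirichlet-multinomial draw, so cell populations are integers
#' that sum exactly to the region total.
#'
#' @param map a [region_map()].
#' @param spec a [strata_spec()].
#' @param min_pop,max_pop bounds for the per-region totals.
#' @param seed integer RNG seed.
#' @param dirichlet_conc concentration of the symmetric Dirichlet split.
#' @return Data frame with columns `region_id`, the stratifying columns of
#'   `spec`, and `population`.
#' @export
make_populations <- function(map, spec, min_pop = 920L, max_pop = 91633L,
                             seed = 1L, dirichlet_conc = 5) {
  if (min_pop <= 0 || min_pop > max_pop) {
    stop("need 0 < min_pop <= max_pop")
  }
  ncell <- nrow(spec)
  withr::with_seed(seed, {
    totals <- round(exp(stats::runif(map$m, log(min_pop), log(max_pop))))
    cells <- lapply(seq_len(map$m), function(i) {
      w <- stats::rgamma(ncell, shape = dirichlet_conc)
      as.integer(stats::rmultinom(1L, totals[i], w / sum(w)))
    })
  })
  out <- spec[rep(seq_len(ncell), map$m),
              setdiff(names(spec), "rate"), drop = FALSE]
  out$region_id <- rep(map$region_id, each = ncell)
  out$population <- unlist(cells)
  rownames(out) <- NULL
  out[, c("region_id", setdiff(names(spec), "rate"), "population")]
}

#' Simulate areal disease counts under a planted-cluster alternative
#'
#' Cases in each (region, stratum) cell are Poisson with mean
#' population x rate x RR_i, where RR_i is `alt$relative_risk` inside the
#' planted cluster and 1 outside.  Cell counts are summed to region level
#' and expected counts are then computed by internal indirect
#' standardization ([expected_counts()]), exactly as an analyst without
#' knowledge of the truth would, so sum(E) = sum(C) always holds.
#'
#' @param map a [region_map()].
#' @param populations stratified population table from [make_populations()].
#' @param spec the [strata_spec()] used to build `populations`.
#' @param alt an [alternative_spec()]; regions must exist in `map`.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_dataset`: list with `map`, `counts`
#'   (a [counts_data()]), `stratified` (the cell-level table with observed
#'   cases), `truth` (the `alt` used) and `seed`.
#' @export
simulate_counts <- function(map, populations, spec, alt = alternative_spec(),
                            seed = 1L) {
  if (!all(alt$cluster_regions %in% map$region_id)) {
    stop("alternative names regions absent from the map")
  }
  tab <- merge(populations, spec,
               by = setdiff(names(spec), "rate"), sort = FALSE)
  rr <- ifelse(tab$region_id %in% alt$cluster_regions,
               alt$relative_risk, 1)
  mu <- tab$population * tab$rate * rr
  tab$observed <- withr::with_seed(seed, stats::rpois(length(mu), mu))
  strat <- tab[, c("region_id", setdiff(names(spec), "rate"),
                   "population", "observed")]
  counts <- expected_counts(strat)
  # align counts to the map's region order
  counts <- counts[match(map$region_id, counts$region_id), ]
  rownames(counts) <- NULL
  attr(counts, "N") <- sum(counts$observed)
  class(counts) <- c("counts_data", "data.frame")
  structure(list(map = map, counts = counts, stratified = strat,
                 truth = alt, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `counts.csv` (`region_id,observed,expected`), `stratified.csv`
#' (cell-level populations and cases) and `truth.json` (the planted
#' alternative) into `dir`.
#'
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(x$counts), file.path(dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(x$stratified, file.path(dir, "stratified.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sprintf(
    '{"cluster_regions": [%s], "relative_risk": %.6g, "seed": %d}',
    paste(sprintf('"%s"', x$truth$cluster_regions), collapse = ", "),
    x$truth$relative_risk, as.integer(x$seed))
  writeLines(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
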