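#' Per-region observed and expected counts
#'
#' The common container consumed by every detection method: for each region,
#' the observed case count C_i and the expected count E_i (the Poisson
#' offset), plus the total observed count N.  After internal indirect
#' standardization ([expected_counts()]) the expecteds conserve the total:
#' sum(E) = sum(C).
#'
#' @param region_ids region labels, matching a [region_map()].
#' @param observed non-negative integer case counts C_i.
#' @param expected strictly positive expected counts E_i.
#' @return An object of class `counts_data`: a data frame with columns
#'   `region_id`, `observed`, `expected`, and attribute `N` = sum(observed).
#' @export
counts_data <- function(region_ids, observed, expected) {
  ids <- as.character(region_ids)
  m <- length(ids)
  if (anyDuplicated(ids) > 0L) stop("duplicate region ids in counts")
  if (length(observed) != m || length(expected) != m) {
    stop("observed and expected must have one value per region")
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop(errorCondition(
      "expected counts must be strictly positive; a zero-population region cannot be analysed",
      class = c("arealclust_bad_expected", "arealclust_error", "error")))
  }
  out <- data.frame(region_id = ids,
                    observed = as.integer(round(observed)),
                    expected = as.numeric(expected))
  attr(out, "N") <- sum(out$observed)
  class(out) <- c("counts_data", "data.frame")
  out
}

#' Expected counts by internal indirect standardization
#'
#' Computes each region's expected case count by applying pooled
#' stratum-specific rates to the region's stratified population: the rate in
#' stratum s is the total number of cases in s across all regions divided by
#' the total population in s, and E_i = sum over strata of
#' population_{i,s} * rate_s.  Pooling the rates from the data itself makes
#' the standardization internal, so sum(E) = sum(C) holds exactly (up to
#' floating point); this conservation is asserted on every call.
#'
#' Stratifying variables are all columns other than `region_id`,
#' `population` and `observed` (typically year, age group and sex); their
#' labels are opaque, so the result is invariant to relabelling of both
#' strata and regions.
#'
#' @param stratified data frame with columns `region_id`, `population`,
#'   `observed`, and at least zero further stratifying columns.
#' @return A [counts_data()] with per-region totals of `observed` and the
#'   standardized `expected`.
#' @export
expected_counts <- function(stratified) {
  need <- c("region_id", "population", "observed")
  if (!all(need %in% names(stratified))) {
    stop("stratified table needs columns region_id, population, observed")
  }
  if (any(stratified$population < 0)) stop("populations must be non-negative")
  if (any(stratified$observed < 0)) stop("case counts must be non-negative")
  if (sum(stratified$observed) == 0) stop("at least one case is required")

  strat_cols <- setdiff(names(stratified), need)
  stratum <- if (length(strat_cols) == 0L) {
    rep("all", nrow(stratified))
  } else {
    do.call(paste, c(stratified[strat_cols], sep = "\r"))
  }
  pop_s <- tapply(stratified$population, stratum, sum)
  cas_s <- tapply(stratified$observed, stratum, sum)
  if (any(cas_s > 0 & pop_s == 0)) {
    stop(errorCondition(
      "a stratum has cases but zero population; its rate is undefined",
      class = c("arealclust_zero_pop_stratum", "arealclust_error", "error")))
  }
  rate_s <- ifelse(pop_s > 0, cas_s / pop_s, 0)

  rid <- as.character(stratified$region_id)
  ids <- unique(rid)
  expd <- rowsum(stratified$population * rate_s[stratum], rid)[ids, 1L]
  obs <- rowsum(stratified$observed, rid)[ids, 1L]

  tot_c <- sum(obs)
  stopifnot(abs(sum(expd) - tot_c) <= 1e-9 * tot_c)
  counts_data(ids, obs, expd)
}
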