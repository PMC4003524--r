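#' Scan configuration
#'
#' @param mode `"circular"` (nearest-neighbour discs) or `"flexible"`
#'   (connected subsets within each anchor's J-nearest-neighbour set).
#' @param J maximum window size in regions; 15 is the conventional default
#'   for region counts near 67.
#' @param n_monte_carlo number of Monte Carlo null replicates (>= 19).
#' @param seed integer RNG seed for the Monte Carlo replicates.
#' @param max_windows combinatorial guard for flexible enumeration: abort
#'   with a sizing error if more candidate windows than this are generated.
#' @param n_report maximum number of ranked non-overlapping clusters to
#'   report.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(mode = c("circular", "flexible"), J = 15L,
                        n_monte_carlo = 999L, seed = 1L,
                        max_windows = 5e5, n_report = 10L) {
  mode <- match.arg(mode)
  if (J < 1) stop("J must be at least 1")
  if (n_monte_carlo < 19) stop("n_monte_carlo must be at least 19")
  structure(list(mode = mode, J = as.integer(J),
                 n_monte_carlo = as.integer(n_monte_carlo),
                 seed = as.integer(seed), max_windows = max_windows,
                 n_report = as.integer(n_report)),
            class = "scan_config")
}

#' Poisson log likelihood-ratio statistic for a scan window
#'
#' The log of the likelihood ratio comparing "elevated rate inside the
#' window" against "uniform rate", for a window with `C_in` observed and
#' `E_in` expected cases out of `N` total observed and `E_total` total
#' expected:
#'
#'   C_in * log(C_in / E_in) +
#'   (N - C_in) * log((N - C_in) / (E_total - E_in)) -
#'   N * log(N / E_total)
#'
#' whenever `C_in > E_in`, and 0 otherwise (windows with no observed excess
#' carry no evidence).  Under internal standardization E_total = N and the
#' last term vanishes.  The convention 0 * log 0 := 0 covers the boundary
#' C_in = N (all cases inside the window).  All arguments are vectorized.
#'
#' @param C_in observed cases inside the window (0 <= C_in <= N).
#' @param E_in expected cases inside the window (0 < E_in < E_total).
#' @param N total observed cases.
#' @param E_total total expected cases (defaults to N).
#' @return Non-negative log likelihood-ratio value(s).
#' @export
log_likelihood_ratio <- function(C_in, E_in, N, E_total = N) {
  if (any(C_in > N)) stop("C_in cannot exceed N")
  if (any(E_in <= 0) || any(E_in >= E_total)) {
    stop("need 0 < E_in < E_total")
  }
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(x / y))
  llr <- xlogy(C_in, E_in) + xlogy(N - C_in, E_total - E_in) -
    xlogy(N, E_total)
  ifelse(C_in > E_in, llr, 0)
}

#' Circular scan windows
#'
#' The window of size j anchored at region i is the set of i and its j - 1
#' nearest neighbours by centroid distance; the full collection over all
#' anchors and j = 1..J is deduplicated by region-set identity (at most
#' m * J distinct windows).  A duplicated window keeps the lowest anchoring
#' region id.
#'
#' @param map a [region_map()].
#' @param order a [nearest_neighbour_order()] for `map`.
#' @param config a [scan_config()] with mode `"circular"` (only `J` is
#'   used).
#' @return List of windows; each an integer vector of region indices with
#'   attribute `anchor`.
#' @export
circular_windows <- function(map, order, config) {
  J <- min(config$J, map$m)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", map$m * J)
  n <- 0L
  idr <- .id_rank(map$region_id)
  for (i in order(idr)) {
    for (j in seq_len(J)) {
      w <- sort(order[i, seq_len(j)])
      key <- paste(w, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        n <- n + 1L
        out[[n]] <- structure(w, anchor = i)
      }
    }
  }
  out[seq_len(n)]
}

#' Flexible scan windows
#'
#' All connected subsets (in the adjacency graph) of each anchor's
#' J-nearest-neighbour set that contain the anchor, of sizes 1..J,
#' deduplicated across anchors by region-set identity.  Enumeration grows
#' connected subgraphs incrementally with a canonical extension order so
#' each subset of a given anchor is produced exactly once; correctness is
#' defined against brute-force subset enumeration.
#'
#' @inheritParams circular_windows
#' @param config a [scan_config()]; `max_windows` caps the enumeration.
#' @return List of windows as in [circular_windows()].
#' @export
flexible_windows <- function(map, order, config) {
  J <- min(config$J, map$m)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 4096L)
  n <- 0L
  idr <- .id_rank(map$region_id)
  for (i in order(idr)) {
    cand <- order[i, seq_len(J)]
    inc <- logical(map$m)
    inc[cand] <- TRUE
    for (w in .connected_subsets(i, map$adj, inc, J)) {
      key <- paste(sort(w), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        n <- n + 1L
        if (n > config$max_windows) {
          stop(errorCondition(
            sprintf("flexible window enumeration exceeded max_windows = %g; lower J or raise the cap",
                    config$max_windows),
            class = c("arealclust_window_overflow", "arealclust_error",
                      "error")))
        }
        if (n > length(out)) out <- c(out, vector("list", length(out)))
        out[[n]] <- structure(sort(w), anchor = i)
      }
    }
  }
  out[seq_len(n)]
}

# Enumerate connected subsets of the candidate set containing `root`,
# sizes 1..J.  Standard rooted connected-subgraph enumeration: each call
# owns a frontier of eligible extension vertices; extending by frontier
# vertex v recurses with v's unseen candidate neighbours appended, then
# permanently forbids v for the remaining siblings, so every subset is
# produced exactly once.
.connected_subsets <- function(root, adj, candidate, J) {
  res <- list()
  forb <- logical(length(candidate))
  recurse <- function(set, frontier, forbidden) {
    res[[length(res) + 1L]] <<- set
    if (length(set) == J) return()
    while (length(frontier) > 0L) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      nb <- adj[[v]]
      nb <- nb[candidate[nb] & !forbidden[nb] & !(nb %in% set) &
                 !(nb %in% frontier)]
      recurse(c(set, v), c(frontier, nb), forbidden)
      forbidden[v] <- TRUE
    }
  }
  start_nb <- adj[[root]]
  start_nb <- start_nb[candidate[start_nb]]
  recurse(root, start_nb, forb)
  res
}

#' Run a spatial scan
#'
#' Evaluates the Poisson log likelihood-ratio statistic over every window
#' (circular or flexible per `config$mode`); the window with the maximum
#' statistic is the most likely cluster.  Significance is assessed by Monte
#' Carlo conditional on the total count N: each null replicate redistributes
#' the N cases over regions multinomially with probabilities E_i / sum(E),
#' and the p-value is (1 + #\{replicates whose maximum >= observed\}) /
#' (1 + n_monte_carlo).  Secondary clusters are reported greedily in
#' decreasing statistic order, skipping windows that overlap a higher-ranked
#' reported window; their p-values compare their statistic to the same null
#' distribution of the maximum.
#'
#' @param counts a [counts_data()] sharing region ids with `map`.
#' @param map a [region_map()].
#' @param config a [scan_config()].
#' @param windows optional precomputed window list (from
#'   [circular_windows()] or [flexible_windows()] on the same map and J),
#'   to amortize enumeration across repeated scans of one map.
#' @return An object of class `scan_result`: data frame with columns
#'   `rank`, `regions` (semicolon-joined ids), `n_regions`, `C_in`, `E_in`,
#'   `log_lr`, `p_value`; attributes `windows` (list), `max_stat`,
#'   `null_max` (the Monte Carlo maxima) and `mode`.
#' @export
scan <- function(counts, map, config, windows = NULL) {
  if (!setequal(counts$region_id, map$region_id)) {
    stop("counts and map must share the same region ids")
  }
  counts <- counts[match(map$region_id, counts$region_id), ]
  if (is.null(windows)) {
    ord <- nearest_neighbour_order(map)
    windows <- if (config$mode == "circular") {
      circular_windows(map, ord, config)
    } else {
      flexible_windows(map, ord, config)
    }
  }
  W <- .window_matrix(windows, map$m)
  E <- counts$expected
  C <- counts$observed
  N <- sum(C)
  Etot <- sum(E)
  Ewin <- as.numeric(W %*% E)

  Cwin <- as.numeric(W %*% C)
  stat <- log_likelihood_ratio(Cwin, Ewin, N, Etot)

  null_max <- withr::with_seed(config$seed, {
    reps <- config$n_monte_carlo
    nm <- numeric(reps)
    chunk <- max(1L, min(reps, floor(2e7 / max(length(windows), 1L))))
    done <- 0L
    while (done < reps) {
      k <- min(chunk, reps - done)
      Cr <- stats::rmultinom(k, N, E / Etot)
      nm[done + seq_len(k)] <- .max_llr(as.matrix(W %*% Cr), Ewin, N, Etot)
      done <- done + k
    }
    nm
  })

  keep <- order(-stat, lengths(windows))
  used <- logical(map$m)
  rows <- list()
  for (k in keep) {
    if (length(rows) >= config$n_report) break
    w <- windows[[k]]
    if (stat[k] <= 0 && length(rows) > 0L) break
    if (any(used[w])) next
    used[w] <- TRUE
    p <- (1 + sum(null_max >= stat[k])) / (1 + config$n_monte_carlo)
    rows[[length(rows) + 1L]] <- data.frame(
      rank = length(rows) + 1L,
      regions = paste(map$region_id[w], collapse = ";"),
      n_regions = length(w),
      C_in = Cwin[k], E_in = Ewin[k], log_lr = stat[k], p_value = p)
  }
  res <- do.call(rbind, rows)
  structure(res, windows = windows, max_stat = max(stat),
            null_max = null_max, mode = config$mode,
            class = c("scan_result", "data.frame"))
}

# sparse window-membership indicator (n_windows x m)
.window_matrix <- function(windows, m) {
  Matrix::sparseMatrix(
    i = rep(seq_along(windows), lengths(windows)),
    j = unlist(windows), x = 1, dims = c(length(windows), m))
}

# column-wise maximum of the log LR statistic over windows;
# Cwin is n_windows x n_replicates
.max_llr <- function(Cwin, Ewin, N, Etot) {
  xlogy <- function(x, y) {
    out <- x * log(x / y)
    out[x == 0] <- 0
    out
  }
  base <- if (N > 0) N * log(N / Etot) else 0
  apply(Cwin, 2L, function(cc) {
    s <- xlogy(cc, Ewin) + xlogy(N - cc, Etot - Ewin) - base
    s[cc <= Ewin] <- 0
    max(s, 0)
  })
}
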