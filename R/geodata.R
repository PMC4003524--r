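#' Construct a validated region map
#'
#' A `region_map` is the spatial substrate shared by every method in the
#' package: a set of region labels, one planar centroid per region, and a
#' symmetric, irreflexive adjacency relation whose graph must be connected
#' (both the CAR prior and the flexible scan windows require connectivity).
#'
#' @param region_ids vector of unique region labels (coerced to character
#'   internally; reported output always uses the input labels).
#' @param centroids numeric matrix or data frame with two columns (x, y),
#'   one row per region, all values finite.
#' @param edges two-column matrix or data frame of region-id pairs. Either
#'   direction (or both) may be given; the relation is symmetrized.
#' @return An object of class `region_map` with components `region_id`
#'   (character), `xy` (m x 2 numeric matrix), `edges` (two-column integer
#'   matrix of 1-based region indices, each undirected edge once, i < j),
#'   `adj` (list of integer neighbour indices per region) and `m`.
#' @examples
#' mp <- region_map(1:3, cbind(c(0, 1, 2), 0), rbind(c(1, 2), c(2, 3)))
#' mp$m
#' @export
region_map <- function(region_ids, centroids, edges) {
  ids <- as.character(region_ids)
  if (anyDuplicated(ids) > 0L) {
    stop(errorCondition(
      sprintf("duplicate region ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = c("arealclust_duplicate_ids", "arealclust_error", "error")))
  }
  m <- length(ids)
  if (m < 1L) stop("region map needs at least one region")
  xy <- as.matrix(centroids)
  storage.mode(xy) <- "double"
  if (nrow(xy) != m || ncol(xy) != 2L) {
    stop("centroids must have one (x, y) row per region")
  }
  if (!all(is.finite(xy))) stop("centroids must be finite")
  dimnames(xy) <- list(ids, c("x", "y"))

  e <- as.matrix(edges)
  if (length(e) == 0L) {
    eidx <- matrix(integer(0), 0L, 2L)
  } else {
    if (ncol(e) != 2L) stop("edges must have two columns")
    a <- match(as.character(e[, 1L]), ids)
    b <- match(as.character(e[, 2L]), ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(as.character(e)[is.na(match(as.character(e), ids))])
      stop(errorCondition(
        sprintf("adjacency refers to unknown region ids: %s",
                paste(bad, collapse = ", ")),
        class = c("arealclust_unknown_region", "arealclust_error", "error")))
    }
    if (any(a == b)) {
      stop(errorCondition(
        sprintf("adjacency contains self-pairs for region(s): %s",
                paste(unique(ids[a[a == b]]), collapse = ", ")),
        class = c("arealclust_self_loop", "arealclust_error", "error")))
    }
    eidx <- unique(cbind(pmin(a, b), pmax(a, b)))
    eidx <- eidx[order(eidx[, 1L], eidx[, 2L]), , drop = FALSE]
  }

  g <- igraph::graph_from_edgelist(matrix(ids[t(eidx)], ncol = 2L,
                                          byrow = TRUE), directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  if (m > 1L && !igraph::is_connected(g)) {
    stop(errorCondition(
      "adjacency graph is disconnected; the CAR model and flexible scan require a connected map",
      class = c("arealclust_disconnected", "arealclust_error", "error")))
  }

  adj <- rep(list(integer(0)), m)
  if (nrow(eidx) > 0L) {
    for (k in seq_len(nrow(eidx))) {
      i <- eidx[k, 1L]; j <- eidx[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }

  structure(list(region_id = ids, xy = xy, edges = eidx, adj = adj, m = m),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d regions, %d undirected edges\n",
              x$m, nrow(x$edges)))
  invisible(x)
}

#' @export
format.region_map <- function(x, ...) {
  sprintf("<region_map: m=%d, edges=%d>", x$m, nrow(x$edges))
}

#' Read a region map from node and adjacency files
#'
#' The node file is a CSV with header `region_id,x,y`; the adjacency file a
#' two-column CSV `region_a,region_b` listing unordered neighbour pairs
#' (one direction suffices; the relation is symmetrized).
#'
#' @param path_nodes path to the node CSV.
#' @param path_adjacency path to the adjacency CSV.
#' @return A validated [region_map()].
#' @export
load_region_map <- function(path_nodes, path_adjacency) {
  nodes <- utils::read.csv(path_nodes, colClasses = c("character", NA, NA))
  if (!all(c("region_id", "x", "y") %in% names(nodes))) {
    stop("node file must have columns region_id, x, y")
  }
  adj <- utils::read.csv(path_adjacency, colClasses = "character")
  region_map(nodes$region_id, as.matrix(nodes[, c("x", "y")]),
             as.matrix(adj[, 1:2]))
}

#' Write a region map to node and adjacency CSV files
#'
#' Inverse of [load_region_map()]: `load_region_map` on the written files
#' reconstructs an identical map.
#'
#' @param map a [region_map()].
#' @param path_nodes,path_adjacency output CSV paths.
#' @return `map`, invisibly.
#' @export
write_region_map <- function(map, path_nodes, path_adjacency) {
  nodes <- data.frame(region_id = map$region_id,
                      x = map$xy[, "x"], y = map$xy[, "y"])
  utils::write.csv(nodes, path_nodes, row.names = FALSE, quote = FALSE)
  adj <- data.frame(region_a = map$region_id[map$edges[, 1L]],
                    region_b = map$region_id[map$edges[, 2L]])
  utils::write.csv(adj, path_adjacency, row.names = FALSE, quote = FALSE)
  invisible(map)
}

#' Nearest-neighbour ordering of regions
#'
#' For each region i, all regions sorted by increasing Euclidean centroid
#' distance from i, with i itself first.  The first j entries of row i form
#' the circular scan window of size j anchored at i, and the first J entries
#' bound the candidate set for flexible windows.  Exact distance ties are
#' broken by ascending position of the region in `map$region_id`, so window
#' sets are reproducible across platforms.
#'
#' @param map a [region_map()].
#' @return An object of class `neighbour_order`: an m x m integer matrix of
#'   1-based region indices, row i being the ordering around region i, plus
#'   a `dist` attribute holding the matching sorted distances.
#' @export
nearest_neighbour_order <- function(map) {
  d <- as.matrix(stats::dist(map$xy))
  m <- map$m
  ord <- matrix(0L, m, m)
  dst <- matrix(0, m, m)
  idr <- .id_rank(map$region_id)
  for (i in seq_len(m)) {
    o <- order(d[i, ], idr)
    # self is at distance 0; ties at 0 cannot occur (ids unique, but
    # coincident centroids could) -- force self first regardless
    o <- c(i, o[o != i])
    ord[i, ] <- o
    dst[i, ] <- d[i, o]
  }
  structure(ord, dist = dst, class = c("neighbour_order", "matrix"))
}

# Tie-break rank of region ids: numeric when all ids parse as numbers
# (so "10" sorts after "2"), lexicographic otherwise.
.id_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) rank(num, ties.method = "first") else
    rank(ids, ties.method = "first")
}
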