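#' Format a cross-method ranking table
#'
#' Turns a [compare_methods()] result into a printable character table with
#' one row per region that at least one method flagged: columns are the
#' scan cluster ranks and the model-based ranks under each relative-risk
#' threshold, with absences rendered as "-".  Emission is a pure function
#' of its input, so repeated calls are byte-identical.
#'
#' @param comparison a [compare_methods()] result.
#' @param keep_all keep regions no method flagged (default FALSE).
#' @return A character data frame of class `method_table`.
#' @export
render_table <- function(comparison, keep_all = FALSE) {
  tab <- comparison$table
  rank_cols <- setdiff(names(tab), "region_id")
  chr <- tab
  for (cl in rank_cols) {
    chr[[cl]] <- ifelse(is.na(tab[[cl]]), "-", as.character(tab[[cl]]))
  }
  if (!keep_all) {
    any_call <- rowSums(!is.na(tab[rank_cols])) > 0
    chr <- chr[any_call, , drop = FALSE]
  }
  rownames(chr) <- NULL
  class(chr) <- c("method_table", "data.frame")
  chr
}

#' Write a method table as CSV and/or Markdown
#'
#' @param x a [render_table()] result.
#' @param path_csv,path_md output paths; NULL skips that format.
#' @return `x`, invisibly.
#' @export
write_method_table <- function(x, path_csv = NULL, path_md = NULL) {
  if (!is.null(path_csv)) {
    utils::write.csv(as.data.frame(x), path_csv, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(path_md)) {
    header <- paste0("| ", paste(names(x), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(x)), collapse = "|"), "|")
    body <- apply(x, 1L, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    writeLines(c(header, sep, body), path_md)
  }
  invisible(x)
}

#' Plot a region map with cluster calls
#'
#' Draws region centroids and adjacency edges, highlighting called regions
#' (colour-graded by rank when ranks are present).  Purely cosmetic output
#' for eyeballing synthetic runs; numeric results live in the tables.
#'
#' @param map a [region_map()].
#' @param calls optional [call_regions()] data frame (or any data frame
#'   with `region_id`, `called` and optionally `rank`).
#' @param file output PNG path.
#' @param width,height,res passed to [grDevices::png()].
#' @return `file`, invisibly.
#' @export
render_map <- function(map, calls = NULL, file, width = 900, height = 900,
                       res = 120) {
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  xy <- map$xy
  plot(xy, type = "n", xlab = "x", ylab = "y", asp = 1,
       main = "region map")
  segments(xy[map$edges[, 1L], 1L], xy[map$edges[, 1L], 2L],
           xy[map$edges[, 2L], 1L], xy[map$edges[, 2L], 2L],
           col = "grey80")
  col <- rep("grey40", map$m)
  cex <- rep(0.9, map$m)
  if (!is.null(calls)) {
    idx <- match(calls$region_id, map$region_id)
    hot <- idx[calls$called]
    if (length(hot) > 0L) {
      if ("rank" %in% names(calls) && any(!is.na(calls$rank))) {
        rk <- calls$rank[calls$called]
        shade <- grDevices::hcl.colors(max(rk, na.rm = TRUE), "Reds",
                                       rev = TRUE)
        col[hot] <- shade[pmin(rk, length(shade))]
      } else {
        col[hot] <- "red3"
      }
      cex[hot] <- 1.4
    }
  }
  points(xy, pch = 19, col = col, cex = cex)
  text(xy, labels = map$region_id, pos = 3, cex = 0.55, col = "grey30")
  invisible(file)
}
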