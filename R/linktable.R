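# ---- link table -------------------------------------------------------------

#' Assemble a link table
#'
#' Collects the pairwise links of an M x N grid: `(M-1) N` north links and
#' `M (N-1)` west links, `2MN - (M+N)` in total. Rows are ordered north links
#' first, then west links, each row-major by reference tile.
#'
#' @param links data.frame of link rows (see [register_pair()]).
#' @param M,N grid dimensions (rows, columns).
#' @return the data.frame with class `link_table` and attributes `M`, `N`.
#' @export
link_table <- function(links, M, N) {
  expected <- 2L * M * N - (M + N)
  if (nrow(links) != expected) {
    stop(sprintf("link table for a %dx%d grid needs %d links, got %d",
                 M, N, expected, nrow(links)))
  }
  structure(links, class = c("link_table", "data.frame"),
            M = as.integer(M), N = as.integer(N))
}

#' @export
print.link_table <- function(x, ...) {
  cat(sprintf("<link_table: %dx%d grid, %d links (%d valid, %d invalid)>\n",
              attr(x, "M"), attr(x, "N"), nrow(x),
              sum(x$status == "valid"), sum(x$status == "invalid")))
  invisible(x)
}

#' Write/read a link table as CSV
#' @param table a `link_table`.
#' @param path file path.
#' @export
write_link_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_link_table
#' @param M,N grid dimensions of the stored table.
#' @export
read_link_table <- function(path, M, N) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$n_matched <- as.integer(df$n_matched)
  link_table(df, M, N)
}

# ---- repair of invalid links ------------------------------------------------

#' Repair invalid links from row/column averages
#'
#' Invalid north links are replaced by the component-wise mean translation of
#' the valid north links whose reference tile lies in the same grid row; if
#' that row has no valid north link, the mean over all valid north links is
#' used. West links are repaired symmetrically by reference column. The
#' rationale is mechanical: tiles in one row share the same vertical stage
#' step, tiles in one column the same horizontal step. Repaired links keep a
#' sentinel matched count (`NA`) so the alignment graph can penalize them,
#' and are marked `stage_used = "repaired"`. Valid links are untouched;
#' averages are taken over the originally valid links only, so the operation
#' is a single pass and idempotent.
#'
#' @param table a `link_table`.
#' @return the repaired `link_table` (all translations finite).
#' @export
repair_links <- function(table) {
  M <- attr(table, "M")
  N <- attr(table, "N")
  for (dir in c("north", "west")) {
    in_dir <- table$direction == dir
    if (!any(in_dir)) next
    valid <- in_dir & table$status == "valid"
    bad <- in_dir & table$status == "invalid"
    if (!any(bad)) next
    if (!any(valid)) {
      stop(sprintf(paste0("no valid %s link in the entire grid: ",
                          "cannot repair by row/column averages"), dir))
    }
    group <- if (dir == "north") table$ref_row else table$ref_col
    gmean_x <- tapply(table$t_x[valid], group[valid], mean)
    gmean_y <- tapply(table$t_y[valid], group[valid], mean)
    all_x <- mean(table$t_x[valid])
    all_y <- mean(table$t_y[valid])
    for (i in which(bad)) {
      g <- as.character(group[i])
      if (g %in% names(gmean_x)) {
        table$t_x[i] <- gmean_x[[g]]
        table$t_y[i] <- gmean_y[[g]]
      } else {
        table$t_x[i] <- all_x
        table$t_y[i] <- all_y
      }
      table$status[i] <- "valid"
      table$stage_used[i] <- "repaired"
      table$n_matched[i] <- NA_integer_
    }
  }
  table
}
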