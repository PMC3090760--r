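# result table writer

#' Write scan/alignment records as a TSV table
#'
#' Tab-separated table with the canonical header `query_id, target_id,
#' window_start, window_end, score, q_begin, q_end, t_begin, t_end`,
#' ordered deterministically by target then window start.  Optional
#' comment lines (provenance) are written first, prefixed with `#`.
#'
#' @param records data.frame of records (extra columns are kept after
#'   the canonical ones); an empty data.frame gives a header-only file.
#' @param path output path.
#' @param comments character vector of provenance lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, comments = character(0)) {
  canonical <- c("query_id", "target_id", "window_start", "window_end",
                 "score", "q_begin", "q_end", "t_begin", "t_end")
  if (nrow(records)) {
    missing_cols <- setdiff(canonical, names(records))
    for (cc in missing_cols) records[[cc]] <- NA
    records <- records[order(records$target_id, records$window_start), ,
                       drop = FALSE]
    extra <- setdiff(names(records), canonical)
    records <- records[, c(canonical, extra), drop = FALSE]
  } else {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(canonical)),
                                      canonical))
  }
  con <- suppressWarnings(try(file(path, "w"), silent = TRUE))
  if (inherits(con, "try-error"))
    stop("cannot write results to ", path, call. = FALSE)
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path file path.
#' @return data.frame (comment lines are skipped).
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
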