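#' Write a results table as TSV
#'
#' Deterministic column order (as in the input), tab-delimited, no quoting.
#' Signed fold-change columns (`fc_ipsi`, `fc_contra`) are rendered to two
#' decimals with `~` for "no qualifying change" (`NA`). For a hierarchy table
#' ([build_gih()]) the two fold changes are combined into a single
#' `fold_change` cell, e.g. `"3.37 | ~"`.
#'
#' @param records A data frame (possibly empty: a header-only file is
#'   written), or a `gih_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  UseMethod("write_results_table")
}

#' @export
write_results_table.default <- function(records, path) {
  records <- as.data.frame(records)
  for (col in intersect(c("fc_ipsi", "fc_contra"), names(records))) {
    records[[col]] <- fmt_fc(records[[col]])
  }
  for (col in intersect(c("ratio"), names(records))) {
    records[[col]] <- ifelse(is.na(records[[col]]), "",
                             sprintf("%.2f", records[[col]]))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to \"", path, "\": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results_table.gih_table <- function(records, path) {
  df <- as.data.frame(records)
  df$fold_change <- paste(fmt_fc(df$fc_ipsi), "|", fmt_fc(df$fc_contra))
  keep <- c("symbol", "tier", "connection_count", "fold_change",
            "compartment", "molecule_type")
  df <- df[, intersect(keep, names(df)), drop = FALSE]
  write_results_table.default(df, path)
}
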