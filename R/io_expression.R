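#' Read a sample-to-group map
#'
#' Two-column tab-delimited file (`sample`, `group`), with or without a
#' header line.
#'
#' @param path File path.
#' @return Named character vector mapping sample id to group label.
#' @export
read_group_map <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   strip.white = TRUE)
  if (ncol(df) != 2) {
    stop("group map must have exactly two columns (sample, group)",
         call. = FALSE)
  }
  if (tolower(df[1, 1]) == "sample" && tolower(df[1, 2]) == "group") {
    df <- df[-1, , drop = FALSE]
  }
  setNames(df[[2]], df[[1]])
}

#' Read a signal + detection-call expression table
#'
#' The expected dialect is a tab-delimited file whose first column holds gene
#' ids and whose remaining columns come in pairs: `<sample>` (numeric signal)
#' and `<sample>.call` (detection call `P`/`M`/`A`).
#'
#' @param path File path.
#' @param group_map Named character vector mapping each sample to its group,
#'   or the path of a file readable by [read_group_map()].
#' @return A validated [expression_dataset()].
#' @export
read_expression_table <- function(path, group_map) {
  if (is.character(group_map) && is.null(names(group_map)) &&
      length(group_map) == 1) {
    group_map <- read_group_map(group_map)
  }
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   strip.white = TRUE)
  if (ncol(df) < 3) {
    stop("expression table needs a gene column plus signal/call pairs",
         call. = FALSE)
  }
  gene_ids <- df[[1]]
  cols <- names(df)[-1]
  call_cols <- grep("\\.call$", cols, value = TRUE)
  samples <- setdiff(cols, call_cols)
  for (s in samples) {
    if (!paste0(s, ".call") %in% call_cols) {
      stop(sprintf("missing call column \"%s.call\" for sample \"%s\"", s, s),
           call. = FALSE)
    }
  }
  unknown <- setdiff(samples, names(group_map))
  if (length(unknown) > 0) {
    stop("samples absent from the group map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  signal <- matrix(NA_real_, length(gene_ids), length(samples),
                   dimnames = list(gene_ids, samples))
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !is.na(df[[s]]) & df[[s]] != "")
    if (length(bad) > 0) {
      stop(sprintf(
        "non-numeric signal \"%s\" for gene \"%s\", sample \"%s\"",
        df[[s]][bad[1]], gene_ids[bad[1]], s
      ), call. = FALSE)
    }
    signal[, s] <- v
  }
  call <- as.matrix(df[, paste0(samples, ".call"), drop = FALSE])
  dimnames(call) <- list(gene_ids, samples)
  expression_dataset(signal, call, group_map)
}

#' Write an expression dataset in signal/call pair format
#'
#' Inverse of [read_expression_table()]; `read(write(x))` reproduces `x` up
#' to floating-point printing precision.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  samples <- colnames(dataset$signal)
  out <- data.frame(gene_id = rownames(dataset$signal),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[s]] <- format(dataset$signal[, s], digits = 15, trim = TRUE,
                       scientific = FALSE)
    out[[paste0(s, ".call")]] <- dataset$call[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
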