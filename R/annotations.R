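#' Read a gene annotation table
#'
#' Tab-delimited with a header; requires `symbol`, `compartment` and
#' `molecule_type` columns, and optionally `gene_id` and `entrez_name`.
#' Compartments outside the recognized vocabulary (extracellular space,
#' plasma membrane, cytoplasm, nucleus) are kept verbatim but sort with
#' "unknown" in hierarchy layouts.
#'
#' @param path File path.
#' @return A data frame, one row per unique symbol (first annotation wins on
#'   duplicates).
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   strip.white = TRUE)
  need <- c("symbol", "compartment", "molecule_type")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[!duplicated(df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  df
}
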