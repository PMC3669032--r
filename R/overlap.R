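#' Overlap of one biological-function set with the IR set
#'
#' @param function_name Name of the function set.
#' @param function_set Character vector of member symbols (non-empty).
#' @param ir_set Character vector of inflammatory-response symbols.
#' @return One-row data frame: `function_name`, `unique_genes` (size of the
#'   function set), `overlap_ir` (shared symbols), `percent` (integer,
#'   half-up, of the function-set size).
#' @export
overlap_percent <- function(function_name, function_set, ir_set) {
  function_set <- unique(function_set)
  ir_set <- unique(ir_set)
  if (length(function_set) == 0) {
    stop("empty function set", call. = FALSE)
  }
  ov <- length(intersect(function_set, ir_set))
  data.frame(
    function_name = function_name,
    unique_genes = length(function_set),
    overlap_ir = ov,
    percent = as.integer(round_half_up(100 * ov / length(function_set))),
    stringsAsFactors = FALSE
  )
}

#' Overlap table for a gene-set collection against its IR set
#'
#' @param collection A [gene_set_collection()].
#' @param ir_name Name of the IR set (default: the collection's designated
#'   IR set). The IR set itself is excluded from the rows.
#' @return Data frame of [overlap_percent()] rows, one per non-IR set.
#' @export
overlap_table <- function(collection, ir_name = NULL) {
  ir_name <- ir_name %||% attr(collection, "ir_name")
  if (is.null(ir_name) || !ir_name %in% names(collection)) {
    stop("IR set name does not resolve in the collection", call. = FALSE)
  }
  ir <- collection[[ir_name]]
  others <- setdiff(names(collection), ir_name)
  do.call(rbind, lapply(others, function(nm) {
    overlap_percent(nm, collection[[nm]], ir)
  }))
}

#' Cumulative overlap across function sets
#'
#' Pooled-count definition: `100 * sum(overlap_ir) / sum(unique_genes)`,
#' reported to one decimal. With a single record this reduces to the same
#' quantity as [overlap_percent()] before integer rounding.
#'
#' @param records Data frame with `unique_genes` and `overlap_ir` columns
#'   (at least one row).
#' @return Percentage, one decimal.
#' @export
cumulative_overlap <- function(records) {
  if (nrow(records) == 0) {
    stop("need at least one overlap record", call. = FALSE)
  }
  tot_unique <- sum(records$unique_genes)
  if (tot_unique == 0) {
    stop("total unique-gene count is zero", call. = FALSE)
  }
  round_half_up(100 * sum(records$overlap_ir) / tot_unique, 1)
}

#' Hypergeometric over-representation p-value for a set overlap
#'
#' One-sided tail probability `P[X >= overlap]` where `X` is the size of the
#' intersection of a random `function_size`-subset of the universe with the
#' IR set (Fisher's exact test, enrichment alternative).
#'
#' @param overlap Observed intersection size.
#' @param function_size,ir_size,universe Set sizes; must satisfy
#'   `overlap <= min(function_size, ir_size)` and both sizes `<= universe`.
#' @return p-value in (0, 1].
#' @export
enrichment_pvalue <- function(overlap, function_size, ir_size, universe) {
  ok <- overlap >= 0 && function_size >= 0 && ir_size >= 0 &&
    overlap <= min(function_size, ir_size) &&
    max(function_size, ir_size) <= universe
  if (!ok) {
    stop("inconsistent counts: need overlap <= min(function_size, ir_size) <= universe",
         call. = FALSE)
  }
  phyper(overlap - 1, ir_size, universe - ir_size, function_size,
         lower.tail = FALSE)
}
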