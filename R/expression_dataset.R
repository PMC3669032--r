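#' Construct a validated expression dataset
#'
#' Bundles a genes-by-samples signal matrix with its per-cell detection calls
#' and a sample-to-group assignment. Signals are MAS5-style summarized
#' intensities (non-negative); detection calls are the usual
#' Present/Marginal/Absent flags.
#'
#' @param signal Numeric matrix, genes x samples, with row names (gene ids)
#'   and column names (sample ids). All values must be finite and >= 0.
#' @param call Character matrix of the same shape with entries in
#'   `c("P", "M", "A")`.
#' @param groups Named character vector mapping every sample id to its group
#'   (e.g. `"ipsilateral"`, `"contralateral"`, `"naive"`).
#' @return An object of class `expression_dataset`: a list with elements
#'   `signal`, `call` and `groups`.
#' @examples
#' sig <- matrix(c(100, 200, 50, 120, 210, 40), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cl <- matrix("P", 3, 2, dimnames = dimnames(sig))
#' ds <- expression_dataset(sig, cl, c(s1 = "naive", s2 = "ipsilateral"))
#' @export
expression_dataset <- function(signal, call, groups) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(signal)) || is.null(colnames(signal))) {
    stop("`signal` must have row names (genes) and column names (samples)",
         call. = FALSE)
  }
  if (!is.matrix(call) || !identical(dim(call), dim(signal))) {
    stop("`call` must be a matrix with the same shape as `signal`",
         call. = FALSE)
  }
  call <- matrix(as.character(call), nrow(signal), ncol(signal),
                 dimnames = dimnames(signal))
  bad <- which(matrix(!(call %in% c("P", "M", "A")), nrow(call)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid detection call \"%s\" for gene \"%s\", sample \"%s\" (allowed: P, M, A)",
      call[bad[1, 1], bad[1, 2]],
      rownames(signal)[bad[1, 1]],
      colnames(signal)[bad[1, 2]]
    ), call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` contains missing or non-finite values", call. = FALSE)
  }
  if (any(signal < 0)) {
    stop("`signal` must be non-negative", call. = FALSE)
  }
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(signal), names(groups))
  if (length(missing) > 0) {
    stop("samples with no group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- groups[colnames(signal)]
  structure(
    list(signal = signal, call = call, groups = groups),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$signal)

#' Sample ids belonging to a group
#'
#' @param dataset An [expression_dataset()].
#' @param group Group label.
#' @return Character vector of sample ids; errors if the group is empty.
#' @export
group_samples <- function(dataset, group) {
  stopifnot(inherits(dataset, "expression_dataset"))
  s <- names(dataset$groups)[dataset$groups == group]
  if (length(s) == 0) {
    stop(sprintf("group \"%s\" has no samples", group), call. = FALSE)
  }
  s
}
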