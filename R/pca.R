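#' Principal-component scores for sample QC
#'
#' Gene-wise mean-centers the (optionally log2-transformed) signal matrix and
#' computes sample scores by projecting each sample's gene vector onto the
#' leading right singular vectors of the centered matrix. Variance fractions
#' come from the squared singular values over the total. With strong group
#' effects, samples cluster by group in the leading components, which is the
#' QC check this supports.
#'
#' Component signs are fixed by making the largest-magnitude gene loading of
#' each component positive, so output is deterministic.
#'
#' @param dataset An [expression_dataset()] or a plain numeric genes-by-samples
#'   matrix.
#' @param n_components Number of components to return (default: all,
#'   `min(genes, samples)`).
#' @param log2_transform Apply `log2(signal + 1)` before centering
#'   (default `TRUE`; disable when signals are already on log scale).
#' @return An object of class `pca_result`: list with `scores`
#'   (samples x components), `variance_fraction` (one entry per returned
#'   component, fractions of *total* variance) and `n_components`.
#' @export
pca_scores <- function(dataset, n_components = NULL, log2_transform = TRUE) {
  x <- if (inherits(dataset, "expression_dataset")) dataset$signal else dataset
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`dataset` must be an expression_dataset or numeric matrix",
         call. = FALSE)
  }
  if (ncol(x) < 2) {
    stop("PCA needs at least two samples", call. = FALSE)
  }
  k_max <- min(dim(x))
  n_components <- n_components %||% k_max
  if (n_components < 1 || n_components > k_max) {
    stop(sprintf("`n_components` must be in [1, %d]", k_max), call. = FALSE)
  }
  if (log2_transform) {
    x <- log2(x + 1)
  }
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  total <- sum(sv$d^2)
  if (total <= .Machine$double.eps * length(xc)) {
    # constant matrix: no variance anywhere
    scores <- matrix(0, ncol(x), n_components,
                     dimnames = list(colnames(x), paste0("PC", seq_len(n_components))))
    return(structure(list(scores = scores,
                          variance_fraction = rep(0, n_components),
                          n_components = n_components),
                     class = "pca_result"))
  }
  # deterministic sign: largest-|loading| gene positive per component
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(sv$u[, j]))
    if (sv$u[i_max, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  scores <- sv$v[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  structure(
    list(scores = scores,
         variance_fraction = sv$d[seq_len(n_components)]^2 / total,
         n_components = n_components),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s), %d sample(s)\n",
              x$n_components, nrow(x$scores)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
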