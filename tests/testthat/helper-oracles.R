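# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation (piecewise formulas, brute-force
# enumeration, set comprehension) kept separate from the package code paths.

# Piecewise fold-ratio formulas, one branch per sign case, transcribed
# directly rather than via the linear-scale simplification the package uses.
oracle_fold_ratio <- function(i, c) {
  if (i > 0 && c > 0) {
    i / c
  } else if (i < 0 && c < 0) {
    1 / (i / c)                    # = 1/[(TBI-I)/(TBI-C)]
  } else if (i > 0 && c < 0) {
    i / -(1 / c)                   # = (TBI-I)/-[1/(TBI-C)]
  } else {
    (1 / abs(i)) / c               # down ipsilaterally, up contralaterally
  }
}

# Brute-force hypergeometric upper tail: sum the combinatorial masses.
oracle_hyper_tail <- function(overlap, function_size, ir_size, universe) {
  ks <- overlap:min(function_size, ir_size)
  sum(choose(ir_size, ks) * choose(universe - ir_size, function_size - ks)) /
    choose(universe, function_size)
}

# Set-comprehension induced-subgraph filter on a raw edge matrix.
oracle_induced_edges <- function(edges, goi) {
  keep <- edges[, 1] %in% goi & edges[, 2] %in% goi
  e <- edges[keep, , drop = FALSE]
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# Eigendecomposition of the sample cross-product matrix as a PCA oracle:
# scores are eigenvectors scaled by sqrt(eigenvalue), defined up to sign.
oracle_pca <- function(x) {
  xc <- x - rowMeans(x)
  B <- crossprod(xc)               # samples x samples
  e <- eigen(B, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(scores = e$vectors %*% diag(sqrt(lam), length(lam)),
       variance_fraction = lam / sum(lam))
}

# Small deterministic three-group dataset builder for hand-computed cases.
make_tiny_dataset <- function(signal_rows, calls = NULL, replicates = 3) {
  signal <- do.call(rbind, signal_rows)
  rownames(signal) <- names(signal_rows)
  samples <- c(paste0("n", seq_len(replicates)),
               paste0("i", seq_len(replicates)),
               paste0("c", seq_len(replicates)))
  colnames(signal) <- samples
  if (is.null(calls)) {
    calls <- matrix("P", nrow(signal), ncol(signal), dimnames = dimnames(signal))
  }
  groups <- setNames(rep(c("naive", "ipsilateral", "contralateral"),
                         each = replicates), samples)
  expression_dataset(signal, calls, groups)
}
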