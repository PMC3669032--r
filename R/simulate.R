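# Synthetic-data generators with known ground truth: a three-group
# expression matrix with planted bilateral response classes, and a tiered
# interaction network with a prescribed degree structure.

# Default planted class sizes mirror the bilateral partition of the
# inflammatory-response genes in the study design this package emulates:
# 146 common (109 similar = 79 up + 30 down; 37 different),
# 188 ipsilateral-unique (179 up, 9 down),
# 38 contralateral-unique (10 up, 28 down) -- 372 changed genes in all.
DEFAULT_CLASS_SIZES <- c(
  "common-similar-up" = 79,
  "common-similar-down" = 30,
  "common-different" = 37,
  "ipsi-unique-up" = 179,
  "ipsi-unique-down" = 9,
  "contra-unique-up" = 10,
  "contra-unique-down" = 28
)

#' Simulate a three-group expression dataset with planted bilateral classes
#'
#' Naive-group means are drawn from a log-normal baseline; ipsilateral and
#' contralateral means are the baseline multiplied (divided, for negative
#' effects) by planted signed fold effects drawn per class:
#'
#' * `common-similar-*`: both hemispheres respond in the same direction with
#'   a planted fold ratio at most `1.4` (safely below the 1.75 divergence
#'   cutoff);
#' * `common-different`: ipsilateral response exceeds the contralateral one
#'   by a planted ratio of at least `2.2` (safely above the cutoff);
#' * `*-unique-*`: one hemisphere changes (magnitude in `effect_range`), the
#'   other stays at baseline;
#' * remaining genes are nulls (no effect).
#'
#' Replicate noise is multiplicative log-normal. Detection calls are `P`
#' when the signal is at or above `call_floor` and `A` otherwise; null genes
#' additionally get forced `A` calls at rate `absent_rate` so the presence
#' filter is exercised. Baselines of changed genes are lifted far enough
#' above the floor that their calls stay `P` even after the planted
#' down-regulation, which makes recovery exact in the zero-noise limit.
#'
#' @param n_genes Total genes (default 1000; must be at least the sum of
#'   class sizes).
#' @param replicates Samples per group (default 3).
#' @param class_sizes Named integer vector over the seven changed classes
#'   (defaults above).
#' @param effect_range Fold-magnitude range for planted unique and similar
#'   effects (default `c(2.5, 8)`; minimum must be >= 2).
#' @param different_ratio_range Planted ipsilateral/contralateral fold-ratio
#'   range for the "different" class (default `c(2.2, 8)`).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (defaults 6 and 1, i.e. median signal ~400).
#' @param noise_sd Multiplicative noise sd on the natural-log scale
#'   (default 0.1).
#' @param call_floor Absolute signal floor for a Present call (default 30).
#' @param absent_rate Per-cell forced-Absent rate for null genes
#'   (default 0.1).
#' @param seed Optional integer seed; a given seed fully determines the
#'   output.
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (data frame `gene_id`, `class`, `effect_ipsi`, `effect_contra` with
#'   signed planted effects, `1` meaning no change).
#' @export
simulate_expression <- function(n_genes = 1000,
                                replicates = 3,
                                class_sizes = DEFAULT_CLASS_SIZES,
                                effect_range = c(2.5, 8),
                                different_ratio_range = c(2.2, 8),
                                baseline_meanlog = 6,
                                baseline_sdlog = 1,
                                noise_sd = 0.1,
                                call_floor = 30,
                                absent_rate = 0.1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  class_sizes <- class_sizes[class_sizes > 0]
  bad <- setdiff(names(class_sizes), names(DEFAULT_CLASS_SIZES))
  if (length(bad) > 0) {
    stop("unknown class name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_changed <- sum(class_sizes)
  if (n_changed > n_genes) {
    stop(sprintf("class sizes sum to %d > n_genes = %d", n_changed, n_genes),
         call. = FALSE)
  }
  if (effect_range[1] < 2) {
    stop("planted changed effects must be at least 2-fold", call. = FALSE)
  }

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  class <- rep("null", n_genes)
  class[seq_len(n_changed)] <- rep(names(class_sizes), class_sizes)

  eff_i <- rep(1, n_genes)
  eff_c <- rep(1, n_genes)
  draw <- function(n, lo, hi) runif(n, lo, hi)
  for (cl in names(class_sizes)) {
    idx <- which(class == cl)
    n <- length(idx)
    if (cl == "common-similar-up" || cl == "common-similar-down") {
      base <- draw(n, max(effect_range[1], 2 * 1.4), effect_range[2])
      r <- draw(n, 1, 1.4)
      s <- if (cl == "common-similar-up") 1 else -1
      eff_i[idx] <- s * base
      eff_c[idx] <- s * base / r          # ratio base/(base/r) = r <= 1.4
    } else if (cl == "common-different") {
      contra <- draw(n, 2, 3)
      r <- draw(n, different_ratio_range[1], different_ratio_range[2])
      eff_i[idx] <- contra * r            # both up, ratio r > 1.75
      eff_c[idx] <- contra
    } else if (cl == "ipsi-unique-up") {
      eff_i[idx] <- draw(n, effect_range[1], effect_range[2])
    } else if (cl == "ipsi-unique-down") {
      eff_i[idx] <- -draw(n, effect_range[1], effect_range[2])
    } else if (cl == "contra-unique-up") {
      eff_c[idx] <- draw(n, effect_range[1], effect_range[2])
    } else if (cl == "contra-unique-down") {
      eff_c[idx] <- -draw(n, effect_range[1], effect_range[2])
    }
  }

  baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  # keep changed genes detectable after down-regulation (factor 4 headroom
  # over the call floor covers the replicate noise tails)
  down <- pmax(1, abs(pmin(eff_i, -1)), abs(pmin(eff_c, -1)))
  changed <- class != "null"
  baseline[changed] <- pmax(baseline[changed],
                            call_floor * 4 * down[changed])

  apply_effect <- function(base, eff) {
    ifelse(eff >= 0, base * eff, base / abs(eff))
  }
  mu <- cbind(
    matrix(baseline, n_genes, replicates),
    matrix(apply_effect(baseline, eff_i), n_genes, replicates),
    matrix(apply_effect(baseline, eff_c), n_genes, replicates)
  )
  samples <- c(sprintf("naive_%d", seq_len(replicates)),
               sprintf("ipsi_%d", seq_len(replicates)),
               sprintf("contra_%d", seq_len(replicates)))
  groups <- setNames(rep(c(GROUP_NAIVE, GROUP_IPSI, GROUP_CONTRA),
                         each = replicates), samples)
  noise <- if (noise_sd > 0) {
    matrix(exp(rnorm(length(mu), 0, noise_sd)), n_genes)
  } else 1
  signal <- mu * noise
  dimnames(signal) <- list(gene_ids, samples)

  call <- ifelse(signal >= call_floor, "P", "A")
  if (absent_rate > 0) {
    null_rows <- which(!changed)
    forced <- matrix(runif(length(null_rows) * length(samples)) < absent_rate,
                     length(null_rows))
    call[null_rows, ][forced] <- "A"
  }
  dimnames(call) <- dimnames(signal)

  list(
    dataset = expression_dataset(signal, call, groups),
    truth = data.frame(gene_id = gene_ids, class = class,
                       effect_ipsi = eff_i, effect_contra = eff_c,
                       stringsAsFactors = FALSE)
  )
}

# Havel-Hakimi realization of a graphical degree sequence; deterministic
# fallback when the uniform sampler rejects a sequence.
havel_hakimi_edges <- function(degrees) {
  n <- length(degrees)
  rem <- degrees
  edges <- matrix(integer(0), 0, 2)
  repeat {
    ord <- order(rem, decreasing = TRUE)
    v <- ord[1]
    d <- rem[v]
    if (d == 0) break
    targets <- ord[2:(d + 1)]
    if (any(rem[targets] == 0)) {
      stop("degree sequence is not graphical", call. = FALSE)
    }
    edges <- rbind(edges, cbind(v, targets))
    rem[v] <- 0
    rem[targets] <- rem[targets] - 1
  }
  edges
}

#' Simulate a tiered interaction network with known ground truth
#'
#' Draws a target degree for each non-orphan node uniformly from its tier's
#' range, fixes parity, and realizes the sequence as a simple undirected
#' graph (uniform connected realization where possible, deterministic
#' Havel-Hakimi otherwise). Orphan nodes are added as isolated vertices.
#' Optional rewiring noise re-targets each edge endpoint independently with
#' probability `rewire_prob`, degrading tier recoverability gracefully.
#'
#' @param tier_sizes Named integer vector over
#'   `c("primary", "secondary", "peripheral", "orphan")`
#'   (default `c(20, 34, 41, 19)`).
#' @param degree_ranges Named list of `c(lo, hi)` degree ranges for the three
#'   connected tiers (defaults: primary 11--20, secondary 5--10,
#'   peripheral 1--4, matching the >10 / 5--10 / <5 tier rule).
#' @param rewire_prob Per-edge rewiring probability in `[0, 1]` (default 0).
#' @param seed Optional integer seed.
#' @return List with `network` (an [interaction_network()]) and `truth`
#'   (data frame `symbol`, `tier`, `degree` of intended tiers/degrees).
#' @export
simulate_network <- function(tier_sizes = c(primary = 20, secondary = 34,
                                            peripheral = 41, orphan = 19),
                             degree_ranges = list(primary = c(11, 20),
                                                  secondary = c(5, 10),
                                                  peripheral = c(1, 4)),
                             rewire_prob = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tier_sizes <- tier_sizes[GIH_TIERS]
  tier_sizes[is.na(tier_sizes)] <- 0
  names(tier_sizes) <- GIH_TIERS
  for (t in c("primary", "secondary", "peripheral")) {
    r <- degree_ranges[[t]]
    ok <- switch(t,
                 primary = r[1] > 10,
                 secondary = r[1] >= 5 && r[2] <= 10,
                 peripheral = r[1] >= 1 && r[2] <= 4)
    if (!ok) {
      stop(sprintf("degree range for tier \"%s\" is inconsistent with the tier rule", t),
           call. = FALSE)
    }
  }

  conn_tiers <- rep(c("primary", "secondary", "peripheral"),
                    tier_sizes[c("primary", "secondary", "peripheral")])
  n_conn <- length(conn_tiers)
  degrees <- vapply(conn_tiers, function(t) {
    r <- degree_ranges[[t]]
    sample(seq(r[1], r[2]), 1)
  }, numeric(1))
  if (any(degrees >= n_conn)) {
    stop("a requested degree reaches the number of connected nodes; increase tier sizes or lower the degree ranges",
         call. = FALSE)
  }
  if (sum(degrees) %% 2 == 1) {
    # adjust one node within its tier range to fix parity
    fixed <- FALSE
    for (i in seq_len(n_conn)) {
      r <- degree_ranges[[conn_tiers[i]]]
      if (degrees[i] < r[2]) { degrees[i] <- degrees[i] + 1; fixed <- TRUE; break }
      if (degrees[i] > r[1]) { degrees[i] <- degrees[i] - 1; fixed <- TRUE; break }
    }
    if (!fixed) stop("cannot fix degree parity within tier ranges", call. = FALSE)
  }
  if (!igraph::is_graphical(degrees)) {
    stop("degree sequence is not graphical; choose smaller degree ranges or larger tier sizes",
         call. = FALSE)
  }

  g <- tryCatch(
    igraph::sample_degseq(degrees, method = "vl"),
    error = function(e) {
      el <- havel_hakimi_edges(degrees)
      igraph::graph_from_edgelist(el, directed = FALSE)
    }
  )
  symbols <- sprintf("GOI%03d", seq_len(n_conn + tier_sizes[["orphan"]]))
  igraph::V(g)$name <- symbols[seq_len(n_conn)]

  if (rewire_prob > 0) {
    g <- igraph::rewire(g, igraph::each_edge(prob = rewire_prob,
                                             loops = FALSE, multiple = FALSE))
    g <- igraph::simplify(g)
  }
  orphans <- if (tier_sizes[["orphan"]] > 0) {
    symbols[(n_conn + 1):length(symbols)]
  } else character(0)
  g <- igraph::add_vertices(g, length(orphans), name = orphans)

  list(
    network = structure(list(graph = g), class = "interaction_network"),
    truth = data.frame(
      symbol = symbols,
      tier = factor(c(conn_tiers, rep("orphan", length(orphans))),
                    levels = GIH_TIERS),
      degree = c(degrees, rep(0, length(orphans))),
      stringsAsFactors = FALSE
    )
  )
}
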