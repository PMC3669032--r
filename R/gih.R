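# Gene interaction hierarchy: induce the genes-of-interest subnetwork, count
# direct (1st-order) connections, and tier genes by that count.

#' Induce the genes-of-interest subnetwork
#'
#' Keeps only edges with both endpoints in the GOI set. GOI absent from the
#' network become isolated nodes (reported via a message), so every GOI is
#' present in the result.
#'
#' @param network An [interaction_network()].
#' @param goi Non-empty character vector of gene symbols.
#' @return An `interaction_network` whose node set is exactly `goi`.
#' @export
induce_goi_network <- function(network, goi) {
  stopifnot(inherits(network, "interaction_network"))
  goi <- unique(trimws(as.character(goi)))
  goi <- goi[nzchar(goi)]
  if (length(goi) == 0) {
    stop("`goi` must be a non-empty set of symbols", call. = FALSE)
  }
  present <- intersect(goi, network_nodes(network))
  absent <- setdiff(goi, present)
  if (length(absent) > 0) {
    message(sprintf("%d GOI absent from the network become isolated: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  g <- igraph::induced_subgraph(network$graph,
                                vids = match(present, network_nodes(network)))
  g <- igraph::add_vertices(g, length(absent), name = absent)
  structure(list(graph = g), class = "interaction_network")
}

#' Number of direct connections of a gene
#'
#' Distinct 1st-order neighbours, self excluded (duplicate edges were already
#' collapsed at network construction).
#'
#' @param network An [interaction_network()] (typically the induced GOI
#'   subnetwork).
#' @param symbol Gene symbol; must be a node.
#' @return Non-negative integer.
#' @export
connection_count <- function(network, symbol) {
  stopifnot(inherits(network, "interaction_network"))
  nodes <- network_nodes(network)
  if (!symbol %in% nodes) {
    stop(sprintf("symbol \"%s\" is not in the network", symbol), call. = FALSE)
  }
  as.integer(igraph::degree(network$graph, v = match(symbol, nodes)))
}

# Tier vocabulary, highest first.
GIH_TIERS <- c("primary", "secondary", "peripheral", "orphan")

#' Assign a hierarchy tier from a connection count
#'
#' More than `primary_gt` connections is "primary"; `secondary_min` up to
#' `primary_gt` is "secondary"; at least one but fewer than `secondary_min`
#' is "peripheral"; zero is "orphan". Defaults reproduce the >10 / 5--10 /
#' <5 / 0 rule.
#'
#' @param count Non-negative integer vector.
#' @param primary_gt Strict lower bound for the primary tier (default 10).
#' @param secondary_min Lower bound (inclusive) for the secondary tier
#'   (default 5).
#' @return Factor with levels `primary`, `secondary`, `peripheral`, `orphan`.
#' @export
assign_tier <- function(count, primary_gt = 10, secondary_min = 5) {
  if (any(count < 0)) {
    stop("connection counts must be non-negative", call. = FALSE)
  }
  tier <- ifelse(count > primary_gt, "primary",
                 ifelse(count >= secondary_min, "secondary",
                        ifelse(count >= 1, "peripheral", "orphan")))
  factor(tier, levels = GIH_TIERS)
}

#' Build the gene interaction hierarchy table
#'
#' Induces the GOI subnetwork, counts each gene's direct connections, tiers
#' the genes, and joins annotations and fold changes into a ranked table.
#' Entries are ordered by tier, then cellular compartment (extracellular
#' space, plasma membrane, cytoplasm, nucleus, unknown), then molecule type,
#' then symbol — a deterministic layout.
#'
#' @param network An [interaction_network()].
#' @param goi Character vector of gene symbols of interest.
#' @param annotations Optional data frame with `symbol`, `compartment`,
#'   `molecule_type` columns; GOI without a row get compartment and type
#'   `"unknown"` (with a warning).
#' @param fold_changes Optional data frame with `symbol` (or `gene_id`),
#'   `fc_ipsi`, `fc_contra`; `NA` means "no qualifying change" and prints as
#'   `~`.
#' @param primary_gt,secondary_min Tier boundaries, see [assign_tier()].
#' @return A `gih_table` (data frame: `symbol`, `connection_count`, `tier`,
#'   `fc_ipsi`, `fc_contra`, `compartment`, `molecule_type`) with attributes
#'   `tier_totals` and `n_connected`.
#' @export
build_gih <- function(network, goi, annotations = NULL, fold_changes = NULL,
                      primary_gt = 10, secondary_min = 5) {
  sub <- induce_goi_network(network, goi)
  nodes <- network_nodes(sub)
  counts <- as.integer(igraph::degree(sub$graph))
  tier <- assign_tier(counts, primary_gt, secondary_min)

  df <- data.frame(
    symbol = nodes,
    connection_count = counts,
    tier = tier,
    fc_ipsi = NA_real_,
    fc_contra = NA_real_,
    compartment = "unknown",
    molecule_type = "unknown",
    stringsAsFactors = FALSE
  )

  if (!is.null(fold_changes)) {
    key <- if ("symbol" %in% names(fold_changes)) "symbol" else "gene_id"
    idx <- match(df$symbol, fold_changes[[key]])
    df$fc_ipsi <- fold_changes$fc_ipsi[idx]
    df$fc_contra <- fold_changes$fc_contra[idx]
  }
  if (!is.null(annotations)) {
    idx <- match(df$symbol, annotations$symbol)
    hit <- !is.na(idx)
    df$compartment[hit] <- annotations$compartment[idx[hit]]
    df$molecule_type[hit] <- annotations$molecule_type[idx[hit]]
    if (any(!hit)) {
      warning(sprintf("%d GOI without annotation set to \"unknown\": %s",
                      sum(!hit), paste(df$symbol[!hit], collapse = ", ")),
              call. = FALSE)
    }
  }

  ord <- order(as.integer(df$tier), compartment_rank(df$compartment),
               tolower(df$molecule_type), df$symbol)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  totals <- table(df$tier)
  structure(df,
            class = c("gih_table", "data.frame"),
            tier_totals = setNames(as.integer(totals), names(totals)),
            n_connected = sum(df$connection_count > 0))
}

#' @export
print.gih_table <- function(x, ...) {
  tt <- attr(x, "tier_totals")
  cat(sprintf("<gih_table> %d gene(s): %s; %d connected, %d orphan\n",
              nrow(x),
              paste(sprintf("%s %d", names(tt), tt), collapse = ", "),
              attr(x, "n_connected"), tt[["orphan"]]))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}
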