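# Bundled example tables curated from a published rat unilateral controlled
# cortical impact microarray study (three groups, n = 3 per group, 24 h
# post-injury), shipped as plain TSV under inst/extdata/.

example_path <- function(file) {
  p <- system.file("extdata", file, package = "bihemi")
  if (p == "") stop("bundled example file not found: ", file, call. = FALSE)
  p
}

read_tilde_fc <- function(x) {
  suppressWarnings(as.numeric(ifelse(x == "~", NA, x)))
}

#' Example: common inflammatory genes that responded differently by hemisphere
#'
#' The 37 inflammatory-response genes changed at least 2-fold on both
#' hemispheres whose TBI-I/TBI-C fold ratio exceeded 1.75, with the reported
#' signed fold changes, ratios and annotations.
#'
#' @return Data frame: `symbol`, `entrez_name`, `fc_ipsi`, `fc_contra`,
#'   `ratio`, `compartment`, `molecule_type`.
#' @export
example_divergent_genes <- function() {
  df <- read.delim(example_path("tbi_divergent_common_genes.tsv"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$fc_ipsi <- as.numeric(df$fc_ipsi)
  df$fc_contra <- as.numeric(df$fc_contra)
  df$ratio <- as.numeric(df$ratio)
  df
}

#' Example: overlap of top biological functions with the IR set
#'
#' Fourteen high-ranking biological functions with their unique gene counts,
#' inflammatory-response overlaps and reported integer percentages.
#'
#' @return Data frame: `function_name`, `unique_genes`, `overlap_ir`,
#'   `percent`.
#' @export
example_function_overlaps <- function() {
  read.delim(example_path("tbi_function_overlap.tsv"),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Example: gene interaction hierarchy of the 114 genes of interest
#'
#' The curated genes-of-interest list with reported tier, signed fold changes
#' (`NA` = no qualifying change, printed as `~`), cellular compartment and
#' molecule type. Useful as a demonstration GOI list for [build_gih()]
#' against any user-supplied interaction network.
#'
#' @return Data frame: `symbol`, `tier`, `fc_ipsi`, `fc_contra`,
#'   `compartment`, `molecule_type`.
#' @export
example_goi_hierarchy <- function() {
  df <- read.delim(example_path("tbi_goi_hierarchy.tsv"),
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  df$fc_ipsi <- read_tilde_fc(df$fc_ipsi)
  df$fc_contra <- read_tilde_fc(df$fc_contra)
  df$tier <- factor(df$tier, levels = GIH_TIERS)
  df
}
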