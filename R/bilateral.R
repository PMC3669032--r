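# Bilateral comparison: the TBI-I/TBI-C fold-ratio statistic, the
# similar/different call for genes changed on both hemispheres, and the
# common/unique x up/down partition of all changed genes.

# Map a signed fold change to the linear expression ratio it encodes:
# x for x >= 1, 1/|x| for x <= -1.
linear_fold <- function(x) {
  ifelse(x > 0, x, 1 / abs(x))
}

#' TBI-I/TBI-C fold ratio for a bilaterally changed gene
#'
#' The ratio measures how differently a gene responded in the two
#' hemispheres. On the linear expression scale it is
#' `linear(fc_ipsi) / linear(fc_contra)` where `linear(x)` is `x` for
#' up-regulation and `1/|x|` for down-regulation. The piecewise sign cases
#' that follow from this single definition:
#' both up, `fc_ipsi / fc_contra`; both down, `fc_contra / fc_ipsi`
#' (i.e. `1 / (fc_ipsi / fc_contra)` on magnitudes); up ipsilaterally and
#' down contralaterally, `fc_ipsi * |fc_contra|`; down ipsilaterally and up
#' contralaterally, `(1 / |fc_ipsi|) / fc_contra`.
#'
#' In `"faithful"` mode (default) the last case always yields a ratio < 1
#' and therefore a "similar" call; `"symmetric"` mode returns
#' `max(r, 1/r)` so any strong divergence, in either direction, exceeds the
#' classification threshold.
#'
#' @param fc_ipsi,fc_contra Signed fold changes with magnitude >= 1
#'   (vectors recycled).
#' @param mode `"faithful"` or `"symmetric"`.
#' @return Numeric ratio(s).
#' @examples
#' fold_ratio(4.22, -3.77)  # 15.91: strongly divergent
#' fold_ratio(-4.00, -7.97) # 1.99
#' @export
fold_ratio <- function(fc_ipsi, fc_contra, mode = c("faithful", "symmetric")) {
  mode <- match.arg(mode)
  if (any(abs(fc_ipsi) < 1) || any(abs(fc_contra) < 1)) {
    stop("signed fold changes must have magnitude >= 1", call. = FALSE)
  }
  r <- linear_fold(fc_ipsi) / linear_fold(fc_contra)
  if (mode == "symmetric") {
    r <- pmax(r, 1 / r)
  }
  r
}

#' Classify a bilaterally changed gene as responding similarly or differently
#'
#' @param ratio Fold ratio(s) from [fold_ratio()].
#' @param threshold Strict cutoff: `"different"` iff `ratio > threshold`
#'   (default 1.75; a ratio of exactly 1.75 is "similar").
#' @return Character vector in `c("similar", "different")`.
#' @export
classify_common <- function(ratio, threshold = 1.75) {
  ifelse(ratio > threshold, "different", "similar")
}

# The full category vocabulary of the bilateral partition.
BILATERAL_CATEGORIES <- c(
  "common-similar-up", "common-similar-down", "common-different",
  "ipsi-unique-up", "ipsi-unique-down",
  "contra-unique-up", "contra-unique-down",
  "unchanged"
)

#' Partition changed genes by hemisphere pattern
#'
#' Genes changed on both sides ("common") receive a fold ratio and a
#' similar/different call; similar genes are sub-labelled up/down by the sign
#' of the ipsilateral fold change. Genes changed on exactly one side are
#' "unique" to that side, up or down by that side's sign. Everything else is
#' "unchanged".
#'
#' @param records Output of [fold_change_records()].
#' @param restrict_to Optional character vector of gene ids (e.g. the
#'   inflammatory-response set); applied before partitioning.
#' @param ratio_threshold Similar/different cutoff, see [classify_common()].
#' @param ratio_mode See [fold_ratio()].
#' @return Data frame with columns `gene_id`, `category` (one of the eight
#'   partition categories), `ratio` (`NA` unless common), `fc_ipsi`,
#'   `fc_contra`.
#' @export
classify_bilateral <- function(records, restrict_to = NULL,
                               ratio_threshold = 1.75,
                               ratio_mode = c("faithful", "symmetric")) {
  ratio_mode <- match.arg(ratio_mode)
  if (!is.null(restrict_to)) {
    records <- records[records$gene_id %in% restrict_to, , drop = FALSE]
  }
  n <- nrow(records)
  category <- rep("unchanged", n)
  ratio <- rep(NA_real_, n)

  common <- records$changed_ipsi & records$changed_contra
  if (any(common)) {
    ratio[common] <- fold_ratio(records$fc_ipsi[common],
                                records$fc_contra[common], mode = ratio_mode)
    call <- classify_common(ratio[common], ratio_threshold)
    sub <- ifelse(call == "different", "common-different",
                  ifelse(records$fc_ipsi[common] > 0,
                         "common-similar-up", "common-similar-down"))
    category[common] <- sub
  }
  ipsi_only <- records$changed_ipsi & !records$changed_contra
  category[ipsi_only] <- ifelse(records$fc_ipsi[ipsi_only] > 0,
                                "ipsi-unique-up", "ipsi-unique-down")
  contra_only <- records$changed_contra & !records$changed_ipsi
  category[contra_only] <- ifelse(records$fc_contra[contra_only] > 0,
                                  "contra-unique-up", "contra-unique-down")

  data.frame(
    gene_id = records$gene_id,
    category = factor(category, levels = BILATERAL_CATEGORIES),
    ratio = ratio,
    fc_ipsi = records$fc_ipsi,
    fc_contra = records$fc_contra,
    stringsAsFactors = FALSE
  )
}

#' Summarize a bilateral partition
#'
#' Counts per category plus the reported percentages: similar/different and
#' similar-up/similar-down are percentages of the *common* total; unique
#' up/down percentages use each side's unique total as denominator. Integer
#' percentages round half away from zero. Undefined percentages (zero
#' denominator) are `NA`.
#'
#' @param classifications Output of [classify_bilateral()].
#' @return An object of class `partition_summary`: list with `counts` (per
#'   category), `totals` (`common`, `ipsi_unique`, `contra_unique`,
#'   `changed`) and `percent`.
#' @export
summarize_partition <- function(classifications) {
  counts <- table(classifications$category)
  counts <- setNames(as.integer(counts), names(counts))
  common <- counts[["common-similar-up"]] + counts[["common-similar-down"]] +
    counts[["common-different"]]
  similar <- counts[["common-similar-up"]] + counts[["common-similar-down"]]
  ipsi_unique <- counts[["ipsi-unique-up"]] + counts[["ipsi-unique-down"]]
  contra_unique <- counts[["contra-unique-up"]] + counts[["contra-unique-down"]]
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  structure(
    list(
      counts = counts,
      totals = c(common = common, ipsi_unique = ipsi_unique,
                 contra_unique = contra_unique,
                 changed = common + ipsi_unique + contra_unique),
      percent = c(
        similar = pct(similar, common),
        different = pct(counts[["common-different"]], common),
        similar_up = pct(counts[["common-similar-up"]], common),
        similar_down = pct(counts[["common-similar-down"]], common),
        ipsi_unique_up = pct(counts[["ipsi-unique-up"]], ipsi_unique),
        ipsi_unique_down = pct(counts[["ipsi-unique-down"]], ipsi_unique),
        contra_unique_up = pct(counts[["contra-unique-up"]], contra_unique),
        contra_unique_down = pct(counts[["contra-unique-down"]], contra_unique)
      )
    ),
    class = "partition_summary"
  )
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("<partition_summary>\n")
  cat(sprintf("  changed genes: %d (common %d, ipsi-unique %d, contra-unique %d)\n",
              x$totals[["changed"]], x$totals[["common"]],
              x$totals[["ipsi_unique"]], x$totals[["contra_unique"]]))
  p <- x$percent
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%d%%", as.integer(v))
  cat(sprintf("  common: %s similar (%s up, %s down), %s different\n",
              fmt(p[["similar"]]), fmt(p[["similar_up"]]),
              fmt(p[["similar_down"]]), fmt(p[["different"]])))
  cat(sprintf("  ipsi-unique: %s up / %s down; contra-unique: %s up / %s down\n",
              fmt(p[["ipsi_unique_up"]]), fmt(p[["ipsi_unique_down"]]),
              fmt(p[["contra_unique_up"]]), fmt(p[["contra_unique_down"]])))
  invisible(x)
}
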