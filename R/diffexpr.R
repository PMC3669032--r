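#' Per-gene mean signal of a group
#'
#' @param dataset An [expression_dataset()].
#' @param group Group label (must have at least one sample).
#' @param summary `"mean"` (arithmetic, default) or `"geomean"` (geometric),
#'   the cross-replicate summarization of the positive signals.
#' @return Named numeric vector, one value per gene.
#' @export
group_mean <- function(dataset, group, summary = c("mean", "geomean")) {
  summary <- match.arg(summary)
  s <- group_samples(dataset, group)
  x <- dataset$signal[, s, drop = FALSE]
  if (summary == "mean") {
    rowMeans(x)
  } else {
    exp(rowMeans(log(x)))
  }
}

#' Signed fold change between two positive means
#'
#' Expression ratios are folded to magnitude >= 1 with the sign giving the
#' direction: `signed_fold_change(200, 100)` is `2`, and
#' `signed_fold_change(50, 200)` is `-4` (a 4-fold decrease). Equal means map
#' to `+1`.
#'
#' @param mean_case,mean_control Positive numeric vectors (recycled).
#' @return Signed fold change(s), always with `abs(.) >= 1`.
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop("group means must be strictly positive", call. = FALSE)
  }
  ifelse(mean_case >= mean_control,
         mean_case / mean_control,
         -(mean_control / mean_case))
}

#' Presence filter over the two injured-hemisphere groups
#'
#' A gene passes when it is called Present in *all* samples of at least one
#' of the two hemisphere groups (ipsilateral or contralateral). Marginal (`M`)
#' calls count as not-present.
#'
#' @param calls_ipsi,calls_contra Character vectors of detection calls
#'   (`P`/`M`/`A`) for one gene.
#' @return Logical flag.
#' @export
presence_pass <- function(calls_ipsi, calls_contra) {
  all(calls_ipsi == "P") || all(calls_contra == "P")
}

#' Fold-change records for the TBI-I and TBI-C contrasts
#'
#' Computes, per gene, the signed fold changes ipsilateral-vs-naive (TBI-I)
#' and contralateral-vs-naive (TBI-C), the all-Present flags per hemisphere,
#' and the changed flags: `|fold change| >=` the threshold (boundary
#' inclusive, "2-fold or more") *and* the presence rule of [presence_pass()].
#'
#' @param dataset An [expression_dataset()] with `ipsilateral`,
#'   `contralateral` and `naive` samples.
#' @param threshold Fold-change magnitude cutoff, `>= 1` (default 2).
#' @param summary Cross-replicate summarization, see [group_mean()].
#' @return Data frame with columns `gene_id`, `fc_ipsi`, `fc_contra`,
#'   `present_ipsi`, `present_contra`, `presence`, `changed_ipsi`,
#'   `changed_contra`.
#' @export
fold_change_records <- function(dataset, threshold = 2,
                                summary = c("mean", "geomean")) {
  summary <- match.arg(summary)
  if (threshold < 1) {
    stop("`threshold` must be >= 1 (fold-change magnitude)", call. = FALSE)
  }
  m_ipsi <- group_mean(dataset, GROUP_IPSI, summary)
  m_contra <- group_mean(dataset, GROUP_CONTRA, summary)
  m_naive <- group_mean(dataset, GROUP_NAIVE, summary)
  calls_i <- dataset$call[, group_samples(dataset, GROUP_IPSI), drop = FALSE]
  calls_c <- dataset$call[, group_samples(dataset, GROUP_CONTRA), drop = FALSE]
  present_ipsi <- rowSums(calls_i != "P") == 0
  present_contra <- rowSums(calls_c != "P") == 0
  presence <- present_ipsi | present_contra
  fc_ipsi <- signed_fold_change(m_ipsi, m_naive)
  fc_contra <- signed_fold_change(m_contra, m_naive)
  data.frame(
    gene_id = rownames(dataset$signal),
    fc_ipsi = unname(fc_ipsi),
    fc_contra = unname(fc_contra),
    present_ipsi = unname(present_ipsi),
    present_contra = unname(present_contra),
    presence = unname(presence),
    changed_ipsi = unname(presence & abs(fc_ipsi) >= threshold),
    changed_contra = unname(presence & abs(fc_contra) >= threshold),
    stringsAsFactors = FALSE
  )
}

#' Genes changed in one contrast
#'
#' @param records Output of [fold_change_records()].
#' @param side `"TBI-I"` (ipsilateral vs naive) or `"TBI-C"` (contralateral
#'   vs naive).
#' @param threshold Optional fold-change magnitude to re-apply (default: use
#'   the `changed_*` flags already in `records`).
#' @return Character vector of gene ids.
#' @export
changed_genes <- function(records, side = c("TBI-I", "TBI-C"),
                          threshold = NULL) {
  side <- match.arg(side)
  fc <- if (side == CONTRAST_IPSI) records$fc_ipsi else records$fc_contra
  if (is.null(threshold)) {
    flag <- if (side == CONTRAST_IPSI) records$changed_ipsi else records$changed_contra
  } else {
    if (threshold < 1) {
      stop("`threshold` must be >= 1 (fold-change magnitude)", call. = FALSE)
    }
    flag <- records$presence & abs(fc) >= threshold
  }
  records$gene_id[flag]
}
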