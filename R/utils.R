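# Internal helpers shared across modules.

# Round half away from zero (only used on non-negative quantities).
# base::round() rounds half to even, which disagrees with the reported
# percentages at ties such as 37.5 -> 38 vs 20.5 -> 21.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Serialize a signed fold change: two decimals, "~" when the gene did not
# qualify as changed (NA).
fmt_fc <- function(x) {
  ifelse(is.na(x), "~", sprintf("%.2f", x))
}

# Canonical sample-group labels used by the three-group design.
GROUP_IPSI <- "ipsilateral"
GROUP_CONTRA <- "contralateral"
GROUP_NAIVE <- "naive"

# Contrast labels.
CONTRAST_IPSI <- "TBI-I"
CONTRAST_CONTRA <- "TBI-C"

# Cellular-compartment display order used when laying out hierarchy tables.
COMPARTMENT_ORDER <- c(
  "extracellular space", "plasma membrane", "cytoplasm", "nucleus", "unknown"
)

compartment_rank <- function(x) {
  r <- match(tolower(trimws(x)), COMPARTMENT_ORDER)
  r[is.na(r)] <- length(COMPARTMENT_ORDER)
  r
}
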