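# Phenotype quantities and the methylation / TRAIL-sensitivity
# classification scheme.

#' Percent inhibition of proliferation by rhsTRAIL
#'
#' From thymidine-uptake radioactivity with and without 100 ng/mL rhsTRAIL:
#' 100 * (1 - treated / untreated). Negative values (growth stimulation) are
#' retained so rank statistics stay honest, clipped at -100.
#'
#' @param cpm_treated Counts per minute with rhsTRAIL (>= 0). Vectorized.
#' @param cpm_untreated Counts per minute without rhsTRAIL (> 0).
#' @return Percent inhibition in `[-100, 100]`.
#' @export
percent_inhibition <- function(cpm_treated, cpm_untreated) {
  if (any(cpm_untreated <= 0)) stop("cpm_untreated must be > 0", call. = FALSE)
  if (any(cpm_treated < 0)) stop("cpm_treated must be >= 0", call. = FALSE)
  pmax(100 * (1 - cpm_treated / cpm_untreated), -100)
}

#' Relative fluorescence intensity of cell-surface staining
#'
#' Ratio of specific-antibody mean fluorescence intensity to that of the
#' isotype control staining.
#'
#' @param mfi_specific,mfi_control Mean fluorescence intensities (> 0).
#' @return RFI ratio.
#' @export
rfi <- function(mfi_specific, mfi_control) {
  if (any(mfi_specific <= 0) || any(mfi_control <= 0))
    stop("MFI values must be > 0", call. = FALSE)
  mfi_specific / mfi_control
}

METH_CATEGORIES <- c("UNMETHYLATED", "DR4_PREF_UNMETH", "DR5_PREF_UNMETH",
                     "METHYLATED")

#' Classify a sample by DR4/DR5 promoter methylation
#'
#' Four-way partition of the (DR4%, DR5%) plane on the 1% threshold:
#' both < 1% unmethylated; DR4 < 1% and DR5 >= 1% DR4-preferentially
#' unmethylated; DR4 >= 1% and DR5 < 1% DR5-preferentially unmethylated;
#' both >= 1% methylated. Samples with both genes >= 10% additionally carry
#' the highly-methylated flag.
#'
#' @param dr4_pct,dr5_pct Mean percent methylation in `[0, 100]`. Vectorized.
#' @return Data frame with `category` (factor over the four levels) and
#'   `highly_methylated` (logical).
#' @export
classify_methylation <- function(dr4_pct, dr5_pct) {
  if (any(dr4_pct < 0 | dr4_pct > 100 | dr5_pct < 0 | dr5_pct > 100))
    stop("percent methylation must lie in [0, 100]", call. = FALSE)
  cat <- ifelse(dr4_pct < 1 & dr5_pct < 1, "UNMETHYLATED",
         ifelse(dr4_pct < 1, "DR4_PREF_UNMETH",
         ifelse(dr5_pct < 1, "DR5_PREF_UNMETH", "METHYLATED")))
  data.frame(category = factor(cat, levels = METH_CATEGORIES),
             highly_methylated = dr4_pct >= 10 & dr5_pct >= 10)
}

TRAIL_CATEGORIES <- c("SENSITIVE", "INTERMEDIATE", "RESISTANT")

#' Classify TRAIL sensitivity from percent inhibition
#'
#' Percent inhibition >= 80 is sensitive, < 25 resistant, otherwise
#' intermediate.
#'
#' @param percent_inhibition Percent inhibition in `[-100, 100]`. Vectorized.
#' @return Factor over SENSITIVE / INTERMEDIATE / RESISTANT.
#' @export
classify_trail <- function(percent_inhibition) {
  if (any(percent_inhibition < -100 | percent_inhibition > 100))
    stop("percent inhibition must lie in [-100, 100]", call. = FALSE)
  factor(ifelse(percent_inhibition >= 80, "SENSITIVE",
         ifelse(percent_inhibition < 25, "RESISTANT", "INTERMEDIATE")),
         levels = TRAIL_CATEGORIES)
}

#' Band a methylation percent
#'
#' Half-open bands: `[0, 1)` unmethylated, `[1, 10)` weak, `[10, 100]` high.
#'
#' @param pct Percent methylation in `[0, 100]`. Vectorized.
#' @return Factor over unmethylated / weak / high.
#' @export
methylation_band <- function(pct) {
  if (any(pct < 0 | pct > 100))
    stop("percent methylation must lie in [0, 100]", call. = FALSE)
  factor(ifelse(pct < 1, "unmethylated", ifelse(pct < 10, "weak", "high")),
         levels = c("unmethylated", "weak", "high"))
}

#' Classify a phenotype table
#'
#' Applies [classify_methylation()] and [classify_trail()] to a panel
#' phenotype table (columns `sample_id`, `dr4_pct`, `dr5_pct`,
#' `inhibition_pct`).
#'
#' @param panel Phenotype data frame.
#' @return The table with `category`, `highly_methylated`, `trail_category`,
#'   `dr4_band` and `dr5_band` columns appended.
#' @export
classify_panel <- function(panel) {
  need <- c("sample_id", "dr4_pct", "dr5_pct", "inhibition_pct")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  mc <- classify_methylation(panel$dr4_pct, panel$dr5_pct)
  panel$category <- mc$category
  panel$highly_methylated <- mc$highly_methylated
  panel$trail_category <- classify_trail(panel$inhibition_pct)
  panel$dr4_band <- methylation_band(panel$dr4_pct)
  panel$dr5_band <- methylation_band(panel$dr5_pct)
  panel
}
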