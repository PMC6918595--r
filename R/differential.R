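#' Call differentially expressed proteins for a contrast
#'
#' Classifies each protein as `increased` (combined FC >= `up` and
#' p < `alpha`), `decreased` (FC <= `down` and p < `alpha`) or `unchanged`.
#' The fold-change boundaries are inclusive; the significance boundary is
#' strict. Note the deliberate asymmetry of the default window: 0.70 is
#' stricter than the reciprocal of 1.3 (1/1.3 ~ 0.769), and the caller does
#' not symmetrize.
#'
#' Proteins without a combined FC (not quantified in every pool) or without
#' a p-value (fewer than 2 measurements) are ineligible: they are classified
#' `unchanged` with `eligible = FALSE` rather than silently dropped.
#'
#' @param quant Output of [quantify_contrast()].
#' @param up Increased threshold (FC >= up), default 1.3; must exceed both
#'   1 and `down`.
#' @param down Decreased threshold (FC <= down), default 0.70.
#' @param alpha Significance level (p < alpha, strict), default 0.05.
#' @return Data frame `protein_id  contrast  fc_geomean  p_value  class
#'   eligible` with `class` in `{increased, decreased, unchanged}`.
#' @export
call_deps <- function(quant, up = 1.3, down = 0.70, alpha = 0.05) {
  if (up <= down || up <= 1) {
    stop("invalid thresholds: need up > 1 and up > down (got up = ", up,
         ", down = ", down, ")")
  }
  fc <- quant$fc_geomean
  p <- quant$p_value
  eligible <- !is.na(fc) & !is.na(p) & quant$quantified_in_all_pools
  cls <- rep("unchanged", nrow(quant))
  cls[eligible & fc >= up & p < alpha] <- "increased"
  cls[eligible & fc <= down & p < alpha] <- "decreased"
  data.frame(protein_id = quant$protein_id,
             contrast = quant$contrast,
             fc_geomean = fc,
             p_value = p,
             class = cls,
             eligible = eligible,
             stringsAsFactors = FALSE)
}

#' Summarize DEP counts per contrast
#'
#' Produces the per-contrast table of increased/decreased/total counts, plus
#' the number of eligible proteins the calls were made over.
#'
#' @param calls One or more [call_deps()] outputs (a data frame or a list of
#'   them, concatenated).
#' @param contrast_order Optional character vector fixing the output row
#'   order; defaults to order of first appearance.
#' @return Data frame `contrast  n_increased  n_decreased  n_total_dep
#'   n_eligible`.
#' @export
summarize_contrasts <- function(calls, contrast_order = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  if (is.null(contrast_order)) contrast_order <- unique(calls$contrast)
  rows <- lapply(contrast_order, function(ct) {
    cc <- calls[calls$contrast == ct, , drop = FALSE]
    n_up <- sum(cc$class == "increased")
    n_dn <- sum(cc$class == "decreased")
    data.frame(contrast = ct, n_increased = n_up, n_decreased = n_dn,
               n_total_dep = n_up + n_dn, n_eligible = sum(cc$eligible),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
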