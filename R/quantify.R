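#' Within-spectrum reporter ratios for a contrast
#'
#' For every unique-peptide PSM with both contrast channels present and
#' strictly positive, computes `ratio = intensity[case] / intensity[control]`.
#' Both reporter ions come from the same fragmentation spectrum, so peptide
#' ionization efficiency cancels in the ratio. Records failing the
#' positivity precondition are skipped (count reported).
#'
#' @param table Filtered, uniqueness-annotated PSM data frame (see
#'   [filter_psms()], [assign_uniqueness()]).
#' @param contrast A [contrast_spec()].
#' @param channel_map Named character vector group -> channel tag; defaults
#'   to the map attached to `table`.
#' @return Data frame `pool_id  protein_id  peptide_sequence  ratio`.
#' @export
peptide_ratios <- function(table, contrast,
                           channel_map = attr(table, "channel_map")) {
  if (is.null(channel_map)) channel_map <- default_channel_map()
  check_channel_map(channel_map)
  case_col <- intensity_column(contrast$case_group, channel_map)
  ctrl_col <- intensity_column(contrast$control_group, channel_map)
  if (is.null(table$unique_peptide)) {
    stop("run assign_uniqueness() before peptide_ratios()")
  }
  eligible <- table$unique_peptide
  ok <- eligible & !is.na(table[[case_col]]) & !is.na(table[[ctrl_col]]) &
    table[[case_col]] > 0 & table[[ctrl_col]] > 0
  skipped <- sum(eligible & !ok)
  if (skipped > 0) {
    message("peptide_ratios(", contrast$name, "): skipped ", skipped,
            " unique-peptide record(s) with missing/non-positive channels")
  }
  data.frame(pool_id = table$pool_id[ok],
             protein_id = table$protein_id[ok],
             peptide_sequence = table$peptide_sequence[ok],
             ratio = table[[case_col]][ok] / table[[ctrl_col]][ok],
             stringsAsFactors = FALSE)
}

#' Protein quantity as the median unique-peptide ratio
#'
#' Per protein and replicate pool, the fold change is the median of that
#' protein's unique-peptide within-spectrum ratios (even counts use midpoint
#' interpolation, the `stats::median` convention).
#'
#' @param ratios Output of [peptide_ratios()].
#' @return Data frame `protein_id  pool_id  fc  n_peptides` (one row per
#'   protein x pool with >= 1 ratio).
#' @export
protein_quantity <- function(ratios) {
  if (nrow(ratios) == 0L) {
    return(data.frame(protein_id = character(0), pool_id = character(0),
                      fc = numeric(0), n_peptides = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(ratios$protein_id, ratios$pool_id, drop = TRUE,
                     sep = "\r")
  med <- tapply(ratios$ratio, key, stats::median)
  cnt <- tapply(ratios$ratio, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, character(1), 1L),
                    pool_id = vapply(parts, `[`, character(1), 2L),
                    fc = as.numeric(med),
                    n_peptides = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$pool_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-replicate fold changes by geometric mean
#'
#' `FC = (prod FC_r)^(1/R)`, computed on the log2 scale.
#'
#' @param fc_r Numeric vector of per-pool fold changes (positive).
#' @return The geometric mean; `NA` if any element is missing.
#' @examples
#' combine_fold_changes(c(2, 0.5)) # 1
#' combine_fold_changes(c(2, 8))   # 4
#' @export
combine_fold_changes <- function(fc_r) {
  if (length(fc_r) == 0L || anyNA(fc_r)) return(NA_real_)
  stopifnot(all(fc_r > 0))
  2^mean(log2(fc_r))
}

#' Protein-level p-value from within-spectrum log2 ratios
#'
#' Two-tailed one-sample t-test of the mean log2 ratio against 0, pooling a
#' protein's unique-peptide log2 ratios across replicate pools. The reporter
#' channels being compared come from the same spectrum, so the ratios are
#' paired observations of the protein's log fold change.
#'
#' Degenerate cases: fewer than 2 measurements give `NA`; zero variance
#' gives p = 1 when the mean is 0 and p = 0 otherwise (the observed shift is
#' then noiseless by construction).
#'
#' @param log2_ratios Numeric vector of log2 ratios.
#' @return Two-tailed p-value in `[0, 1]`, or `NA`.
#' @export
protein_pvalue <- function(log2_ratios) {
  x <- log2_ratios[!is.na(log2_ratios)]
  if (length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0) {
    return(if (mean(x) == 0) 1 else 0)
  }
  stats::t.test(x, mu = 0, alternative = "two.sided")$p.value
}

#' Quantify one contrast across all replicate pools
#'
#' Full protein-level quantitation for a contrast: within-spectrum ratios
#' from unique peptides, per-pool median rollup, geometric-mean combination
#' (defined only for proteins quantified in every pool, mirroring the
#' restriction to the commonly quantified protein set), and a pooled
#' two-tailed t-test on log2 ratios.
#'
#' @param table Filtered, uniqueness-annotated combined PSM data frame.
#' @param contrast A [contrast_spec()].
#' @param channel_map Group -> channel tag map (default: attached to table).
#' @param pools Pool ids that must all quantify a protein for its combined
#'   FC to be defined; default all pools present in `table`.
#' @return Data frame with one row per quantified protein: `protein_id`,
#'   `contrast`, one `fc_<pool>` column per pool, `fc_geomean`, `n_peptides`
#'   (total ratio measurements), `p_value`, `quantified_in_all_pools`.
#' @export
quantify_contrast <- function(table, contrast,
                              channel_map = attr(table, "channel_map"),
                              pools = NULL) {
  ratios <- peptide_ratios(table, contrast, channel_map)
  if (is.null(pools)) pools <- sort(unique(table$pool_id))
  per_pool <- protein_quantity(ratios)
  proteins <- sort(unique(per_pool$protein_id))
  fc_mat <- matrix(NA_real_, nrow = length(proteins), ncol = length(pools),
                   dimnames = list(proteins, pools))
  fc_mat[cbind(per_pool$protein_id, per_pool$pool_id)] <- per_pool$fc
  n_pep <- tapply(ratios$ratio, factor(ratios$protein_id, levels = proteins),
                  length)
  in_all <- rowSums(!is.na(fc_mat)) == length(pools)
  geo <- rep(NA_real_, length(proteins))
  geo[in_all] <- 2^rowMeans(log2(fc_mat[in_all, , drop = FALSE]))
  pvals <- vapply(split(log2(ratios$ratio),
                        factor(ratios$protein_id, levels = proteins)),
                  protein_pvalue, numeric(1))
  out <- data.frame(protein_id = proteins,
                    contrast = contrast$name,
                    stringsAsFactors = FALSE)
  for (p in pools) out[[paste0("fc_", p)]] <- fc_mat[, p]
  out$fc_geomean <- geo
  out$n_peptides <- as.integer(n_pep)
  out$p_value <- unname(pvals)
  out$quantified_in_all_pools <- unname(in_all)
  rownames(out) <- NULL
  out
}
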