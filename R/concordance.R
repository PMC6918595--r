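#' Actin-normalized relative expression from densitometry
#'
#' Western-blot band quantification: each lane's band intensity is divided
#' by the same lane's housekeeping actin intensity, and all of a protein's
#' lane values are then divided by the mean of its reference group so the
#' reference mean equals 1. The reference group is the first group appearing
#' in the table (recorded in the output). Lanes with zero or missing actin
#' are excluded with a warning.
#'
#' @param table Data frame `protein  group  lane  band_intensity
#'   actin_intensity` (see [generate_densitometry()]).
#' @return List with `values` (per-lane normalized values), `summary`
#'   (per protein x group mean and SEM) and `reference_group`.
#' @export
wb_relative_expression <- function(table) {
  req <- c("protein", "group", "lane", "band_intensity", "actin_intensity")
  absent <- setdiff(req, names(table))
  if (length(absent) > 0) {
    stop("densitometry table missing column(s): ",
         paste(absent, collapse = ", "))
  }
  bad <- is.na(table$actin_intensity) | table$actin_intensity <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " lane(s) with missing/zero actin")
    table <- table[!bad, , drop = FALSE]
  }
  ref_group <- table$group[1]
  table$value <- table$band_intensity / table$actin_intensity
  out <- lapply(split(table, table$protein), function(tt) {
    ref_mean <- mean(tt$value[tt$group == ref_group])
    tt$value <- tt$value / ref_mean
    tt
  })
  values <- do.call(rbind, out)[, c("protein", "group", "lane", "value")]
  rownames(values) <- NULL
  key <- interaction(values$protein, values$group, drop = TRUE, sep = "\r")
  mu <- tapply(values$value, key, mean)
  sem <- tapply(values$value, key,
                function(v) stats::sd(v) / sqrt(length(v)))
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  summary <- data.frame(protein = vapply(parts, `[`, character(1), 1L),
                        group = vapply(parts, `[`, character(1), 2L),
                        mean = as.numeric(mu), sem = as.numeric(sem),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$protein, summary$group), , drop = FALSE]
  rownames(summary) <- NULL
  list(values = values, summary = summary, reference_group = ref_group)
}

#' One-way ANOVA on normalized densitometry values
#'
#' Per protein, tests for a group effect on the actin-normalized values with
#' a one-way ANOVA F-test and attaches significance stars (`**` for
#' p < 0.01, `*` for p < 0.05). If every group has zero within-group
#' variance the F statistic is degenerate; the convention is p = 1 when all
#' values are identical and p = 0 otherwise.
#'
#' @param values The `values` element of [wb_relative_expression()].
#' @return Data frame `protein  p_value  stars`.
#' @export
wb_anova <- function(values) {
  rows <- lapply(split(values, values$protein), function(tt) {
    counts <- table(tt$group)
    if (length(counts) < 2L || any(counts < 2L)) {
      stop("ANOVA needs >= 2 groups with >= 2 lanes each (protein ",
           tt$protein[1], ")")
    }
    within_var <- tapply(tt$value, tt$group, stats::var)
    if (all(within_var == 0)) {
      p <- if (stats::var(tt$value) == 0) 1 else 0
    } else {
      fit <- stats::aov(value ~ group, data = tt)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    data.frame(protein = tt$protein[1], p_value = p,
               stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between orthogonal fold-change measurements
#'
#' Pearson correlation between western-blot and reporter-ion fold changes,
#' paired by (protein, contrast). Pairs with a missing value on either side
#' are dropped. The two-tailed p-value comes from the t-transform of r
#' (`stats::cor.test`). An optional log2 transform of both axes is offered
#' for sensitivity analysis; the default correlates raw fold changes.
#'
#' @param wb_fc Data frame `protein  contrast  fc` of blot-derived fold
#'   changes.
#' @param itraq_fc Data frame `protein  contrast  fc` of reporter-derived
#'   fold changes.
#' @param log2 If `TRUE`, correlate log2 fold changes.
#' @return List `r`, `p_value`, `n` (pairs used).
#' @export
fc_correlation <- function(wb_fc, itraq_fc, log2 = FALSE) {
  merged <- merge(wb_fc, itraq_fc, by = c("protein", "contrast"),
                  suffixes = c("_wb", "_itraq"))
  merged <- merged[!is.na(merged$fc_wb) & !is.na(merged$fc_itraq), ,
                   drop = FALSE]
  if (nrow(merged) < 3L) {
    stop("fc_correlation needs >= 3 matched (protein, contrast) pairs; got ",
         nrow(merged))
  }
  x <- merged$fc_wb
  y <- merged$fc_itraq
  if (log2) {
    x <- base::log2(x)
    y <- base::log2(y)
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged))
}

#' Fetal-loss percentage between gestation stages
#'
#' `loss% = 100 * (mean(early) - mean(late)) / mean(early)` computed from
#' per-sow viable-fetus counts. Group means are reported with population
#' standard deviations (divisor n), the convention that reproduces summaries
#' like 16.3 +/- 0.47 for counts {16, 16, 17}.
#'
#' @param counts Data frame `group  sow_id  viable_fetuses` (see
#'   [fixture_fetal_counts()]).
#' @param early_group,late_group Group labels present in `counts`.
#' @return List `loss_pct`, `early` and `late` (each `list(group, n, mean,
#'   sd)`).
#' @examples
#' fetal_loss_rate(fixture_fetal_counts(), "DUD49", "DUD72")$loss_pct # 21.2
#' @export
fetal_loss_rate <- function(counts, early_group, late_group) {
  group_stats <- function(g) {
    x <- counts$viable_fetuses[counts$group == g]
    if (length(x) == 0L) stop("no counts for group '", g, "'")
    list(group = g, n = length(x), mean = mean(x),
         sd = sqrt(mean((x - mean(x))^2)))
  }
  early <- group_stats(early_group)
  late <- group_stats(late_group)
  if (early$mean <= 0) stop("mean of early group must be positive")
  list(loss_pct = 100 * (early$mean - late$mean) / early$mean,
       early = early, late = late)
}
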