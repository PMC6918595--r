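make_dens <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

dens_row <- function(protein, group, lane, band, actin = 100) {
  data.frame(protein = protein, group = group, lane = lane,
             band_intensity = band, actin_intensity = actin,
             stringsAsFactors = FALSE)
}

test_that("actin normalization anchors the reference group at 1", {
  # all bands equal to actin -> every normalized value is 1
  tab <- make_dens(dens_row("PX", "A", 1:3, 100),
                   dens_row("PX", "B", 1:3, 100))
  rel <- wb_relative_expression(tab)
  expect_equal(rel$values$value, rep(1, 6))

  # bands 2x actin in group A, 1x in B -> group ratio 2
  tab2 <- make_dens(dens_row("PX", "A", 1:3, 200),
                    dens_row("PX", "B", 1:3, 100))
  rel2 <- wb_relative_expression(tab2)
  s <- rel2$summary
  expect_equal(s$mean[s$group == "A"] / s$mean[s$group == "B"], 2)
  expect_identical(rel2$reference_group, "A")
  expect_equal(s$mean[s$group == "A"], 1)  # reference mean anchored

  # rescaling band and actin of one lane together changes nothing
  tab3 <- tab2
  tab3$band_intensity[1] <- tab3$band_intensity[1] * 7
  tab3$actin_intensity[1] <- tab3$actin_intensity[1] * 7
  expect_equal(wb_relative_expression(tab3)$values$value,
               rel2$values$value)

  # zero actin invalidates the lane
  tab4 <- tab2
  tab4$actin_intensity[4] <- 0
  expect_warning(rel4 <- wb_relative_expression(tab4), "zero actin")
  expect_equal(nrow(rel4$values), 5)

  expect_error(wb_relative_expression(tab2[, 1:3]), "missing column")
})

test_that("densitometry ANOVA follows the F-test with star conventions", {
  set.seed(5)
  # identical group means, nonzero within-group noise -> no star
  tab <- make_dens(dens_row("PX", "A", 1:3, 100 + c(-2, 0, 2)),
                   dens_row("PX", "B", 1:3, 100 + c(-1, 0, 1)))
  res <- wb_anova(wb_relative_expression(tab)$values)
  expect_gt(res$p_value, 0.05)
  expect_identical(res$stars, "")

  # two groups: F-test p equals the equal-variance two-sample t-test p
  tab2 <- make_dens(dens_row("PY", "A", 1:3, c(95, 100, 105)),
                    dens_row("PY", "B", 1:3, c(130, 140, 150)))
  vals <- wb_relative_expression(tab2)$values
  res2 <- wb_anova(vals)
  tt <- stats::t.test(value ~ group, data = vals, var.equal = TRUE)
  expect_equal(res2$p_value, tt$p.value)
  expect_identical(res2$stars,
                   if (res2$p_value < 0.01) "**" else
                     if (res2$p_value < 0.05) "*" else "")

  # degenerate: zero within-group variance everywhere
  tab3 <- make_dens(dens_row("PZ", "A", 1:3, 100),
                    dens_row("PZ", "B", 1:3, 200))
  expect_equal(wb_anova(wb_relative_expression(tab3)$values)$p_value, 0)
  tab4 <- make_dens(dens_row("PW", "A", 1:3, 100),
                    dens_row("PW", "B", 1:3, 100))
  expect_equal(wb_anova(wb_relative_expression(tab4)$values)$p_value, 1)
})

test_that("star thresholds map p-values as documented", {
  # via the degenerate path we cannot reach 0.01 < p < 0.05, so construct
  # group data whose ANOVA p is known to land in each band
  set.seed(6)
  find_case <- function(lo, hi) {
    for (i in 1:200) {
      vals <- data.frame(protein = "PX",
                         group = rep(c("A", "B"), each = 3),
                         lane = rep(1:3, 2),
                         value = c(stats::rnorm(3, 1, 0.1),
                                   stats::rnorm(3, 1.4, 0.1)))
      p <- wb_anova(vals)$p_value
      if (p > lo && p < hi) return(vals)
    }
    stop("no case found")
  }
  star_case <- wb_anova(find_case(0.011, 0.049))
  expect_identical(star_case$stars, "*")
  strong_case <- wb_anova(find_case(0, 0.009))
  expect_identical(strong_case$stars, "**")
})

test_that("fold-change correlation behaves like Pearson's r", {
  fc <- function(p, ct, v) data.frame(protein = p, contrast = ct, fc = v,
                                      stringsAsFactors = FALSE)
  wb <- fc(sprintf("P%d", 1:5), "C1", c(0.5, 0.8, 1.2, 1.6, 2.1))
  expect_equal(fc_correlation(wb, wb)$r, 1)
  anti <- wb; anti$fc <- 3 - wb$fc
  expect_equal(fc_correlation(wb, anti)$r, -1)
  expect_error(fc_correlation(wb[1:2, ], wb[1:2, ]), ">= 3")

  # affine rescaling of either axis leaves r unchanged
  scaled <- wb; scaled$fc <- 0.3 * wb$fc + 2
  set.seed(7)
  noisy <- wb; noisy$fc <- wb$fc + stats::rnorm(5, 0, 0.2)
  expect_equal(fc_correlation(wb, noisy)$r,
               fc_correlation(scaled, noisy)$r)

  # pairing is by (protein, contrast); unmatched rows are dropped
  extra <- rbind(wb, fc("P9", "C2", 5))
  expect_equal(fc_correlation(extra, wb)$n, 5)

  # Monte Carlo: generative correlation 0.9 recovered at large n
  set.seed(8)
  x <- stats::rnorm(500)
  y <- 0.9 * x + sqrt(1 - 0.81) * stats::rnorm(500)
  big_wb <- fc(sprintf("P%03d", 1:500), "C1", x + 5)
  big_it <- fc(sprintf("P%03d", 1:500), "C1", y + 5)
  est <- fc_correlation(big_wb, big_it)
  expect_equal(est$r, 0.9, tolerance = 0.05)
  expect_lt(est$p_value, 1e-10)
  expect_equal(est$n, 500)
})

test_that("fetal-loss arithmetic matches the recorded group means", {
  fx <- fixture_fetal_counts()
  du <- fetal_loss_rate(fx, "DUD49", "DUD72")
  expect_equal(round(du$loss_pct, 1), 21.2)
  expect_equal(du$early$mean, 11)
  expect_equal(round(du$early$sd, 2), 0.82)
  ms <- fetal_loss_rate(fx, "MSD49", "MSD72")
  # (16.33 - 14.33) / 16.33 = 6/49: ~12.2%, not the sometimes-quoted 13%
  expect_equal(ms$loss_pct, 100 * 6 / 49)
  same <- fetal_loss_rate(fx, "DUD49", "DUD49")
  expect_equal(same$loss_pct, 0)
  # scale invariance in counts
  fx2 <- fx; fx2$viable_fetuses <- fx2$viable_fetuses * 10
  expect_equal(fetal_loss_rate(fx2, "DUD49", "DUD72")$loss_pct,
               du$loss_pct)
  expect_error(fetal_loss_rate(fx, "DUD49", "NOPE"), "NOPE")
})
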