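test_that("degenerate or inconsistent configurations are rejected", {
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(n_replicate_pools = 0), "n_replicate_pools")
  expect_error(simulation_config(frac_spiked = 1.2), "frac_spiked")
  expect_error(simulation_config(channel_groups = c(A = "127")),
               "at least two")
  expect_error(simulation_config(spike_fc_up = c(1.5, 1.2)), "spike_fc_up")
  expect_error(simulation_config(spike_fc_down = c(0.5, 0.75)),
               "spike_fc_down")
  expect_error(simulation_config(peptides_per_protein = c(5, 3)),
               "peptides_per_protein")
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulation_config(n_proteins = 30, seed = 7)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$psm_tables, e2$psm_tables)
  expect_identical(e1$truth, e2$truth)
  d1 <- tempfile("sim1_"); d2 <- tempfile("sim2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  write_experiment(e1, d1)
  write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("noise-free null experiment has all channel ratios exactly 1", {
  cfg <- simulation_config(n_proteins = 25, cv_reporter = 0, frac_spiked = 0,
                           frac_low_quality = 0, seed = 2)
  e <- generate_experiment(cfg)
  for (tab in e$psm_tables) {
    int <- as.matrix(tab[, grep("^intensity_", names(tab))])
    expect_true(all(int == int[, 1]))
  }
})

test_that("noise-free spikes propagate exactly through the full rollup", {
  cfg <- simulation_config(n_proteins = 40, cv_reporter = 0,
                           frac_spiked = 0.25, frac_low_quality = 0,
                           spike_fc_up = 2.0, spike_fc_down = 0.5, seed = 5)
  e <- generate_experiment(cfg)
  psm <- assign_uniqueness(combine_psm_tables(e$psm_tables))
  for (ct in default_contrasts()) {
    q <- suppressMessages(quantify_contrast(psm, ct))
    truth_fc <- e$truth$proteins[[paste0("fc_", ct$name)]]
    names(truth_fc) <- e$truth$proteins$protein_id
    common <- q$protein_id[q$quantified_in_all_pools]
    expect_equal(q$fc_geomean[match(common, q$protein_id)],
                 unname(truth_fc[common]), tolerance = 1e-12)
  }
})

test_that("shared peptides occur at the configured rate and sum parents", {
  cfg <- simulation_config(n_proteins = 150, frac_shared_peptides = 0.2,
                           cv_reporter = 0, frac_low_quality = 0, seed = 9)
  e <- generate_experiment(cfg)
  frac <- mean(e$truth$peptides$shared)
  expect_equal(frac, 0.2, tolerance = 0.02)
  # a shared peptide's intensity exceeds either parent's own contribution
  tab <- e$psm_tables[[1]]
  shared_rows <- grepl(";", tab$protein_ids, fixed = TRUE)
  expect_true(any(shared_rows))
  expect_identical(sort(unique(tab$protein_ids[shared_rows])),
                   sort(unique(e$truth$peptides$protein_ids[
                     e$truth$peptides$shared])))
})

test_that("densitometry tracks true fold changes; exact when noise-free", {
  truth <- list(proteins = data.frame(protein_id = c("PX", "PY"),
                                      mult_A = c(1, 1), mult_B = c(0.5, 2),
                                      stringsAsFactors = FALSE))
  dens <- generate_densitometry(truth, c("PX", "PY"), noise_cv = 0, seed = 1)
  rel <- wb_relative_expression(dens)
  s <- rel$summary
  expect_equal(s$mean[s$protein == "PX" & s$group == "B"], 0.5)
  expect_equal(s$mean[s$protein == "PY" & s$group == "B"], 2)
  expect_identical(rel$reference_group, "A")
  expect_identical(dens,
                   generate_densitometry(truth, c("PX", "PY"),
                                         noise_cv = 0, seed = 1))
  expect_error(generate_densitometry(truth, "NOPE", 0, 1), "NOPE")
})

test_that("noisy densitometry FC estimate is unbiased (Monte Carlo)", {
  truth <- list(proteins = data.frame(protein_id = "PX", mult_A = 1,
                                      mult_B = 2, stringsAsFactors = FALSE))
  est <- vapply(1:1000, function(s) {
    dens <- generate_densitometry(truth, "PX", noise_cv = 0.05, seed = s)
    rel <- wb_relative_expression(dens)
    rel$summary$mean[rel$summary$group == "B"]
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 3 * se)
})

test_that("fetal-count fixture reproduces the recorded group summaries", {
  fx <- fixture_fetal_counts()
  gm <- tapply(fx$viable_fetuses, fx$group, mean)
  gs <- tapply(fx$viable_fetuses, fx$group,
               function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(round(unname(gm["DUD72"]), 2), 8.67)
  expect_equal(round(unname(gm["MSD49"]), 1), 16.3)
  expect_equal(round(unname(gm["MSD72"]), 1), 14.3)
  expect_equal(unname(gm["DUD49"]), 11)
  expect_equal(round(as.numeric(gs[c("MSD49", "MSD72", "DUD49", "DUD72")]), 2),
               c(0.47, 0.47, 0.82, 0.47))
  # population-SD convention: direct arithmetic on {16,16,17}
  expect_equal(round(sqrt(mean((c(16, 16, 17) - mean(c(16, 16, 17)))^2)), 2),
               0.47)
})

test_that("null data with moderate noise keeps the DEP false-positive rate low", {
  fpr <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_proteins = 40, frac_spiked = 0,
                             cv_reporter = 0.1, frac_low_quality = 0,
                             seed = s)
    e <- generate_experiment(cfg)
    psm <- assign_uniqueness(combine_psm_tables(e$psm_tables))
    calls <- do.call(rbind, lapply(default_contrasts(), function(ct) {
      call_deps(suppressMessages(quantify_contrast(psm, ct)))
    }))
    mean(calls$class != "unchanged")
  }, numeric(1))
  expect_lte(mean(fpr), 0.05)
})
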