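#' Configuration for a simulated multiplexed proteomics experiment
#'
#' Defines the study conditions for the spike-in simulator: a four-group,
#' two-pool isobaric design in which a fraction of proteins carries a true
#' abundance shift (a "spike") in one randomly chosen group, so that every
#' contrast touching that group sees a true fold change outside the
#' differential-expression window (0.70, 1.3).
#'
#' Defaults are the benchmark study conditions used throughout the package's
#' recovery tests: 200 proteins, 20% spiked at fold changes drawn from
#' {1.5, 2.0} (up) and {0.5, 0.67} (down), 4-6 peptides per protein with 10%
#' shared peptides, two replicate pools, and 5% multiplicative reporter noise.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Integer range `c(min, max)`; each protein gets
#'   a uniformly drawn number of peptides in this range.
#' @param frac_shared_peptides Fraction of peptides mapped to a second parent
#'   protein. Shared peptides receive the summed intensity of their parents
#'   and are therefore excluded from rollup by the uniqueness rule.
#' @param n_replicate_pools Number of replicate pools (independent LC-MS/MS
#'   runs of the same labeled design).
#' @param channel_groups Named character vector group -> channel tag; default
#'   [default_channel_map()].
#' @param frac_spiked Fraction of proteins with a true abundance shift.
#' @param spike_fc_up,spike_fc_down Candidate true fold changes for up- and
#'   down-spikes; all up values must be >= 1.3 and all down values <= 0.70 so
#'   spikes sit outside the calling window.
#' @param cv_reporter Coefficient of variation of multiplicative log-normal
#'   reporter noise (0 = noise-free).
#' @param abundance_log_mean,abundance_log_sd Log-normal parameters (natural
#'   log) of protein baseline abundance.
#' @param ionization_log_sd Log-normal sd of per-peptide ionization factors;
#'   constant across channels and pools so that within-spectrum ratios cancel
#'   them.
#' @param frac_low_quality Fraction of extra junk PSM rows (low ion score or
#'   high q-value) appended to exercise the identification filters.
#' @param n_terms Number of annotation terms.
#' @param frac_terms_enriched Fraction of terms planted preferentially on
#'   spiked proteins (these are emitted in the BP namespace).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   outputs.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 200L,
                              peptides_per_protein = c(4L, 6L),
                              frac_shared_peptides = 0.10,
                              n_replicate_pools = 2L,
                              channel_groups = default_channel_map(),
                              frac_spiked = 0.20,
                              spike_fc_up = c(1.5, 2.0),
                              spike_fc_down = c(0.5, 0.67),
                              cv_reporter = 0.05,
                              abundance_log_mean = log(1e6),
                              abundance_log_sd = 1,
                              ionization_log_sd = 0.5,
                              frac_low_quality = 0.05,
                              n_terms = 40L,
                              frac_terms_enriched = 0.25,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              frac_shared_peptides = frac_shared_peptides,
              n_replicate_pools = as.integer(n_replicate_pools),
              channel_groups = channel_groups,
              frac_spiked = frac_spiked,
              spike_fc_up = spike_fc_up,
              spike_fc_down = spike_fc_down,
              cv_reporter = cv_reporter,
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd,
              ionization_log_sd = ionization_log_sd,
              frac_low_quality = frac_low_quality,
              n_terms = as.integer(n_terms),
              frac_terms_enriched = frac_terms_enriched,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$n_replicate_pools < 1L) stop("n_replicate_pools must be positive")
  if (length(cfg$channel_groups) < 2L) {
    stop("channel_groups must define at least two labeled groups")
  }
  check_channel_map(cfg$channel_groups)
  if (length(cfg$peptides_per_protein) != 2L ||
      cfg$peptides_per_protein[1] < 1L ||
      cfg$peptides_per_protein[2] < cfg$peptides_per_protein[1]) {
    stop("peptides_per_protein must be an increasing positive range c(min, max)")
  }
  for (f in c("frac_shared_peptides", "frac_spiked", "frac_low_quality",
              "frac_terms_enriched")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$cv_reporter < 0) stop("cv_reporter must be non-negative")
  if (cfg$n_terms < 1L) stop("n_terms must be positive")
  if (any(cfg$spike_fc_up < 1.3)) {
    stop("all spike_fc_up values must be >= 1.3")
  }
  if (any(cfg$spike_fc_down > 0.70) || any(cfg$spike_fc_down <= 0)) {
    stop("all spike_fc_down values must be positive and <= 0.70")
  }
  invisible(cfg)
}

# multiplicative log-normal noise with unit mean on the log scale;
# cv = 0 degenerates to exactly 1
reporter_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

random_peptide_sequences <- function(n) {
  # tryptic-looking unique sequences: 8-15 residues ending in K/R
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    lens <- sample(8:15, need, replace = TRUE)
    new <- vapply(lens, function(l) {
      paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs[seq_len(n)]
}

#' Generate a simulated isobaric experiment with ground truth
#'
#' Builds one PSM table per replicate pool, a protein -> term annotation map
#' with planted enriched terms, and the ground truth needed for recovery
#' testing. The expected reporter intensity of peptide j of protein i in
#' channel g is `baseline_i * multiplier_{i,g} * ionization_j * noise`, with
#' log-normal multiplicative noise. Shared peptides sum the contributions of
#' all their parent proteins (which is why downstream rollup restricts to
#' unique peptides).
#'
#' @param config A [simulation_config()].
#' @return List with elements:
#'   \describe{
#'     \item{psm_tables}{named list of PSM data frames, one per pool, in the
#'       TSV dialect consumed by [read_psm_table()].}
#'     \item{annotation}{list with `map` (protein_id, term_id) and `terms`
#'       (term_id, namespace, name).}
#'     \item{truth}{list with `proteins` (baseline, spiked flag, per-group
#'       multipliers, true FC per standard contrast), `terms` (enriched flag)
#'       and `peptides` (sequence, parents, shared flag).}
#'     \item{config}{the config used.}
#'   }
#' @export
generate_experiment <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_proteins
  groups <- names(config$channel_groups)

  protein_id <- sprintf("P%04d", seq_len(n))
  baseline <- stats::rlnorm(n, config$abundance_log_mean,
                            config$abundance_log_sd)

  # spikes: one affected group per spiked protein, FC drawn from the
  # candidate sets (up and down alternating through a random split)
  n_spiked <- round(config$frac_spiked * n)
  spiked_idx <- sort(sample.int(n, n_spiked))
  mult <- matrix(1, nrow = n, ncol = length(groups),
                 dimnames = list(protein_id, groups))
  spike_group <- rep(NA_character_, n)
  spike_fc <- rep(1, n)
  if (n_spiked > 0) {
    fc_pool <- c(config$spike_fc_up, config$spike_fc_down)
    for (i in spiked_idx) {
      g <- sample(groups, 1L)
      f <- sample(fc_pool, 1L)
      mult[i, g] <- f
      spike_group[i] <- g
      spike_fc[i] <- f
    }
  }

  # peptides
  npep <- sample(seq(config$peptides_per_protein[1],
                     config$peptides_per_protein[2]),
                 n, replace = TRUE)
  parent1 <- rep(seq_len(n), npep)
  total_pep <- length(parent1)
  sequences <- random_peptide_sequences(total_pep)
  ionization <- stats::rlnorm(total_pep, 0, config$ionization_log_sd)
  parent2 <- rep(NA_integer_, total_pep)
  n_shared <- round(config$frac_shared_peptides * total_pep)
  if (n_shared > 0 && n > 1) {
    shared_idx <- sample.int(total_pep, n_shared)
    parent2[shared_idx] <- vapply(shared_idx, function(j) {
      sample(setdiff(seq_len(n), parent1[j]), 1L)
    }, integer(1))
  }
  shared <- !is.na(parent2)

  int_cols <- paste0("intensity_", unname(config$channel_groups))
  make_pool <- function(pool) {
    tab <- data.frame(
      spectrum_id = sprintf("pool%d_scan%05d", pool, seq_len(total_pep)),
      peptide_sequence = sequences,
      protein_ids = ifelse(shared,
                           paste(protein_id[parent1], protein_id[parent2],
                                 sep = ";"),
                           protein_id[parent1]),
      ion_score = round(stats::runif(total_pep, 30, 90), 2),
      qvalue = signif(stats::runif(total_pep, 0, 0.005), 4),
      stringsAsFactors = FALSE
    )
    for (k in seq_along(groups)) {
      expected <- baseline[parent1] * mult[cbind(parent1, k)] *
        ionization
      if (any(shared)) {
        expected[shared] <- expected[shared] +
          baseline[parent2[shared]] * mult[cbind(parent2[shared], k)] *
          ionization[shared]
      }
      tab[[int_cols[k]]] <- expected * reporter_noise(total_pep,
                                                      config$cv_reporter)
    }
    # junk rows exercising the identification filters
    n_lq <- round(config$frac_low_quality * total_pep)
    if (n_lq > 0) {
      pick <- sample.int(total_pep, n_lq, replace = TRUE)
      junk <- tab[pick, , drop = FALSE]
      junk$spectrum_id <- sprintf("pool%d_junk%05d", pool, seq_len(n_lq))
      bad_score <- seq_len(n_lq) %% 2L == 1L
      junk$ion_score[bad_score] <- round(stats::runif(sum(bad_score), 5, 20), 2)
      junk$qvalue[!bad_score] <- signif(stats::runif(sum(!bad_score),
                                                     0.01, 0.2), 4)
      tab <- rbind(tab, junk)
    }
    rownames(tab) <- NULL
    tab$pool_id <- sprintf("pool%d", pool)
    tab
  }
  psm_tables <- lapply(seq_len(config$n_replicate_pools), make_pool)
  names(psm_tables) <- sprintf("pool%d", seq_len(config$n_replicate_pools))

  annotation <- simulate_annotation(config, protein_id, spiked_idx)

  truth_proteins <- data.frame(protein_id = protein_id,
                               baseline = baseline,
                               spiked = seq_len(n) %in% spiked_idx,
                               spike_group = spike_group,
                               spike_fc = spike_fc,
                               stringsAsFactors = FALSE)
  for (g in groups) truth_proteins[[paste0("mult_", g)]] <- mult[, g]
  for (ct in default_contrasts()) {
    if (all(c(ct$case_group, ct$control_group) %in% groups)) {
      truth_proteins[[paste0("fc_", ct$name)]] <-
        mult[, ct$case_group] / mult[, ct$control_group]
    }
  }

  truth_peptides <- data.frame(
    peptide_sequence = sequences,
    protein_ids = ifelse(shared,
                         paste(protein_id[parent1], protein_id[parent2],
                               sep = ";"),
                         protein_id[parent1]),
    shared = shared,
    ionization = ionization,
    stringsAsFactors = FALSE
  )

  list(psm_tables = psm_tables,
       annotation = annotation,
       truth = list(proteins = truth_proteins,
                    terms = annotation$truth_terms,
                    peptides = truth_peptides),
       config = config)
}

simulate_annotation <- function(config, protein_id, spiked_idx) {
  n <- length(protein_id)
  n_terms <- config$n_terms
  n_enr <- round(config$frac_terms_enriched * n_terms)
  term_id <- sprintf("T%04d", seq_len(n_terms))
  enriched <- seq_len(n_terms) <= n_enr
  namespace <- ifelse(enriched, "BP",
                      sample(c("BP", "MF", "CC", "PATHWAY"),
                             n_terms, replace = TRUE))
  rows <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    k <- sample(5:15, 1L)
    k <- min(k, n)
    if (enriched[t] && length(spiked_idx) > 0) {
      # ~80% of members drawn from spiked proteins
      k_sp <- min(length(spiked_idx), max(1L, round(0.8 * k)))
      members <- c(sample(spiked_idx, k_sp),
                   sample(setdiff(seq_len(n), spiked_idx),
                          min(k - k_sp, n - length(spiked_idx))))
    } else {
      members <- sample.int(n, k)
    }
    rows[[t]] <- data.frame(protein_id = protein_id[sort(unique(members))],
                            term_id = term_id[t],
                            stringsAsFactors = FALSE)
  }
  list(map = do.call(rbind, rows),
       terms = data.frame(term_id = term_id, namespace = namespace,
                          name = paste0("term ", term_id),
                          stringsAsFactors = FALSE),
       truth_terms = data.frame(term_id = term_id, enriched = enriched,
                                stringsAsFactors = FALSE))
}

#' Write a simulated experiment to disk
#'
#' Writes one PSM TSV per pool plus annotation and ground-truth TSVs,
#' UTF-8 with '.' decimal separator.
#'
#' @param experiment Result of [generate_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths (`psm` is a vector
#'   with one path per pool).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  psm_paths <- character(0)
  for (pool in names(experiment$psm_tables)) {
    p <- file.path(dir, paste0("psm_", pool, ".tsv"))
    tab <- experiment$psm_tables[[pool]]
    write_tsv(tab[setdiff(names(tab), "pool_id")], p)
    psm_paths[pool] <- p
  }
  paths <- list(
    psm = psm_paths,
    annotation_map = file.path(dir, "annotation_map.tsv"),
    annotation_terms = file.path(dir, "annotation_terms.tsv"),
    truth_proteins = file.path(dir, "truth_proteins.tsv"),
    truth_terms = file.path(dir, "truth_terms.tsv"),
    truth_peptides = file.path(dir, "truth_peptides.tsv")
  )
  write_tsv(experiment$annotation$map, paths$annotation_map)
  write_tsv(experiment$annotation$terms, paths$annotation_terms)
  write_tsv(experiment$truth$proteins, paths$truth_proteins)
  write_tsv(experiment$truth$terms, paths$truth_terms)
  write_tsv(experiment$truth$peptides, paths$truth_peptides)
  invisible(paths)
}

#' Simulate an experiment and write it to disk
#'
#' Convenience wrapper: [generate_experiment()] followed by
#' [write_experiment()].
#'
#' @inheritParams generate_experiment
#' @param dir Output directory.
#' @return List with `experiment` (in-memory objects) and `paths` (files).
#' @export
simulate_experiment <- function(config, dir) {
  experiment <- generate_experiment(config)
  paths <- write_experiment(experiment, dir)
  invisible(list(experiment = experiment, paths = paths))
}

#' Simulate a western-blot densitometry table
#'
#' Emulates film densitometry for selected proteins: per group, three lanes
#' (biological repeats) of band intensity plus a housekeeping actin intensity
#' per lane. Group mean band levels track the true group multipliers from the
#' simulation ground truth, so with `noise_cv = 0` the actin-normalized group
#' ratio equals the true fold change exactly.
#'
#' @param truth The `truth` element of a [generate_experiment()] result.
#' @param proteins Character vector of protein ids to blot (must exist in the
#'   truth table).
#' @param noise_cv Multiplicative log-normal noise CV on band and actin
#'   intensities.
#' @param seed Integer seed.
#' @param n_lanes Lanes (biological repeats) per group.
#' @return Data frame `protein  group  lane  band_intensity  actin_intensity`.
#' @export
generate_densitometry <- function(truth, proteins, noise_cv = 0.05,
                                  seed = 1L, n_lanes = 3L) {
  tp <- truth$proteins
  missing <- setdiff(proteins, tp$protein_id)
  if (length(missing) > 0) {
    stop("unknown protein(s): ", paste(missing, collapse = ", "))
  }
  mult_cols <- grep("^mult_", names(tp), value = TRUE)
  groups <- sub("^mult_", "", mult_cols)
  set.seed(as.integer(seed))
  rows <- list()
  for (pr in proteins) {
    i <- match(pr, tp$protein_id)
    for (g in seq_along(groups)) {
      band <- 1000 * tp[[mult_cols[g]]][i] * reporter_noise(n_lanes, noise_cv)
      actin <- 500 * reporter_noise(n_lanes, noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = pr, group = groups[g], lane = seq_len(n_lanes),
        band_intensity = band, actin_intensity = actin,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixture table of viable-fetus counts per sow
#'
#' Integer per-sow realizations of the recorded group summaries for viable
#' fetuses at days 49 and 72 in Meishan (MS) and Duroc (DU) sows, three sows
#' per group: MSD49 {16, 16, 17} (mean 16.3, sd 0.47), MSD72 {14, 14, 15}
#' (14.3 +/- 0.47), DUD49 {10, 11, 12} (11 +/- 0.82) and DUD72 {8, 9, 9}
#' (8.67 +/- 0.47), where sd is the population standard deviation.
#'
#' @return Data frame `group  sow_id  viable_fetuses`.
#' @seealso [fetal_loss_rate()]
#' @export
fixture_fetal_counts <- function() {
  data.frame(
    group = rep(c("MSD49", "MSD72", "DUD49", "DUD72"), each = 3L),
    sow_id = paste0(rep(c("MS", "MS", "DU", "DU"), each = 3L),
                    rep(1:3, times = 4L), rep(c("_d49", "_d72"),
                                              each = 3L, times = 2L)),
    viable_fetuses = c(16L, 16L, 17L, 14L, 14L, 15L,
                       10L, 11L, 12L, 8L, 9L, 9L),
    stringsAsFactors = FALSE
  )
}
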