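# In-code fixtures: tiny PSM tables in the TSV dialect the package reads.

psm_row <- function(spectrum, seq, prots, score = 50, q = 0.001,
                    i127 = 100, i128 = 100, i129 = 100, i130 = 100,
                    pool = "pool1") {
  data.frame(spectrum_id = spectrum, peptide_sequence = seq,
             protein_ids = prots, ion_score = score, qvalue = q,
             intensity_127 = i127, intensity_128 = i128,
             intensity_129 = i129, intensity_130 = i130,
             pool_id = pool, stringsAsFactors = FALSE)
}

make_psm_table <- function(..., channel_map = default_channel_map()) {
  tab <- do.call(rbind, list(...))
  rownames(tab) <- NULL
  attr(tab, "channel_map") <- channel_map
  tab
}

write_psm_fixture <- function(tab, path = tempfile(fileext = ".tsv")) {
  utils::write.table(tab[setdiff(names(tab), "pool_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# quant-result rows for exercising the DEP caller directly
quant_row <- function(protein, fc, p, common = TRUE,
                      contrast = "MSD49_vs_DUD49") {
  data.frame(protein_id = protein, contrast = contrast, fc_geomean = fc,
             p_value = p, n_peptides = 4L,
             quantified_in_all_pools = common, stringsAsFactors = FALSE)
}

# independent sort-based median oracle (midpoint rule for even counts)
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

# independent hypergeometric pmf via log-binomials (no dhyper)
hyper_pmf_oracle <- function(x, r1, r2, k) {
  exp(lchoose(r1, x) + lchoose(r2, k - x) - lchoose(r1 + r2, k))
}

fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 + r2 == 0) return(NA_real_)
  xs <- max(0, k - r2):min(r1, k)
  dens <- hyper_pmf_oracle(xs, r1, r2, k)
  d_obs <- dens[xs == a]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}
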