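#' Run the full differential-proteomics pipeline
#'
#' End-to-end orchestration: read per-pool PSM tables, apply identification
#' filters, flag unique peptides experiment-wide, quantify every contrast
#' (per-pool median rollup, geometric-mean combination, pooled t-test), call
#' DEPs, run Fisher enrichment of each contrast's DEP set against its
#' commonly quantified background, compute cross-contrast Venn counts and
#' direction concordance for one contrast pair, and (when inputs are given)
#' the orthogonal-validation statistics. All result tables are written as
#' TSV under `out_dir` together with a JSON run manifest recording
#' parameters and per-stage counts; re-running with unchanged inputs
#' reproduces the bundle byte-for-byte.
#'
#' @param psm_paths Character vector of PSM TSV paths, one per replicate
#'   pool (names, if present, are used as pool ids).
#' @param annotation_map_path,annotation_terms_path Annotation TSVs (see
#'   [read_annotation()]).
#' @param out_dir Output directory, created if missing.
#' @param channel_map Group -> channel tag map.
#' @param contrasts List of [contrast_spec()]; default the four standard
#'   breed/stage contrasts.
#' @param min_ion_score,max_fdr Identification filters (see
#'   [filter_psms()]).
#' @param up,down,alpha DEP thresholds (see [call_deps()]).
#' @param top_bp,top_pathway Top-k sizes for the BP and pathway reports.
#' @param overlap_pair Length-2 character vector naming the contrasts whose
#'   shared DEPs are classified by direction; both must be in `contrasts`.
#' @param densitometry_path Optional densitometry TSV for
#'   [wb_relative_expression()] / [wb_anova()].
#' @param fetal_counts_path Optional fetal-count TSV for
#'   [fetal_loss_rate()].
#' @return Invisibly, a list with all in-memory results (`quant`, `deps`,
#'   `summary`, `enrichment`, `venn`, `overlap`, `concordance`, `manifest`).
#' @export
run_pipeline <- function(psm_paths,
                         annotation_map_path,
                         annotation_terms_path,
                         out_dir,
                         channel_map = default_channel_map(),
                         contrasts = default_contrasts(),
                         min_ion_score = 20, max_fdr = 0.01,
                         up = 1.3, down = 0.70, alpha = 0.05,
                         top_bp = 15L, top_pathway = 5L,
                         overlap_pair = c("MSD49_vs_DUD49",
                                          "DUD72_vs_DUD49"),
                         densitometry_path = NULL,
                         fetal_counts_path = NULL) {
  for (p in c(psm_paths, annotation_map_path, annotation_terms_path,
              densitometry_path, fetal_counts_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(psm_paths))) {
    names(psm_paths) <- sprintf("pool%d", seq_along(psm_paths))
  }

  tables <- lapply(names(psm_paths), function(pid) {
    read_psm_table(psm_paths[[pid]], channel_map, pool_id = pid)
  })
  psm <- combine_psm_tables(tables)
  n_psms_read <- nrow(psm)
  psm <- filter_psms(psm, min_ion_score, max_fdr)
  n_psms_filtered <- nrow(psm)
  psm <- assign_uniqueness(psm)
  n_unique_records <- sum(psm$unique_peptide)

  annotation <- read_annotation(annotation_map_path, annotation_terms_path)

  contrast_names <- vapply(contrasts, `[[`, character(1), "name")
  quant <- list()
  deps <- list()
  stage_counts <- list()
  for (ct in contrasts) {
    q <- quantify_contrast(psm, ct, channel_map)
    calls <- call_deps(q, up = up, down = down, alpha = alpha)
    quant[[ct$name]] <- q
    deps[[ct$name]] <- calls
    stage_counts[[ct$name]] <- list(
      n_quantified = nrow(q),
      n_common = sum(q$quantified_in_all_pools),
      n_increased = sum(calls$class == "increased"),
      n_decreased = sum(calls$class == "decreased"))
    write_tsv(round_numeric(q), file.path(out_dir,
                                          paste0("quant_", ct$name, ".tsv")))
    write_tsv(round_numeric(calls), file.path(out_dir,
                                              paste0("deps_", ct$name, ".tsv")))
  }

  dep_summary <- summarize_contrasts(deps, contrast_names)
  write_tsv(dep_summary, file.path(out_dir, "dep_summary.tsv"))

  enrichment <- list()
  for (ct_name in contrast_names) {
    q <- quant[[ct_name]]
    background <- q$protein_id[q$quantified_in_all_pools]
    calls <- deps[[ct_name]]
    dep_ids <- calls$protein_id[calls$class != "unchanged"]
    enr <- fisher_enrichment(dep_ids, background, annotation)
    enrichment[[ct_name]] <- enr
    write_tsv(round_numeric(enr),
              file.path(out_dir, paste0("enrichment_", ct_name, ".tsv")))
    write_tsv(round_numeric(top_terms(enr, "BP", top_bp)),
              file.path(out_dir, paste0("top_bp_", ct_name, ".tsv")))
    write_tsv(round_numeric(top_terms(enr, "PATHWAY", top_pathway)),
              file.path(out_dir, paste0("top_pathway_", ct_name, ".tsv")))
  }

  dep_sets <- lapply(deps, function(d) d$protein_id[d$class != "unchanged"])
  venn <- NULL
  if (length(dep_sets) >= 2L && length(dep_sets) <= 4L) {
    venn <- venn_counts(dep_sets)
    write_tsv(venn, file.path(out_dir, "venn_dep_regions.tsv"))
  }
  overlap <- NULL
  if (all(overlap_pair %in% contrast_names)) {
    overlap <- classify_shared_deps(deps[[overlap_pair[1]]],
                                    deps[[overlap_pair[2]]])
    write_tsv(round_numeric(overlap),
              file.path(out_dir, "shared_dep_concordance.tsv"))
  }

  concordance <- list()
  if (!is.null(densitometry_path)) {
    dens <- read_tsv(densitometry_path)
    rel <- wb_relative_expression(dens)
    concordance$wb <- rel
    concordance$wb_anova <- wb_anova(rel$values)
    write_tsv(round_numeric(rel$summary),
              file.path(out_dir, "wb_relative_expression.tsv"))
    write_tsv(round_numeric(concordance$wb_anova),
              file.path(out_dir, "wb_anova.tsv"))
  }
  if (!is.null(fetal_counts_path)) {
    counts <- read_tsv(fetal_counts_path)
    fl <- list()
    for (breed in list(c("MSD49", "MSD72"), c("DUD49", "DUD72"))) {
      if (all(breed %in% counts$group)) {
        fl[[paste(breed, collapse = "_to_")]] <-
          fetal_loss_rate(counts, breed[1], breed[2])
      }
    }
    concordance$fetal_loss <- fl
    if (length(fl) > 0) {
      fl_df <- data.frame(
        transition = names(fl),
        loss_pct = round(vapply(fl, `[[`, numeric(1), "loss_pct"), 6),
        stringsAsFactors = FALSE)
      write_tsv(fl_df, file.path(out_dir, "fetal_loss.tsv"))
    }
  }

  manifest <- list(
    package = "itraqdep",
    version = as.character(utils::packageVersion("itraqdep")),
    parameters = list(min_ion_score = min_ion_score, max_fdr = max_fdr,
                      up = up, down = down, alpha = alpha,
                      top_bp = top_bp, top_pathway = top_pathway,
                      channel_map = as.list(channel_map),
                      contrasts = contrast_names,
                      overlap_pair = overlap_pair),
    inputs = list(psm = unname(vapply(psm_paths, basename, character(1))),
                  pools = names(psm_paths)),
    counts = c(list(n_psms_read = n_psms_read,
                    n_psms_filtered = n_psms_filtered,
                    n_unique_peptide_records = n_unique_records),
               stage_counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(psm = psm, quant = quant, deps = deps,
                 summary = dep_summary, enrichment = enrichment,
                 venn = venn, overlap = overlap, concordance = concordance,
                 manifest = manifest))
}

# round floating-point columns for stable, diffable TSV output
round_numeric <- function(df, digits = 10) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  }
  df
}
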