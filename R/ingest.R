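#' Read a PSM reporter-intensity table
#'
#' Parses one replicate pool's PSM table from TSV. Required columns:
#' `spectrum_id`, `peptide_sequence`, `protein_ids` (';'-separated
#' accessions), `ion_score`, `qvalue`, and one `intensity_<tag>` column per
#' channel in `channel_map`. Blank intensities are read as missing (`NA`);
#' rows whose intensity or score fields are non-numeric text are dropped
#' with a warning naming the offending line numbers.
#'
#' @param path Path to the TSV file.
#' @param channel_map Named character vector group -> channel tag.
#' @param pool_id Replicate-pool identifier attached to every row; defaults
#'   to the file name without extension.
#' @return Data frame of PSM records with a `pool_id` column and the channel
#'   map stored in `attr(, "channel_map")`.
#' @export
read_psm_table <- function(path, channel_map = default_channel_map(),
                           pool_id = NULL) {
  check_channel_map(channel_map)
  if (is.null(pool_id)) {
    pool_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  int_cols <- paste0("intensity_", unname(channel_map))
  required <- c("spectrum_id", "peptide_sequence", "protein_ids",
                "ion_score", "qvalue", int_cols)
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0) {
    stop("PSM table '", path, "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  numeric_cols <- c("ion_score", "qvalue", int_cols)
  bad <- rep(FALSE, nrow(raw))
  for (col in numeric_cols) {
    v <- trimws(raw[[col]])
    converted <- suppressWarnings(as.numeric(v))
    # blank (or literal NA) = missing, legal for intensities only
    is_blank <- !nzchar(v) | v == "NA"
    malformed <- is.na(converted) & !is_blank
    if (col %in% c("ion_score", "qvalue")) malformed <- malformed | is_blank
    bad <- bad | malformed
    converted[is_blank] <- NA_real_
    raw[[col]] <- converted
  }
  if (any(bad)) {
    # +1 for the header line
    warning("dropping ", sum(bad), " malformed row(s) in '", path,
            "' (file line ", paste(which(bad) + 1L, collapse = ", "), ")")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (any(raw$qvalue < 0 | raw$qvalue > 1, na.rm = TRUE)) {
    stop("q-values outside [0, 1] in '", path, "'")
  }
  raw$pool_id <- pool_id
  rownames(raw) <- NULL
  attr(raw, "channel_map") <- channel_map
  raw
}

#' Combine per-pool PSM tables into one experiment table
#'
#' @param tables List of PSM data frames from [read_psm_table()] (or the
#'   `psm_tables` element of [generate_experiment()]).
#' @return Single data frame; the channel map of the first table is carried
#'   over (all tables must agree).
#' @export
combine_psm_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  maps <- lapply(tables, attr, "channel_map")
  maps <- maps[!vapply(maps, is.null, logical(1))]
  if (length(maps) > 1L &&
      !all(vapply(maps, identical, logical(1), y = maps[[1]]))) {
    stop("PSM tables carry conflicting channel maps")
  }
  out <- do.call(rbind, lapply(tables, function(t) {
    attr(t, "channel_map") <- NULL
    t
  }))
  rownames(out) <- NULL
  if (length(maps) >= 1L) attr(out, "channel_map") <- maps[[1]]
  out
}

#' Apply identification filters to a PSM table
#'
#' Retains rows with ion score strictly above `min_ion_score` and q-value
#' strictly below `max_fdr` (score > 20 and FDR < 1% by default). Row order
#' is preserved; the operation is idempotent.
#'
#' @param table PSM data frame.
#' @param min_ion_score Minimum ion score (exclusive).
#' @param max_fdr Maximum PSM-level q-value (exclusive).
#' @return Filtered PSM data frame; retention is reported via `message()`.
#' @export
filter_psms <- function(table, min_ion_score = 20, max_fdr = 0.01) {
  keep <- !is.na(table$ion_score) & table$ion_score > min_ion_score &
    !is.na(table$qvalue) & table$qvalue < max_fdr
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channel_map") <- attr(table, "channel_map")
  message("filter_psms: retained ", nrow(out), " of ", nrow(table),
          " PSMs (ion_score > ", min_ion_score, ", qvalue < ", max_fdr, ")")
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warning("filter_psms: no PSMs pass the identification filters")
  }
  out
}

#' Flag unique peptides experiment-wide
#'
#' A peptide sequence is unique iff it maps to exactly one distinct protein
#' accession across the whole experiment (all pools jointly); only unique
#' peptides enter protein quantitation. The grouping key is the bare
#' sequence. Adds columns `unique_peptide` (logical) and `protein_id` (the
#' single accession, `NA` for non-unique peptides).
#'
#' @param table Combined PSM data frame (all pools).
#' @return The table with uniqueness columns added.
#' @export
assign_uniqueness <- function(table) {
  prot_sets <- lapply(split(table$protein_ids, table$peptide_sequence),
                      function(p) unique(unlist(strsplit(p, ";", fixed = TRUE))))
  n_prot <- vapply(prot_sets, length, integer(1))
  uniq_map <- ifelse(n_prot == 1L,
                     vapply(prot_sets, `[`, character(1), 1L),
                     NA_character_)
  table$unique_peptide <- n_prot[table$peptide_sequence] == 1L
  table$protein_id <- unname(uniq_map[table$peptide_sequence])
  table
}
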