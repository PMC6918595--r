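#' Venn region counts for 2-4 named sets
#'
#' Partitions the union of the sets into the 2^k - 1 exclusive Venn regions
#' and counts the members of each. Region names are the sorted member-set
#' names joined with `"&"`, so output is deterministic and diffable.
#'
#' @param id_sets Named list of 2-4 character vectors.
#' @return Data frame `region  count` covering every region (zero counts
#'   included), ordered by region degree then name.
#' @export
venn_counts <- function(id_sets) {
  if (!is.list(id_sets) || length(id_sets) < 2L || length(id_sets) > 4L) {
    stop("venn_counts supports 2 to 4 named sets")
  }
  if (is.null(names(id_sets)) || any(!nzchar(names(id_sets))) ||
      anyDuplicated(names(id_sets))) {
    stop("sets must have distinct non-empty names")
  }
  set_names <- names(id_sets)
  id_sets <- lapply(id_sets, unique)
  universe <- unique(unlist(id_sets, use.names = FALSE))
  membership <- vapply(id_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  k <- length(set_names)
  combos <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(sort(set_names), size, simplify = FALSE)
    combos <- c(combos, cmb)
  }
  rows <- lapply(combos, function(members) {
    inside <- if (length(universe) == 0L) logical(0) else {
      rowSums(membership[, members, drop = FALSE]) == length(members) &
        rowSums(membership[, setdiff(set_names, members),
                           drop = FALSE]) == 0
    }
    data.frame(region = paste(members, collapse = "&"),
               count = sum(inside), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify DEPs shared between two contrasts by direction concordance
#'
#' Shared proteins are those called differentially expressed (class not
#' `unchanged`) in both contrasts. Each receives one concordance label:
#' `both_increased`, `both_decreased`, or `reverse` (opposite directions in
#' the two contrasts, the "reverse expression pattern" case).
#'
#' @param calls_a,calls_b [call_deps()] outputs for the two contrasts.
#' @return Data frame `protein_id  contrast_a  contrast_b  class_a  class_b
#'   concordance`, one row per shared DEP, ordered by protein id.
#' @export
classify_shared_deps <- function(calls_a, calls_b) {
  dep_a <- calls_a[calls_a$class != "unchanged", , drop = FALSE]
  dep_b <- calls_b[calls_b$class != "unchanged", , drop = FALSE]
  shared <- sort(intersect(dep_a$protein_id, dep_b$protein_id))
  class_a <- dep_a$class[match(shared, dep_a$protein_id)]
  class_b <- dep_b$class[match(shared, dep_b$protein_id)]
  concordance <- as.character(ifelse(class_a == class_b,
                                     paste0("both_", class_a),
                                     "reverse"))
  data.frame(protein_id = shared,
             contrast_a = if (length(shared)) dep_a$contrast[match(shared, dep_a$protein_id)] else character(0),
             contrast_b = if (length(shared)) dep_b$contrast[match(shared, dep_b$protein_id)] else character(0),
             class_a = class_a,
             class_b = class_b,
             concordance = concordance,
             stringsAsFactors = FALSE)
}
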