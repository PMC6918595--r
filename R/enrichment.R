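#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' Exact test on the table `rbind(c(a, b), c(c, d))` with fixed margins,
#' using the probability-mass two-tailed rule: the p-value sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. Ties are detected with a relative tolerance of 1e-7 (the
#' same convention as `stats::fisher.test`) so that mathematically equal
#' probabilities are not split by floating-point rounding.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` is the
#'   target-and-selected cell.
#' @return Two-tailed p-value in `[0, 1]` (`NA` for the empty table).
#' @export
fisher_p_two_tailed <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- r1 + r2
  if (n == 0) return(NA_real_)
  lo <- max(0, k - r2)
  hi <- min(r1, k)
  x <- lo:hi
  dens <- stats::dhyper(x, r1, r2, k)
  d_obs <- dens[x == a]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Fisher exact enrichment of a DEP set against the quantified background
#'
#' For every annotation term with at least one annotated background protein,
#' builds the 2x2 table (a = DEPs with term, b = DEPs without, c = non-DEP
#' background with term, d = non-DEP background without) and computes the
#' two-tailed Fisher exact p-value against the commonly quantified
#' background, the odds ratio `(a*d)/(b*c)`, and a Benjamini-Hochberg
#' adjusted p-value (reported alongside; top-term selection uses raw p).
#' Background proteins absent from the annotation map simply count in the
#' without-term cells.
#'
#' @param dep_set Character vector of DEP protein ids; must be a subset of
#'   `background`.
#' @param background Character vector of all quantified protein ids.
#' @param annotation List with `map` (columns `protein_id`, `term_id`) and
#'   `terms` (columns `term_id`, `namespace`, `name`), as produced by
#'   [generate_experiment()] or [read_annotation()].
#' @return Data frame `term_id  namespace  name  a  b  c  d  odds_ratio
#'   p_value  p_adj`, one row per term with >= 1 background annotation.
#' @export
fisher_enrichment <- function(dep_set, background, annotation) {
  dep_set <- unique(dep_set)
  background <- unique(background)
  stray <- setdiff(dep_set, background)
  if (length(stray) > 0) {
    stop("DEP set is not a subset of the background; offending id(s): ",
         paste(stray, collapse = ", "))
  }
  map <- annotation$map
  map <- map[map$protein_id %in% background, , drop = FALSE]
  terms <- annotation$terms
  n_dep <- length(dep_set)
  n_bg <- length(background)
  ann_split <- split(map$protein_id, factor(map$term_id,
                                            levels = terms$term_id))
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    with_term <- unique(ann_split[[terms$term_id[i]]])
    m <- length(with_term)
    if (m == 0L) return(NULL)
    a <- sum(with_term %in% dep_set)
    b <- n_dep - a
    c <- m - a
    d <- n_bg - n_dep - c
    or <- (a * d) / (b * c)
    if (is.nan(or)) or <- NA_real_  # 0/0: undefined
    data.frame(term_id = terms$term_id[i], namespace = terms$namespace[i],
               name = terms$name[i], a = a, b = b, c = c, d = d,
               odds_ratio = or,
               p_value = fisher_p_two_tailed(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), namespace = character(0),
                      name = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Top enriched terms in a namespace
#'
#' Keeps over-represented significant terms (odds ratio > 1 and raw
#' p < 0.05), sorts ascending by p with ties broken by descending `a` then
#' lexical term id, and truncates to `k`. The conventional report shows the
#' top 15 biological processes and top 5 pathways.
#'
#' @param results Output of [fisher_enrichment()].
#' @param namespace Namespace to report (`"BP"`, `"MF"`, `"CC"`,
#'   `"PATHWAY"`).
#' @param k Number of terms to keep (>= 1); default 15 for BP, 5 for
#'   PATHWAY, 15 otherwise.
#' @param alpha Raw-p significance cutoff (strict), default 0.05.
#' @return Ordered data frame (possibly empty) of at most `k` rows.
#' @export
top_terms <- function(results, namespace = "BP",
                      k = if (namespace == "PATHWAY") 5L else 15L,
                      alpha = 0.05) {
  stopifnot(k >= 1)
  hits <- results[results$namespace == namespace &
                    !is.na(results$odds_ratio) & results$odds_ratio > 1 &
                    results$p_value < alpha, , drop = FALSE]
  hits <- hits[order(hits$p_value, -hits$a, hits$term_id), , drop = FALSE]
  out <- utils::head(hits, k)
  rownames(out) <- NULL
  out
}

#' Read an annotation map from TSV files
#'
#' @param map_path 2-column TSV `protein_id  term_id`.
#' @param terms_path TSV `term_id  namespace  name`; namespaces are GO-style
#'   (`BP`, `MF`, `CC`) or `PATHWAY`.
#' @return List with `map` and `terms` data frames.
#' @export
read_annotation <- function(map_path, terms_path) {
  map <- read_tsv(map_path)
  terms <- read_tsv(terms_path)
  if (!all(c("protein_id", "term_id") %in% names(map))) {
    stop("annotation map must have columns protein_id, term_id")
  }
  if (!all(c("term_id", "namespace", "name") %in% names(terms))) {
    stop("term table must have columns term_id, namespace, name")
  }
  list(map = map, terms = terms)
}
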