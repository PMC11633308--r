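# Generic set-overlap machinery for binding targets vs
# knockdown-responsive gene sets, the Jaccard index, and the
# regulated-cassette-exon gene count.

#' Overlap test between two gene sets within a universe
#'
#' Builds the 2x2 table `a = |A n B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = |U \ (A u B)|`. The one-sided (greater) Fisher exact p equals the
#' hypergeometric upper tail at `a`; `"hypergeom_ge"` is the same test by
#' duality. The odds ratio is `ad/bc` with a 0.5 correction applied to
#' all cells only when some cell is zero.
#'
#' @param setA,setB Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector of gene ids.
#' @param test `"fisher_greater"`, `"fisher_two_sided"` or
#'   `"hypergeom_ge"`.
#' @return One-row data frame with the cells, `odds_ratio`, `p_value`,
#'   `test`, `universe_size`.
#' @export
set_overlap_test <- function(setA, setB, universe,
                             test = c("fisher_greater", "fisher_two_sided",
                                      "hypergeom_ge")) {
  test <- match.arg(test)
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  outA <- setdiff(setA, universe); outB <- setdiff(setB, universe)
  if (length(outA) || length(outB)) {
    stop("element outside universe: ", c(outA, outB)[1])
  }
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c_ <- length(setB) - a
  d <- length(universe) - a - b - c_
  p <- switch(test,
    fisher_greater = fisher_greater_p(a, b, c_, d),
    hypergeom_ge = fisher_greater_p(a, b, c_, d),
    fisher_two_sided = stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                                 byrow = TRUE))$p.value)
  data.frame(a = a, b = b, c = c_, d = d,
             odds_ratio = odds_ratio_2x2(a, b, c_, d),
             p_value = p, test = test,
             universe_size = length(universe), stringsAsFactors = FALSE)
}

#' Jaccard index of two sets
#'
#' @param setA,setB Character vectors.
#' @return `|A n B| / |A u B|`; 0 when both sets are empty.
#' @export
jaccard <- function(setA, setB) {
  u <- length(union(setA, setB))
  if (u == 0) return(0)
  length(intersect(setA, setB)) / u
}

## distance from point j to half-open interval [s, e): 0 when contained
point_interval_gap <- function(j, s, e) {
  pmax(0, pmax(s - j, j - (e - 1)))
}

#' Count genes with a binding-supported regulated cassette exon
#'
#' A (gene, event) pair is supported when some binding window on that
#' gene lies within `max_dist` bp of one of the event's cassette-exon
#' junction coordinates (gap 0 when the junction falls inside the
#' window). Genes are counted once regardless of how many events or
#' windows support them.
#'
#' @param windows Gene-assigned window frame (`gene_id`, `start`, `end`).
#' @param se_events Significant skipped-exon events with `gene_id` and a
#'   `junction_coords` list-column.
#' @param max_dist Maximum window-to-junction gap in bp.
#' @return List with `n_genes`, `supporting` (data frame of
#'   gene/event/window triples) and `n_skipped` (events without junction
#'   coordinates).
#' @export
count_regulated_cassettes <- function(windows, se_events, max_dist = 50L) {
  triples <- list(); n_skipped <- 0L
  for (i in seq_len(NROW(se_events))) {
    jc <- se_events$junction_coords[[i]]
    if (is.null(jc) || length(jc) == 0 || all(is.na(jc))) {
      n_skipped <- n_skipped + 1L
      next
    }
    w <- windows[windows$gene_id == se_events$gene_id[i], , drop = FALSE]
    for (wi in seq_len(nrow(w))) {
      gap <- min(point_interval_gap(jc, w$start[wi], w$end[wi]))
      if (gap <= max_dist) {
        triples[[length(triples) + 1]] <- data.frame(
          gene_id = se_events$gene_id[i],
          event_id = se_events$event_id[i],
          window = sprintf("%s:%d-%d", w$chrom[wi], w$start[wi], w$end[wi]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0) warning(n_skipped, " event(s) without junction ",
                             "coordinates skipped")
  supporting <- if (length(triples)) do.call(rbind, triples) else
    data.frame(gene_id = character(0), event_id = character(0),
               window = character(0))
  list(n_genes = length(unique(supporting$gene_id)),
       supporting = supporting, n_skipped = n_skipped)
}

#' Build a binding target gene set, optionally restricted by feature class
#'
#' @param windows Annotated window frame.
#' @param filter `NULL` (all windows) or a character vector of feature
#'   classes.
#' @return Character vector of unique gene ids.
#' @export
build_target_sets <- function(windows, filter = NULL) {
  if (!is.null(filter)) {
    if (is.null(windows$feature_class)) {
      stop("windows are not annotated; run annotate_windows() first")
    }
    windows <- windows[windows$feature_class %in% filter, , drop = FALSE]
  }
  unique(windows$gene_id[!is.na(windows$gene_id) & windows$gene_id != ""])
}

#' Benjamini-Hochberg adjustment of a panel of overlap tests
#'
#' @param results Data frame with a `p_value` column.
#' @return `results` with a `p_adj` column added.
#' @export
adjust_panel <- function(results) {
  results$p_adj <- stats::p.adjust(results$p_value, method = "BH")
  results
}
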