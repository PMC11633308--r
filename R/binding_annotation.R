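# Assignment of eCLIP enriched windows to transcript feature classes,
# feature enrichment odds ratios against a background window set, and
# binding-breadth classification.

FEATURE_CLASSES <- c("5'UTR", "CDS", "3'UTR", "intron", "SS5_ADJ", "SS5_PROX",
                     "SS3_ADJ", "SS3_PROX", "noncoding", "intergenic")

#' Classify a window into a transcript feature class
#'
#' Classification is by window midpoint. Splice-site classes take
#' precedence over plain containment classes: a midpoint within `adj_bp`
#' (default 50 bp) of a splice site is SS5_ADJ/SS3_ADJ, within `prox_bp`
#' (default 300 bp) SS5_PROX/SS3_PROX. 5' splice sites are donors, 3'
#' splice sites acceptors, strand-aware. When both a donor and an acceptor
#' qualify at the same tier, the nearer wins; exact ties go to the 3'
#' splice site. Otherwise the class is the containment feature holding the
#' midpoint (5'UTR/CDS/3'UTR/intron, or noncoding for genes without a
#' CDS). A window that does not overlap the gene is intergenic.
#'
#' @param window One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param gene A [gene_model()].
#' @param adj_bp,prox_bp Splice-site distance tiers in bp.
#' @param use_ss_classes When `FALSE`, only containment classes are
#'   assigned (used e.g. when scoring feature enrichment on simulations
#'   planted by containment feature).
#' @return A feature class string.
#' @export
classify_feature <- function(window, gene, adj_bp = 50L, prox_bp = 300L,
                             use_ss_classes = TRUE) {
  mid <- midpoint(window$start, window$end)
  if (window$chrom != gene$chrom || window$end <= gene$start ||
      window$start >= gene$end) {
    return("intergenic")
  }
  if (use_ss_classes && nrow(gene$exons) >= 2) {
    ss <- splice_sites(gene)
    d5 <- if (length(ss$donor)) min(abs(mid - ss$donor)) else Inf
    d3 <- if (length(ss$acceptor)) min(abs(mid - ss$acceptor)) else Inf
    for (tier in list(c(adj_bp, 1), c(prox_bp, 2))) {
      lim <- tier[1]
      if (d5 <= lim || d3 <= lim) {
        use3 <- d3 <= lim && (d5 > lim || d3 <= d5)
        return(c(if (use3) "SS3_ADJ" else "SS5_ADJ",
                 if (use3) "SS3_PROX" else "SS5_PROX")[tier[2]])
      }
    }
  }
  containment_class(mid, gene)
}

midpoint <- function(start, end) (as.numeric(start) + as.numeric(end)) / 2

## donor/acceptor boundary coordinates, strand-aware
splice_sites <- function(g) {
  n <- nrow(g$exons)
  if (n < 2) return(list(donor = numeric(0), acceptor = numeric(0)))
  if (g$strand == "+") {
    list(donor = g$exons[-n, 2], acceptor = g$exons[-1, 1])
  } else {
    list(donor = g$exons[-1, 1], acceptor = g$exons[-n, 2])
  }
}

containment_class <- function(mid, gene) {
  if (mid < gene$start || mid >= gene$end) return("intergenic")
  pos_in <- function(iv) {
    !is.null(iv) && nrow(iv) > 0 && any(iv[, 1] <= mid & mid < iv[, 2])
  }
  in_exon <- pos_in(gene$exons)
  if (!in_exon) return("intron")
  if (is.null(gene$cds) || nrow(gene$cds) == 0) return("noncoding")
  if (pos_in(gene$utr5)) return("5'UTR")
  if (pos_in(gene$cds)) return("CDS")
  if (pos_in(gene$utr3)) return("3'UTR")
  ## exonic but not in the partition (should not happen for valid models)
  "noncoding"
}

#' Annotate a window table with feature classes
#'
#' @param windows `enriched_windows` data frame with `gene_id` column (or
#'   windows are matched to the gene containing their midpoint).
#' @param genes Annotation from [read_annotation()] / [make_annotation()].
#' @inheritParams classify_feature
#' @return `windows` with a `feature_class` column added.
#' @export
annotate_windows <- function(windows, genes, adj_bp = 50L, prox_bp = 300L,
                             use_ss_classes = TRUE) {
  windows$feature_class <- vapply(seq_len(nrow(windows)), function(i) {
    g <- genes[[windows$gene_id[i]]]
    if (is.null(g)) return("intergenic")
    classify_feature(windows[i, ], g, adj_bp, prox_bp, use_ss_classes)
  }, character(1))
  windows
}

#' Feature enrichment odds ratio (IP windows vs background windows)
#'
#' Builds the 2x2 table of windows inside/outside the feature class for IP
#' and background sets. The odds ratio is `(ip_in/ip_out)/(bg_in/bg_out)`;
#' when any cell is zero the Haldane-Anscombe 0.5 correction is applied to
#' all cells for the ratio (the Fisher p is computed on the raw counts).
#' The p-value is the one-sided (greater) Fisher exact tail.
#'
#' @param ip_windows,background_windows Annotated window frames (must
#'   carry `feature_class`).
#' @param feature_class The class tested.
#' @return One-row data frame: the four cells, `odds_ratio`, `log2_or`,
#'   `fisher_p`.
#' @export
feature_enrichment_odds <- function(ip_windows, background_windows,
                                    feature_class) {
  if (NROW(ip_windows) == 0) stop("empty IP window set")
  if (NROW(background_windows) == 0) stop("empty background window set")
  ip_in <- sum(ip_windows$feature_class == feature_class)
  ip_out <- nrow(ip_windows) - ip_in
  bg_in <- sum(background_windows$feature_class == feature_class)
  bg_out <- nrow(background_windows) - bg_in
  or <- odds_ratio_2x2(ip_in, ip_out, bg_in, bg_out)
  p <- fisher_greater_p(ip_in, ip_out, bg_in, bg_out)
  data.frame(feature_class = feature_class, ip_in = ip_in, ip_out = ip_out,
             bg_in = bg_in, bg_out = bg_out, odds_ratio = or,
             log2_or = log2(or), fisher_p = p, stringsAsFactors = FALSE)
}

odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / b) / (c / d)
}

## one-sided (greater) Fisher exact p: hypergeometric upper tail at a
fisher_greater_p <- function(a, b, c, d) {
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Feature enrichment across all classes present
#'
#' @inheritParams feature_enrichment_odds
#' @param classes Feature classes to test (default: all classes observed
#'   in either set).
#' @return Data frame with one row per class.
#' @export
feature_enrichment_table <- function(ip_windows, background_windows,
                                     classes = NULL) {
  if (is.null(classes)) {
    classes <- intersect(FEATURE_CLASSES,
                         union(ip_windows$feature_class,
                               background_windows$feature_class))
  }
  do.call(rbind, lapply(classes, function(cl) {
    feature_enrichment_odds(ip_windows, background_windows, cl)
  }))
}

#' Binding breadth of a window set
#'
#' Counts unique bound transcripts (gene ids). `strict = FALSE` applies
#' the "widespread RBP" rule (a minimum of `threshold` unique
#' transcripts, i.e. >=); `strict = TRUE` applies the dual-binder rule
#' (strictly more than `threshold` unique genes).
#'
#' @param windows Gene-assigned window frame.
#' @param threshold Transcript-count threshold (default 500).
#' @param strict Use strict inequality.
#' @return List with `n_unique_transcripts` and `widespread`.
#' @export
binding_breadth <- function(windows, threshold = 500L, strict = FALSE) {
  n <- length(unique(windows$gene_id[!is.na(windows$gene_id) &
                                       windows$gene_id != ""]))
  list(n_unique_transcripts = n,
       widespread = if (strict) n > threshold else n >= threshold)
}
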