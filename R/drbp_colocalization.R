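# DNA/RNA dual-binder classification and binding-site geometry:
# nearest-gene assignment of DNA peaks, signed DNA-to-RNA distances,
# metagene density over percent of transcript length, and TSS/TTS
# proximity tests.

#' Assign DNA peaks to their nearest gene
#'
#' Distance is 0 for a peak overlapping the gene span; otherwise the gap
#' between peak and gene span. `dist_to_tss` is the signed midpoint
#' distance to the gene's TSS, positive downstream in the gene's
#' orientation.
#'
#' @param peaks `dna_peaks` data frame.
#' @param genes Annotation list.
#' @return `peaks` with `gene_id`, `gene_dist` and `dist_to_tss` columns.
#' @export
assign_nearest_gene <- function(peaks, genes) {
  if (length(genes) == 0) stop("empty annotation")
  gdf <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                    chrom = vapply(genes, `[[`, "", "chrom"),
                    start = vapply(genes, `[[`, 0L, "start"),
                    end = vapply(genes, `[[`, 0L, "end"),
                    strand = vapply(genes, `[[`, "", "strand"),
                    tss = vapply(genes, `[[`, 0L, "tss"),
                    stringsAsFactors = FALSE)
  peaks$gene_id <- NA_character_
  peaks$gene_dist <- NA_real_
  peaks$dist_to_tss <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    cand <- gdf[gdf$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    gap <- pmax(0, pmax(cand$start - peaks$end[i],
                        peaks$start[i] - cand$end))
    j <- which.min(gap)
    pm <- midpoint(peaks$start[i], peaks$end[i])
    signed <- (pm - cand$tss[j]) * ifelse(cand$strand[j] == "+", 1, -1)
    peaks$gene_id[i] <- cand$gene_id[j]
    peaks$gene_dist[i] <- gap[j]
    peaks$dist_to_tss[i] <- signed
  }
  peaks
}

#' Classify a ZFP's binding mode from DNA peaks and RNA windows
#'
#' A dual DNA/RNA binder (DRBP) binds strictly more than `threshold`
#' unique genes at both levels. DNA peaks farther than `max_intergenic`
#' bp from their nearest gene are excluded from the DNA gene count.
#'
#' @param dna_peaks Peaks (gene-assigned, or `genes` must be supplied).
#' @param rna_windows Gene-assigned window frame.
#' @param genes Annotation (used to assign peaks lacking `gene_id`).
#' @param threshold Gene-count threshold (strict >).
#' @param max_intergenic Maximum peak-to-gene distance in bp.
#' @return List with `n_dna_genes`, `n_rna_genes`, `mode` (one of
#'   `"DRBP"`, `"DNA_only"`, `"RNA_only"`, `"neither"`).
#' @export
classify_binding_mode <- function(dna_peaks, rna_windows, genes = NULL,
                                  threshold = 500L, max_intergenic = 1e5) {
  if (is.null(dna_peaks$gene_id) || is.null(dna_peaks$gene_dist)) {
    if (is.null(genes)) stop("peaks lack gene assignment and no ",
                             "annotation given")
    dna_peaks <- assign_nearest_gene(dna_peaks, genes)
  }
  keep <- !is.na(dna_peaks$gene_id) & dna_peaks$gene_dist <= max_intergenic
  n_dna <- length(unique(dna_peaks$gene_id[keep]))
  n_rna <- length(unique(rna_windows$gene_id[!is.na(rna_windows$gene_id) &
                                               rna_windows$gene_id != ""]))
  mode <- if (n_dna > threshold && n_rna > threshold) "DRBP"
          else if (n_dna > threshold) "DNA_only"
          else if (n_rna > threshold) "RNA_only"
          else "neither"
  list(n_dna_genes = n_dna, n_rna_genes = n_rna, mode = mode)
}

#' Signed distance from each DNA peak to its nearest same-gene RNA window
#'
#' Distances are midpoint to midpoint, restricted to windows on the same
#' gene as the peak. The sign is positive when the window midpoint lies
#' 3' (downstream) of the peak midpoint in the gene's orientation.
#' Nearest means smallest |distance|; exact ties resolve to the positive
#' (downstream) side. Peaks on genes without windows are omitted.
#'
#' @param dna_peaks Gene-assigned peak frame.
#' @param rna_windows Gene-assigned window frame.
#' @param genes Annotation list (for strand lookup).
#' @return Data frame `peak, gene_id, distance`.
#' @export
peak_distance_profile <- function(dna_peaks, rna_windows, genes) {
  out <- list()
  for (i in seq_len(nrow(dna_peaks))) {
    gid <- dna_peaks$gene_id[i]
    if (is.na(gid) || is.null(genes[[gid]])) next
    w <- rna_windows[rna_windows$gene_id == gid, , drop = FALSE]
    if (nrow(w) == 0) next
    orient <- if (genes[[gid]]$strand == "+") 1 else -1
    pm <- midpoint(dna_peaks$start[i], dna_peaks$end[i])
    d <- (midpoint(w$start, w$end) - pm) * orient
    best <- order(abs(d), -sign(d))[1]   # ties -> positive side first
    out[[length(out) + 1]] <- data.frame(
      peak = if (!is.null(dna_peaks$name)) dna_peaks$name[i] else i,
      gene_id = gid, distance = d[best], stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peak = character(0), gene_id = character(0),
               distance = numeric(0))
}

#' Metagene density of RNA windows over percent of transcript length
#'
#' Each window is placed at `100 * (strand-oriented distance from the
#' gene 5' end to the window midpoint) / gene length`, clipped to
#' [0, 100] and binned to integer percent (101 bins, 0 = TSS,
#' 100 = TTS). Densities are normalized to sum to 1.
#'
#' @param rna_windows Gene-assigned window frame.
#' @param genes Annotation list.
#' @param n_bins Number of bins (101 gives integer percent).
#' @return List with `bins` (0..100), `density`, `counts`, `n_windows`.
#' @export
metagene_density <- function(rna_windows, genes, n_bins = 101L) {
  counts <- rep(0L, n_bins)
  n_used <- 0L
  for (i in seq_len(NROW(rna_windows))) {
    g <- genes[[rna_windows$gene_id[i]]]
    if (is.null(g)) next
    len <- g$end - g$start
    if (len <= 0) stop("zero-length gene ", g$gene_id)
    mid <- midpoint(rna_windows$start[i], rna_windows$end[i])
    pos <- if (g$strand == "+") 100 * (mid - g$start) / len
           else 100 * (g$end - mid) / len
    b <- min(max(floor(pos), 0), n_bins - 1L) + 1L
    counts[b] <- counts[b] + 1L
    n_used <- n_used + 1L
  }
  dens <- if (n_used > 0) counts / n_used else counts
  list(bins = seq_len(n_bins) - 1L, density = dens, counts = counts,
       n_windows = n_used)
}

#' TSS/TTS proximity enrichment test between two groups of profiles
#'
#' For each metagene profile, the TSS-proximal density is the summed
#' density of bins 0..`proximal_pct` and the TTS-proximal density that of
#' bins `100-proximal_pct`..100 ("within 2% of the transcript length" at
#' the default). Groups are compared per end with a two-sided
#' Mann-Whitney U test.
#'
#' @param profiles_a,profiles_b Lists of profiles from
#'   [metagene_density()] (at least 2 per group).
#' @param proximal_pct Proximity margin in percent of transcript length.
#' @return Data frame with one row per end: median proximal densities
#'   and the Mann-Whitney p-value.
#' @export
tss_tts_enrichment_test <- function(profiles_a, profiles_b,
                                    proximal_pct = 2L) {
  if (length(profiles_a) < 2 || length(profiles_b) < 2) {
    stop("each group needs >= 2 profiles")
  }
  prox <- function(p, end) {
    idx <- if (end == "TSS") seq_len(proximal_pct + 1L)
           else length(p$density) - proximal_pct:0
    sum(p$density[idx])
  }
  rows <- lapply(c("TSS", "TTS"), function(end) {
    xa <- vapply(profiles_a, prox, numeric(1), end = end)
    xb <- vapply(profiles_b, prox, numeric(1), end = end)
    wt <- stats::wilcox.test(xa, xb, exact = FALSE)
    data.frame(end = end, median_a = stats::median(xa),
               median_b = stats::median(xb), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
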