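# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

## two-exon '+' gene: exons [100,200) and [400,600); CDS [150,500)
tiny_gene_plus <- function() {
  gene_model("gplus", "chr1", "+", 100L, 600L,
             exons = rbind(c(100L, 200L), c(400L, 600L)),
             utr5 = rbind(c(100L, 150L)),
             cds = rbind(c(150L, 200L), c(400L, 500L)),
             utr3 = rbind(c(500L, 600L)))
}

## same structure mirrored onto the '-' strand
tiny_gene_minus <- function() {
  gene_model("gminus", "chr1", "-", 100L, 600L,
             exons = rbind(c(100L, 200L), c(400L, 600L)),
             utr5 = rbind(c(500L, 600L)),
             cds = rbind(c(150L, 200L), c(400L, 500L)),
             utr3 = rbind(c(100L, 150L)))
}

window_at <- function(start, end, chrom = "chr1", gene_id = "g") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), gene_id = gene_id, score = 0,
             strand = "+", odds_ratio = 10, fdr = 0.01,
             stringsAsFactors = FALSE)
}

## exhaustive one-sided Fisher p by enumerating hypergeometric outcomes
enumerate_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  mass <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  sum(mass[xs >= a])
}

## brute-force alignment oracle: enumerate every (offset, mismatch)
## alignment of a k-mer pair and apply the category priority list
oracle_align <- function(kmer, anchor) {
  k <- nchar(anchor)
  cats <- c("exact", "1mm", "1off", "1off1mm", "2mm")
  cands <- list()
  for (off in c(-1L, 0L, 1L)) {
    idx <- seq_len(k)
    ## candidate position i sits over anchor position i + off
    pair <- idx[idx + off >= 1 & idx + off <= k]
    a_chars <- strsplit(anchor, "")[[1]][pair + off]
    c_chars <- strsplit(kmer, "")[[1]][pair]
    mm <- sum(a_chars != c_chars)
    cat <- if (off == 0 && mm == 0) "exact"
      else if (off == 0 && mm == 1) "1mm"
      else if (off == 0 && mm == 2) "2mm"
      else if (off != 0 && mm == 0) "1off"
      else if (off != 0 && mm == 1) "1off1mm"
      else NA
    if (!is.na(cat)) {
      cands[[length(cands) + 1]] <- list(offset = off, n_mismatch = mm,
                                         category = cat)
    }
  }
  if (length(cands) == 0) return(NULL)
  keys <- vapply(cands, function(x) {
    c(match(x$category, cats), abs(x$offset), as.integer(x$offset > 0))
  }, numeric(3))
  cands[[order(keys[1, ], keys[2, ], keys[3, ])[1]]]
}

random_kmer <- function(k = 5) {
  paste(sample(c("A", "C", "G", "U"), k, replace = TRUE), collapse = "")
}

## brute-force per-position ARM recount
oracle_arm <- function(sequence, window = 5, min_frac = 0.5, edge_skip = 2) {
  L <- nchar(sequence)
  aa <- strsplit(toupper(sequence), "")[[1]]
  half <- window %/% 2
  out <- integer(0)
  for (c0 in 0:(L - 1)) {
    if (c0 < edge_skip || c0 > L - 1 - edge_skip) next
    lo <- c0 - half; hi <- c0 + half
    if (lo < 0 || hi > L - 1) next
    if (sum(aa[(lo:hi) + 1] %in% c("K", "R")) > min_frac * window) {
      out <- c(out, c0)
    }
  }
  out
}

mk_series <- function(cpm_by_rep_t, library_total = 4e5, gene = "g1",
                      condition = "control") {
  ## cpm_by_rep_t: matrix reps x timepoints of CPM values
  tps <- c(0, 2, 4, 8)
  rows <- expand.grid(rep = seq_len(nrow(cpm_by_rep_t)),
                      ti = seq_along(tps))
  data.frame(gene_id = gene, condition = condition,
             timepoint_h = tps[rows$ti], replicate = rows$rep,
             tc_conversions = cpm_by_rep_t[cbind(rows$rep, rows$ti)] *
               library_total / 1e6,
             library_total = library_total, stringsAsFactors = FALSE)
}
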