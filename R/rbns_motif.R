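# RBNS motif derivation: k-mer counting, pulldown/input enrichment,
# priority-ordered alignment of top k-mers to the most enriched k-mer,
# and the enrichment-weighted position matrix with edge trimming.

#' Count k-mers in a read pool with a sliding window
#'
#' Every read of length L contributes L - k + 1 windows over its full
#' sequence (constant flanks included if present in the records). Reads
#' containing symbols outside A/C/G/U/T are skipped and tallied; T is
#' read as U.
#'
#' @param reads Character vector of sequences.
#' @param k Word size (default 5).
#' @return Named integer vector of counts over the RNA alphabet, with the
#'   number of skipped reads as attribute `n_skipped`.
#' @export
count_kmers <- function(reads, k = 5L) {
  if (k <= 0) stop("k must be positive")
  reads <- chartr("T", "U", toupper(reads))
  valid <- !grepl("[^ACGU]", reads) & nchar(reads) >= k
  n_skipped <- sum(grepl("[^ACGU]", reads))
  reads <- reads[valid]
  if (length(reads) == 0) {
    return(structure(stats::setNames(integer(0), character(0)),
                     n_skipped = n_skipped))
  }
  max_start <- max(nchar(reads)) - k + 1L
  kmers <- unlist(lapply(seq_len(max_start), function(j) {
    s <- substr(reads, j, j + k - 1L)
    s[nchar(s) == k]
  }), use.names = FALSE)
  tab <- table(kmers)
  structure(stats::setNames(as.integer(tab), names(tab)),
            n_skipped = n_skipped)
}

#' k-mer enrichment between pulldown and input pools
#'
#' Frequencies are computed over the union of observed k-mers after
#' adding `pseudocount` to every count, and enrichment is
#' `R = freq_pulldown / freq_input`. The table is sorted by R descending,
#' ties broken lexicographically.
#'
#' @param counts_pd,counts_in Named count vectors from [count_kmers()].
#' @param pseudocount Added to every count before frequencies (keeps R
#'   finite for k-mers unseen in one pool).
#' @return Data frame `kmer, count_pd, count_in, freq_pd, freq_in, R`.
#' @export
kmer_enrichment <- function(counts_pd, counts_in, pseudocount = 1) {
  ks <- unique(c(names(counts_pd), names(counts_in)))
  if (length(ks) > 1 && length(unique(nchar(ks))) != 1) {
    stop("mismatched k between pools")
  }
  ks <- sort(ks)
  lookup <- function(counts) {
    v <- unname(counts[match(ks, names(counts))])
    v[is.na(v)] <- 0L
    v
  }
  pd <- lookup(counts_pd) + pseudocount
  ins <- lookup(counts_in) + pseudocount
  freq_pd <- pd / sum(pd)
  freq_in <- ins / sum(ins)
  df <- data.frame(kmer = ks, count_pd = pd - pseudocount,
                   count_in = ins - pseudocount,
                   freq_pd = as.numeric(freq_pd),
                   freq_in = as.numeric(freq_in),
                   R = as.numeric(freq_pd / freq_in),
                   stringsAsFactors = FALSE)
  df[order(-df$R, df$kmer), , drop = FALSE]
}

## All candidate alignments of `kmer` to `anchor` within the allowed
## budget: offset in {-1, 0, +1}, category per (offset, mismatches).
## Returns NULL when no category admits the pair.
ALIGN_CATEGORIES <- c("exact", "1mm", "1off", "1off1mm", "2mm")

align_one_kmer <- function(kmer, anchor) {
  stopifnot(nchar(kmer) == nchar(anchor))
  k <- nchar(anchor)
  cands <- list()
  for (off in c(0L, -1L, 1L)) {
    if (off == 0L) {
      mm <- sum(strsplit(kmer, "")[[1]] != strsplit(anchor, "")[[1]])
      cat <- if (mm == 0) "exact" else if (mm == 1) "1mm"
             else if (mm == 2) "2mm" else NA
    } else {
      ## candidate shifted by off relative to anchor; overlap of k-1 bases
      a_part <- if (off > 0) substr(anchor, 1 + off, k)
                else substr(anchor, 1, k + off)
      c_part <- if (off > 0) substr(kmer, 1, k - off)
                else substr(kmer, 1 - off, k)
      mm <- sum(strsplit(a_part, "")[[1]] != strsplit(c_part, "")[[1]])
      cat <- if (mm == 0) "1off" else if (mm == 1) "1off1mm" else NA
    }
    if (!is.na(cat)) {
      cands[[length(cands) + 1]] <- list(offset = off, n_mismatch = mm,
                                         category = cat)
    }
  }
  if (length(cands) == 0) return(NULL)
  ## priority: category order, then smaller |offset|, then negative offset
  rank <- vapply(cands, function(x) {
    match(x$category, ALIGN_CATEGORIES) * 100 + abs(x$offset) * 10 +
      (x$offset > 0)
  }, numeric(1))
  cands[[which.min(rank)]]
}

#' Align top enriched k-mers to the most enriched k-mer
#'
#' The most enriched k-mer anchors the first group; each remaining k-mer
#' of the top `top_n` is assigned its best alignment to the anchor under
#' the priority exact > 1 mismatch > 1 offset > 1 offset + 1 mismatch >
#' 2 mismatches (offset magnitude at most 1; within a category the
#' smaller |offset| and then the negative offset wins). K-mers admitting
#' no category seed a new group, recursively.
#'
#' @param enrichment Data frame from [kmer_enrichment()] (sorted by R).
#' @param top_n How many top k-mers to align (default 20).
#' @return List of groups; each group has `anchor` and `members`, a data
#'   frame `kmer, R, offset, n_mismatch, category` (the anchor is a member
#'   with category `"exact"`, offset 0).
#' @export
align_top_kmers <- function(enrichment, top_n = 20L) {
  if (top_n < 2) stop("top_n must be >= 2")
  top <- utils::head(enrichment, top_n)
  groups <- list()
  pending <- top
  while (nrow(pending) > 0) {
    anchor <- pending$kmer[1]
    members <- data.frame(kmer = anchor, R = pending$R[1], offset = 0L,
                          n_mismatch = 0L, category = "exact",
                          stringsAsFactors = FALSE)
    rejected <- pending[0, ]
    for (i in seq_len(nrow(pending))[-1]) {
      al <- align_one_kmer(pending$kmer[i], anchor)
      if (is.null(al)) {
        rejected <- rbind(rejected, pending[i, ])
      } else {
        members <- rbind(members, data.frame(
          kmer = pending$kmer[i], R = pending$R[i], offset = al$offset,
          n_mismatch = al$n_mismatch, category = al$category,
          stringsAsFactors = FALSE))
      }
    }
    groups[[length(groups) + 1]] <- list(anchor = anchor, members = members)
    pending <- rejected
  }
  groups
}

#' Build the enrichment-weighted position matrix for an aligned group
#'
#' Each aligned k-mer adds its enrichment R to the matching base at every
#' position it covers (anchor positions 1..k; a k-mer at offset o covers
#' 1+o..k+o). Edge columns whose total weight (support) falls below
#' `trim_frac` times the maximum column support are trimmed iteratively
#' from both ends; interior columns are never removed.
#'
#' @param group One group from [align_top_kmers()].
#' @param trim_frac Edge-trimming threshold as a fraction of the maximum
#'   column support.
#' @return List of class `weighted_pwm`: `weights` (4 x m matrix, rows
#'   A/C/G/U, raw R sums), `probs` (column-normalized), `support`
#'   (per-column totals), `consensus` and `offsets` (retained column
#'   positions relative to the anchor start).
#' @export
build_weighted_pwm <- function(group, trim_frac = 0.25) {
  members <- group$members
  if (NROW(members) == 0) stop("empty group")
  k <- nchar(group$anchor)
  lo <- min(members$offset); hi <- max(members$offset) + k - 1L
  ncol_full <- hi - lo + 1L
  letters4 <- c("A", "C", "G", "U")
  w <- matrix(0, nrow = 4, ncol = ncol_full,
              dimnames = list(letters4, NULL))
  for (i in seq_len(nrow(members))) {
    chars <- strsplit(members$kmer[i], "")[[1]]
    cols <- members$offset[i] - lo + seq_len(k)
    for (j in seq_len(k)) {
      w[chars[j], cols[j]] <- w[chars[j], cols[j]] + members$R[i]
    }
  }
  support <- colSums(w)
  keep <- seq_len(ncol_full)
  thr <- function() trim_frac * max(support[keep])
  repeat {
    if (length(keep) == 0) stop("all columns trimmed: degenerate group")
    if (support[keep[1]] < thr()) { keep <- keep[-1]; next }
    if (support[keep[length(keep)]] < thr()) {
      keep <- keep[-length(keep)]; next
    }
    break
  }
  w <- w[, keep, drop = FALSE]
  support <- support[keep]
  probs <- sweep(w, 2, support, "/")
  structure(list(weights = w, probs = probs, support = support,
                 consensus = paste(letters4[apply(w, 2, which.max)],
                                   collapse = ""),
                 offsets = keep + lo - 1L),
            class = "weighted_pwm")
}

#' @export
print.weighted_pwm <- function(x, ...) {
  cat("<weighted_pwm> consensus", x$consensus, "over", ncol(x$weights),
      "positions\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Full RBNS motif workflow
#'
#' Counts k-mers in both pools, computes enrichment, aligns the top
#' k-mers and builds one weighted position matrix per alignment group.
#'
#' @param pulldown,input Character vectors of reads (or FASTA paths).
#' @param k Word size.
#' @param top_n Top k-mers aligned.
#' @param pseudocount,trim_frac Passed through.
#' @return List with `enrichment`, `groups`, `pwms`.
#' @export
rbns_motifs <- function(pulldown, input, k = 5L, top_n = 20L,
                        pseudocount = 1, trim_frac = 0.25) {
  if (length(pulldown) == 1 && file.exists(pulldown)) {
    pulldown <- read_pool(pulldown)
  }
  if (length(input) == 1 && file.exists(input)) input <- read_pool(input)
  enr <- kmer_enrichment(count_kmers(pulldown, k), count_kmers(input, k),
                         pseudocount)
  groups <- align_top_kmers(enr, top_n)
  pwms <- lapply(groups, build_weighted_pwm, trim_frac = trim_frac)
  list(enrichment = enr, groups = groups, pwms = pwms)
}
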