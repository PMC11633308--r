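# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of (cfg, its own arguments): the RNG
# stream is derived from the master seed and a stable per-generator label,
# so adding or re-ordering generators never perturbs another's output, and
# the caller's RNG state is untouched.

#' Simulation configuration
#'
#' @param seed Master integer seed; every generator derives its own stream
#'   from it, so a fixed seed gives byte-identical outputs.
#' @param n_genes Number of genes for [make_annotation()].
#' @param gene_length_range Two-element bp range for simulated gene lengths.
#' @param n_exons_range Two-element range for exon counts per gene.
#' @param noncoding_frac Fraction of genes emitted without a CDS.
#' @param n_chroms Number of chromosomes genes are spread over.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 100L,
                       gene_length_range = c(2000L, 10000L),
                       n_exons_range = c(1L, 10L),
                       noncoding_frac = 0.1, n_chroms = 4L) {
  stopifnot(n_genes >= 1, length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2])
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 n_exons_range = as.integer(n_exons_range),
                 noncoding_frac = noncoding_frac,
                 n_chroms = as.integer(n_chroms)),
            class = "sim_config")
}

## Stable 31-bit stream seed from (seed, label); arithmetic kept below 2^53
## so it is exact in doubles on every platform.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

with_gen_seed <- function(cfg, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(cfg$seed, label))
  expr
}

# ---- annotation -------------------------------------------------------------

#' Simulate a gene annotation
#'
#' Generates `cfg$n_genes` non-overlapping genes laid out along
#' `cfg$n_chroms` chromosomes, on both strands, with 1-10 exons each
#' (minimum exon and intron size 30 bp) and a 5'UTR/CDS/3'UTR partition of
#' exonic space in transcript order (roughly 15/60/25 percent). A
#' `noncoding_frac` fraction of genes carries no CDS.
#'
#' @param cfg A [sim_config()].
#' @param path Optional path: when given, the annotation is also written as
#'   BED12.
#' @return Named list of [gene_model()] objects.
#' @export
make_annotation <- function(cfg, path = NULL) {
  min_exon <- 30L; min_intron <- 30L
  need <- function(n) n * min_exon + (n - 1L) * min_intron
  if (need(cfg$n_exons_range[1]) > cfg$gene_length_range[2]) {
    stop("gene_length_range too small to host ", cfg$n_exons_range[1],
         " exons (need >= ", need(cfg$n_exons_range[1]), " bp)")
  }
  genes <- with_gen_seed(cfg, "annotation", {
    cursor <- stats::setNames(rep(1000L, cfg$n_chroms),
                              paste0("chr", seq_len(cfg$n_chroms)))
    lapply(seq_len(cfg$n_genes), function(i) {
      len <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), 1)
      feas <- cfg$n_exons_range[1]:cfg$n_exons_range[2]
      feas <- feas[need(feas) <= len]
      n_ex <- if (length(feas) == 1) feas else sample(feas, 1)
      ex <- random_gene_structure(len, n_ex, min_exon, min_intron)
      chrom <- paste0("chr", 1L + (i - 1L) %% cfg$n_chroms)
      start <- cursor[[chrom]]
      cursor[[chrom]] <<- start + len + sample(500:2000, 1)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      coding <- stats::runif(1) >= cfg$noncoding_frac
      exons <- cbind(start + ex$exon_starts, start + ex$exon_ends)
      parts <- if (coding) partition_exonic_space(exons, strand)
               else list(utr5 = NULL, cds = NULL, utr3 = NULL)
      gene_model(gene_id = sprintf("G%04d", i), chrom = chrom,
                 strand = strand, start = start, end = start + len,
                 exons = exons, utr5 = parts$utr5, cds = parts$cds,
                 utr3 = parts$utr3)
    })
  })
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  if (!is.null(path)) write_annotation_bed12(genes, path)
  genes
}

## exon/intron layout for one gene of total length len (gene-local coords)
random_gene_structure <- function(len, n_ex, min_exon, min_intron) {
  extra <- len - n_ex * min_exon - (n_ex - 1L) * min_intron
  w <- stats::runif(2L * n_ex - 1L)
  add <- floor(w / sum(w) * extra)
  add[1] <- add[1] + (extra - sum(add))   # absorb rounding remainder
  sizes <- rep(c(min_exon, min_intron), length.out = 2L * n_ex - 1L) + add
  bounds <- cumsum(c(0L, sizes))
  idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
  list(exon_starts = bounds[idx], exon_ends = bounds[idx + 1L])
}

## split exonic space ~15/60/25 in transcript order (strand-aware)
partition_exonic_space <- function(exons, strand) {
  total <- sum(exons[, 2] - exons[, 1])
  if (total < 3) stop("gene too short to partition exonic space")
  u5 <- max(1L, as.integer(round(0.15 * total)))
  u3 <- max(1L, as.integer(round(0.25 * total)))
  cds_len <- total - u5 - u3
  tx_slice <- function(from, to) transcript_to_genomic(exons, strand, from, to)
  list(utr5 = tx_slice(0L, u5),
       cds = tx_slice(u5, u5 + cds_len),
       utr3 = tx_slice(u5 + cds_len, total))
}

## map a half-open transcript-coordinate slice to genomic exon fragments
transcript_to_genomic <- function(exons, strand, from, to) {
  ex <- if (strand == "+") exons else exons[rev(seq_len(nrow(exons))), ,
                                            drop = FALSE]
  out <- NULL; pos <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2] - ex[i, 1]
    lo <- max(from - pos, 0L); hi <- min(to - pos, w)
    if (lo < hi) {
      piece <- if (strand == "+") c(ex[i, 1] + lo, ex[i, 1] + hi)
               else c(ex[i, 2] - hi, ex[i, 2] - lo)
      out <- rbind(out, piece)
    }
    pos <- pos + w
  }
  if (is.null(out)) return(NULL)
  out[order(out[, 1]), , drop = FALSE]
}

# ---- binding (eCLIP windows + Cut&Run peaks) --------------------------------

#' Simulate eCLIP enriched windows and Cut&Run peaks with planted structure
#'
#' RNA windows are placed by midpoint over genic space. With
#' `planted_or > 1`, the odds of a window midpoint landing in
#' `planted_feature` space versus other genic space are multiplied by
#' `planted_or` relative to a length-uniform background (which is also
#' emitted, for enrichment testing). With `planted_tss_bias != 1`, window
#' positions are instead drawn along percent-of-transcript-length with a
#' `planted_tss_bias`-fold density on the first 3% of the transcript. DNA
#' peaks are placed within 1 kb of a random TSS with probability
#' `tss_peak_frac` and uniformly on the chromosome otherwise.
#'
#' @param cfg A [sim_config()].
#' @param genes Annotation from [make_annotation()].
#' @param planted_feature Containment feature class to enrich
#'   (`"5'UTR"`, `"CDS"`, `"3'UTR"`, `"intron"`, `"noncoding"`).
#' @param planted_or Odds multiplier (>= 1) for the planted feature.
#' @param planted_tss_bias Density multiplier for the TSS-proximal 3% of
#'   transcript length.
#' @param n_windows,n_background,n_peaks Output sizes.
#' @param window_width Window width in bp.
#' @param tss_peak_frac Fraction of DNA peaks planted TSS-proximal.
#' @return List with `windows`, `background` (both `enriched_windows`
#'   frames), `peaks` (`dna_peaks` frame) and `ground_truth`.
#' @export
simulate_binding <- function(cfg, genes, planted_feature = "3'UTR",
                             planted_or = 1, planted_tss_bias = 1,
                             n_windows = 2000L, n_background = 2000L,
                             n_peaks = 500L, window_width = 50L,
                             tss_peak_frac = 0.5) {
  if (planted_or < 1) stop("planted_or must be >= 1")
  spaces <- feature_spaces(genes, planted_feature)
  if (sum(spaces$in_len) == 0) {
    stop("planted_feature '", planted_feature, "' absent from annotation")
  }
  with_gen_seed(cfg, "binding", {
    draw_windows <- function(n, weight) {
      if (planted_tss_bias != 1) {
        mids <- draw_tss_biased(genes, n, planted_tss_bias)
      } else {
        mids <- draw_feature_weighted(spaces, n, weight)
      }
      data.frame(chrom = mids$chrom, start = mids$mid - window_width %/% 2L,
                 end = mids$mid - window_width %/% 2L + window_width,
                 gene_id = mids$gene_id, score = 0L, strand = mids$strand,
                 odds_ratio = round(8 + stats::rexp(n, 1), 3),
                 fdr = round(stats::runif(n, 0, 0.049), 5),
                 stringsAsFactors = FALSE)
    }
    windows <- draw_windows(n_windows, planted_or)
    background <- draw_windows(n_background, 1)
    class(windows) <- class(background) <- c("enriched_windows", "data.frame")
    peaks <- draw_dna_peaks(genes, n_peaks, tss_peak_frac)
    list(windows = windows, background = background, peaks = peaks,
         ground_truth = list(planted_feature = planted_feature,
                             planted_or = planted_or,
                             planted_tss_bias = planted_tss_bias,
                             in_len = sum(spaces$in_len),
                             out_len = sum(spaces$out_len),
                             tss_peak_frac = tss_peak_frac))
  })
}

## per-gene bp space inside/outside the planted containment feature
feature_spaces <- function(genes, feature) {
  per_gene <- lapply(genes, function(g) {
    iv <- containment_intervals(g)
    inside <- iv[[feature]]
    all_iv <- do.call(rbind, iv)
    in_len <- if (is.null(inside)) 0L else sum(inside[, 2] - inside[, 1])
    list(gene = g, inside = inside,
         outside = setdiff_intervals(cbind(g$start, g$end), inside),
         in_len = in_len,
         out_len = (g$end - g$start) - in_len)
  })
  list(per_gene = per_gene,
       in_len = vapply(per_gene, `[[`, numeric(1), "in_len"),
       out_len = vapply(per_gene, `[[`, numeric(1), "out_len"))
}

## containment feature intervals for a gene (no splice-site classes)
containment_intervals <- function(g) {
  introns <- setdiff_intervals(cbind(g$start, g$end), g$exons)
  if (is.null(g$cds) || nrow(g$cds) == 0) {
    list(`5'UTR` = NULL, CDS = NULL, `3'UTR` = NULL, intron = introns,
         noncoding = g$exons)
  } else {
    list(`5'UTR` = g$utr5, CDS = g$cds, `3'UTR` = g$utr3, intron = introns,
         noncoding = NULL)
  }
}

setdiff_intervals <- function(span, sub) {
  if (is.null(sub) || nrow(sub) == 0) return(span)
  out <- NULL; pos <- span[1, 1]
  sub <- sub[order(sub[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub[i, 1] > pos) out <- rbind(out, c(pos, sub[i, 1]))
    pos <- max(pos, sub[i, 2])
  }
  if (pos < span[1, 2]) out <- rbind(out, c(pos, span[1, 2]))
  out
}

draw_feature_weighted <- function(spaces, n, weight) {
  in_tot <- sum(spaces$in_len); out_tot <- sum(spaces$out_len)
  p_in <- weight * in_tot / (weight * in_tot + out_tot)
  inside <- stats::runif(n) < p_in
  pick <- function(lens, ivs_field, m) {
    gi <- sample.int(length(lens), m, replace = TRUE, prob = lens)
    mids <- vapply(gi, function(j) {
      ivs <- spaces$per_gene[[j]][[ivs_field]]
      w <- ivs[, 2] - ivs[, 1]
      k <- if (nrow(ivs) == 1) 1L else sample.int(nrow(ivs), 1, prob = w)
      as.integer(ivs[k, 1] + sample.int(ivs[k, 2] - ivs[k, 1], 1) - 1L)
    }, integer(1))
    list(mid = mids, g = gi)
  }
  mid <- integer(n); gidx <- integer(n)
  if (any(inside)) {
    res_in <- pick(spaces$in_len, "inside", sum(inside))
    mid[inside] <- res_in$mid; gidx[inside] <- res_in$g
  }
  if (any(!inside)) {
    res_out <- pick(spaces$out_len, "outside", sum(!inside))
    mid[!inside] <- res_out$mid; gidx[!inside] <- res_out$g
  }
  gl <- spaces$per_gene[gidx]
  list(mid = mid,
       chrom = vapply(gl, function(x) x$gene$chrom, ""),
       strand = vapply(gl, function(x) x$gene$strand, ""),
       gene_id = vapply(gl, function(x) x$gene$gene_id, ""))
}

draw_tss_biased <- function(genes, n, bias, prox = 0.03) {
  lens <- vapply(genes, function(g) g$end - g$start, numeric(1))
  gi <- sample.int(length(genes), n, replace = TRUE, prob = lens)
  p_prox <- bias * prox / (bias * prox + (1 - prox))
  u <- ifelse(stats::runif(n) < p_prox,
              stats::runif(n, 0, prox), stats::runif(n, prox, 1))
  g <- genes[gi]
  mid <- vapply(seq_len(n), function(i) {
    gg <- g[[i]]
    if (gg$strand == "+") as.integer(gg$start + floor(u[i] * (gg$end - gg$start)))
    else as.integer(gg$end - 1L - floor(u[i] * (gg$end - gg$start)))
  }, integer(1))
  list(mid = mid, chrom = vapply(g, `[[`, "", "chrom"),
       strand = vapply(g, `[[`, "", "strand"),
       gene_id = vapply(g, `[[`, "", "gene_id"))
}

draw_dna_peaks <- function(genes, n, tss_frac) {
  chrom_ends <- tapply(vapply(genes, `[[`, 0L, "end"),
                       vapply(genes, `[[`, "", "chrom"), max)
  near_tss <- stats::runif(n) < tss_frac
  gi <- sample.int(length(genes), n, replace = TRUE)
  width <- 200L
  start <- integer(n); chrom <- character(n)
  for (i in seq_len(n)) {
    if (near_tss[i]) {
      g <- genes[[gi[i]]]
      center <- g$tss + sample(-1000:1000, 1)
      start[i] <- max(0L, as.integer(center) - width %/% 2L)
      chrom[i] <- g$chrom
    } else {
      chrom[i] <- sample(names(chrom_ends), 1)
      start[i] <- sample.int(max(chrom_ends[[chrom[i]]] + 50000L - width, 1L), 1)
    }
  }
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   name = sprintf("peak_%d", seq_len(n)),
                   score = round(stats::runif(n, 100, 1000)),
                   strand = ".",
                   signal = round(stats::runif(n, 1, 20), 3),
                   pvalue = round(stats::runif(n, 2, 30), 3),
                   qvalue = round(stats::runif(n, 2, 30), 3),
                   summit_offset = width %/% 2L,
                   stringsAsFactors = FALSE)
  df$planted_tss <- near_tss
  class(df) <- c("dna_peaks", "data.frame")
  df
}

# ---- knockdown differential tables ------------------------------------------

#' Simulate knockdown differential tables and significant-event counts
#'
#' For each ZFP dataset, true significant-event counts are Poisson around
#' the batch mean (inflated by `excess` for planted outliers), and
#' expression/splicing/APA tables are constructed so that the pipeline's
#' significance thresholds recover exactly those counts.
#'
#' @param cfg A [sim_config()].
#' @param batch_means Named numeric vector: mean significant-DEG count per
#'   batch (ASE/APAE means are scaled to 1/2 and 1/5 of it).
#' @param n_per_batch Datasets per batch.
#' @param outliers Optional data frame `(zfp_id, batch, excess)`: planted
#'   high-residual ZFPs with counts inflated by `1 + excess`.
#' @param n_genes Rows per differential table.
#' @param make_tables When `FALSE`, only the event-count matrix is built.
#' @return List with `counts` (event-count matrix), `tables` (per-ZFP list
#'   of `expr`/`splice`/`apa` frames) and `ground_truth`.
#' @export
simulate_kd_tables <- function(cfg, batch_means = c(A = 100, B = 1000),
                               n_per_batch = 8L, outliers = NULL,
                               n_genes = 2000L, make_tables = TRUE) {
  if (!is.null(outliers)) {
    if (any(outliers$excess <= -1)) stop("excess fraction must be > -1")
    bad <- setdiff(outliers$batch, names(batch_means))
    if (length(bad)) stop("unknown batch label in outlier map: ",
                          paste(bad, collapse = ", "))
  }
  with_gen_seed(cfg, "kd_tables", {
    grid <- do.call(rbind, lapply(names(batch_means), function(b) {
      data.frame(batch = b, idx = seq_len(n_per_batch),
                 stringsAsFactors = FALSE)
    }))
    grid$zfp_id <- sprintf("ZFP_%s%02d", grid$batch, grid$idx)
    if (!is.null(outliers) && is.null(outliers$zfp_id)) {
      stop("outliers must carry zfp_id")
    }
    mult <- rep(1, nrow(grid))
    if (!is.null(outliers)) {
      for (i in seq_len(nrow(outliers))) {
        j <- which(grid$batch == outliers$batch[i])[1]
        grid$zfp_id[j] <- outliers$zfp_id[i]
        mult[j] <- 1 + outliers$excess[i]
      }
    }
    mu <- batch_means[grid$batch]
    counts <- data.frame(zfp_id = grid$zfp_id, batch = grid$batch,
                         degs = stats::rpois(nrow(grid), mu * mult),
                         ases = stats::rpois(nrow(grid), mu * mult / 2),
                         apaes = stats::rpois(nrow(grid), mu * mult / 5),
                         stringsAsFactors = FALSE)
    tables <- NULL
    if (make_tables) {
      tables <- lapply(seq_len(nrow(counts)), function(i) {
        list(expr = make_expr_table(n_genes, counts$degs[i]),
             splice = make_splice_table(n_genes, counts$ases[i]),
             apa = make_apa_table(n_genes, counts$apaes[i]))
      })
      names(tables) <- counts$zfp_id
    }
    list(counts = counts, tables = tables,
         ground_truth = list(
           batch_means = batch_means, outliers = outliers,
           planted_multiplier = stats::setNames(mult, grid$zfp_id)))
  })
}

make_expr_table <- function(n_genes, n_sig) {
  stopifnot(n_sig <= n_genes)
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  sig <- sample.int(n_genes, n_sig)
  fdr <- stats::runif(n_genes, 0.05, 1)
  log2fc <- stats::rnorm(n_genes, 0, 0.1)
  fdr[sig] <- stats::runif(n_sig, 0, 0.049)
  log2fc[sig] <- sample(c(-1, 1), n_sig, TRUE) *
    (log2(1.2) + stats::rexp(n_sig, 2))
  na_idx <- sample(setdiff(seq_len(n_genes), sig),
                   min(5L, n_genes - n_sig))
  fdr[na_idx] <- NA
  data.frame(gene_id = gene_id, log2fc = log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

make_splice_table <- function(n_genes, n_sig) {
  n_ev <- max(n_genes, n_sig)
  gene_id <- sprintf("G%04d", sample.int(n_genes, n_ev, replace = TRUE))
  type <- sample(c("SE", "A5SS", "A3SS", "MXE", "RI"), n_ev, TRUE,
                 prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  anchor <- sample.int(100000L, n_ev, replace = TRUE)
  fdr <- stats::runif(n_ev, 0.05, 1)
  dpsi <- stats::runif(n_ev, -0.15, 0.15)
  sig <- sample.int(n_ev, n_sig)
  fdr[sig] <- stats::runif(n_sig, 0, 0.049)
  dpsi[sig] <- sample(c(-1, 1), n_sig, TRUE) * stats::runif(n_sig, 0.21, 0.8)
  df <- data.frame(event_id = sprintf("EV%05d", seq_len(n_ev)),
                   gene_id = gene_id, event_type = type,
                   junction_starts = paste(anchor, anchor + 150L, sep = ","),
                   delta_psi = dpsi, fdr = fdr, stringsAsFactors = FALSE)
  df$junction_coords <- lapply(seq_len(n_ev), function(i) {
    c(anchor[i], anchor[i] + 150L)
  })
  df
}

make_apa_table <- function(n_genes, n_sig) {
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  fdr <- stats::runif(n_genes, 0.05, 1)
  dpsi <- stats::runif(n_genes, -0.15, 0.15)
  sig <- sample.int(n_genes, n_sig)
  fdr[sig] <- stats::runif(n_sig, 0, 0.049)
  dpsi[sig] <- sample(c(-1, 1), n_sig, TRUE) * stats::runif(n_sig, 0.21, 0.8)
  data.frame(gene_id = gene_id, delta_psi = dpsi, fdr = fdr,
             stringsAsFactors = FALSE)
}

# ---- SLAM-seq ---------------------------------------------------------------

#' Simulate SLAM-seq T>C conversion counts for a decay time course
#'
#' Per gene and replicate, conversion counts at chase time `t` are
#' Poisson with mean `depth * 2^(-t / half_life)`. Library totals are
#' emitted so CPM filtering behaves as on real data: with the default
#' `library_total` of 4e5, a gene at depth 1000 sits at 2500 CPM at t=0.
#'
#' @param cfg A [sim_config()].
#' @param half_lives Named numeric vector of true half-lives (hours).
#' @param condition Condition label written into the table.
#' @param reps Number of replicates.
#' @param timepoints Chase timepoints in hours.
#' @param depth Expected conversions per gene at t=0 (scalar or named
#'   vector aligned with `half_lives`).
#' @param library_total Per-library total used as the CPM denominator.
#' @param noise `"poisson"` or `"none"` (deterministic expected counts).
#' @return List with `series` (long data frame in the `slam` table schema)
#'   and `ground_truth` (true half-lives and expected CPM-filter failures
#'   at the default CPM > 5 cutoff).
#' @export
simulate_slam <- function(cfg, half_lives, condition = "control", reps = 3L,
                          timepoints = c(0, 2, 4, 8), depth = 1000,
                          library_total = 4e5, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (any(half_lives <= 0)) stop("half_lives must be positive")
  if (any(depth <= 0)) stop("depth must be positive")
  if (reps < 1) stop("reps must be >= 1")
  depth <- rep_len(depth, length(half_lives))
  genes <- names(half_lives)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_along(half_lives))
  with_gen_seed(cfg, paste0("slam_", condition), {
    grid <- expand.grid(gene = seq_along(half_lives), t = timepoints,
                        rep = seq_len(reps))
    mu <- depth[grid$gene] * 2^(-grid$t / half_lives[grid$gene])
    counts <- if (noise == "poisson") stats::rpois(nrow(grid), mu) else mu
    series <- data.frame(gene_id = genes[grid$gene], condition = condition,
                         timepoint_h = grid$t, replicate = grid$rep,
                         tc_conversions = counts,
                         library_total = library_total,
                         stringsAsFactors = FALSE)
    expected_fail <- depth * 1e6 / library_total <= 5
    list(series = series,
         ground_truth = list(
           half_lives = stats::setNames(half_lives, genes),
           depth = stats::setNames(depth, genes),
           expected_filter_fail = stats::setNames(expected_fail, genes)))
  })
}

# ---- RBNS -------------------------------------------------------------------

#' Simulate RBNS pulldown and input read pools
#'
#' The input pool is uniform random sequence; in the pulldown pool a
#' `planted_fraction` of reads carries one draw from the planted motif
#' model at a uniformly chosen position.
#'
#' @param cfg A [sim_config()].
#' @param motif Consensus string (e.g. `"GAAGA"`) or a 4 x m probability
#'   matrix with rownames `A,C,G,U`.
#' @param planted_fraction Fraction of pulldown reads carrying the motif.
#' @param n_reads Reads per pool.
#' @param read_len Read length (nt).
#' @param consensus_prob Per-position probability of the consensus base
#'   when `motif` is given as a string.
#' @return List with `pulldown` and `input` character vectors (DNA
#'   alphabet, as sequenced) and `ground_truth`.
#' @export
simulate_rbns <- function(cfg, motif = "GAAGA", planted_fraction = 0.3,
                          n_reads = 50000L, read_len = 20L,
                          consensus_prob = 0.85) {
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("planted_fraction must be in [0,1]")
  }
  pwm <- if (is.character(motif)) consensus_to_pwm(motif, consensus_prob)
         else motif
  m <- ncol(pwm)
  if (m > read_len) stop("motif longer than read_len")
  bases <- c("A", "C", "G", "T")
  with_gen_seed(cfg, "rbns", {
    rand_pool <- function(n) {
      mat <- matrix(sample(bases, n * read_len, TRUE), nrow = n)
      apply(mat, 1, paste, collapse = "")
    }
    input <- rand_pool(n_reads)
    pulldown <- rand_pool(n_reads)
    planted <- which(stats::runif(n_reads) < planted_fraction)
    for (i in planted) {
      ins <- vapply(seq_len(m), function(j) {
        sample(bases, 1, prob = pwm[, j])
      }, "")
      pos <- sample.int(read_len - m + 1L, 1)
      substr(pulldown[i], pos, pos + m - 1L) <- paste(ins, collapse = "")
    }
    consensus <- paste(c("A", "C", "G", "U")[apply(pwm, 2, which.max)],
                       collapse = "")
    list(pulldown = pulldown, input = input,
         ground_truth = list(pwm = pwm, consensus = consensus,
                             planted_fraction = planted_fraction,
                             n_planted = length(planted)))
  })
}

consensus_to_pwm <- function(consensus, p = 0.85) {
  letters4 <- c("A", "C", "G", "U")
  cons <- chartr("T", "U", toupper(consensus))
  pwm <- matrix((1 - p) / 3, nrow = 4, ncol = nchar(cons),
                dimnames = list(letters4, NULL))
  for (j in seq_len(nchar(cons))) {
    pwm[substr(cons, j, j), j] <- p
  }
  pwm
}

#' Write a read pool as FASTA
#' @param reads Character vector of sequences.
#' @param path Output path.
#' @param prefix Record-name prefix.
#' @export
write_pool_fasta <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA/FASTQ read pool as plain sequences
#' @param path Input path.
#' @param format `"fasta"` or `"fastq"`.
#' @return Character vector of sequences.
#' @export
read_pool <- function(path, format = "fasta") {
  as.character(Biostrings::readDNAStringSet(path, format = format))
}

# ---- Ribo-STAMP EPR ---------------------------------------------------------

#' Simulate Ribo-STAMP edit and exon-read counts
#'
#' Two knockdown and two control samples per gene. Exon reads are Poisson
#' around `depth`; edits are Poisson around `epr * exon_reads` with a
#' per-sample lognormal factor (`noise_sd` on the log scale), and KD
#' samples have their edit rate multiplied by the planted ratio.
#'
#' @param cfg A [sim_config()].
#' @param n_genes Number of genes.
#' @param effect_genes Named numeric vector: planted KD/control EPR ratio
#'   for affected genes (others are 1).
#' @param reps Replicates per condition (>= 2; the differential test needs
#'   at least two).
#' @param depth Expected exon reads per gene and sample.
#' @param noise_sd Lognormal sd of the per-sample EPR factor.
#' @return List with `table` (long data frame in the `epr` schema) and
#'   `ground_truth`.
#' @export
simulate_epr <- function(cfg, n_genes = 500L, effect_genes = NULL, reps = 2L,
                         depth = 20000, noise_sd = 0.02) {
  if (reps < 2) stop("reps must be >= 2")
  if (!is.null(effect_genes) && any(effect_genes <= 0)) {
    stop("planted EPR ratios must be > 0")
  }
  with_gen_seed(cfg, "epr", {
    genes <- sprintf("G%04d", seq_len(n_genes))
    ratio <- stats::setNames(rep(1, n_genes), genes)
    if (!is.null(effect_genes)) ratio[names(effect_genes)] <- effect_genes
    base_epr <- stats::setNames(stats::runif(n_genes, 0.02, 0.1), genes)
    samples <- c(sprintf("KD_%d", seq_len(reps)),
                 sprintf("CTL_%d", seq_len(reps)))
    rows <- lapply(samples, function(s) {
      is_kd <- grepl("^KD", s)
      reads <- stats::rpois(n_genes, depth)
      lambda <- base_epr * (if (is_kd) ratio else 1) *
        stats::rlnorm(n_genes, 0, noise_sd) * reads
      data.frame(gene_id = genes, sample = s,
                 edits = stats::rpois(n_genes, lambda), exon_reads = reads,
                 stringsAsFactors = FALSE)
    })
    list(table = do.call(rbind, rows),
         ground_truth = list(ratio = ratio, base_epr = base_epr))
  })
}

# ---- tethering reporter -----------------------------------------------------

#' Simulate tethering-reporter luminescence wells
#'
#' Firefly and Renilla luminescence are lognormal around construct means;
#' planted constructs have their firefly/Renilla ratio multiplied by the
#' given fold change. A construct named `"control"` at fold 1 is always
#' included.
#'
#' @param cfg A [sim_config()].
#' @param effect_constructs Named numeric vector of planted fold changes.
#' @param n_null Number of additional no-effect constructs.
#' @param reps Wells per construct.
#' @param sdlog Lognormal sd of the well-to-well ratio noise.
#' @param reporter Reporter label (`"stability"`, `"splice_up"`,
#'   `"splice_down"`).
#' @return List with `wells` (data frame in the `tethering` schema) and
#'   `ground_truth`.
#' @export
simulate_tethering <- function(cfg, effect_constructs = NULL, n_null = 10L,
                               reps = 3L, sdlog = 0.1,
                               reporter = "stability") {
  if (reps < 2) stop("reps must be >= 2")
  if (!is.null(effect_constructs) && any(effect_constructs <= 0)) {
    stop("planted fold changes must be > 0")
  }
  with_gen_seed(cfg, paste0("tethering_", reporter), {
    folds <- c(control = 1,
               stats::setNames(rep(1, n_null), sprintf("NULL_%02d",
                                                       seq_len(n_null))),
               effect_constructs)
    rows <- lapply(names(folds), function(cid) {
      ff <- stats::rlnorm(reps, log(1000 * folds[[cid]]), sdlog)
      rr <- stats::rlnorm(reps, log(1000), sdlog)
      data.frame(construct_id = cid, replicate = seq_len(reps),
                 firefly = round(ff, 2), renilla = round(rr, 2),
                 reporter = reporter, stringsAsFactors = FALSE)
    })
    list(wells = do.call(rbind, rows),
         ground_truth = list(folds = folds))
  })
}

# ---- proteins ---------------------------------------------------------------

#' Simulate protein sequences with planted ARM loci and RBD/IDR tracks
#'
#' Background residues are drawn from the 18 non-K/R amino acids (plus K/R
#' at `background_kr_freq`), so planted arginine/lysine-rich loci are
#' exactly the positions satisfying the >0.5 K/R window rule when
#' `background_kr_freq = 0`. Occlusion Z is strictly below -1 on planted
#' RBD residues and at or above -1 elsewhere; disorder scores exceed 0.4
#' exactly on planted IDR residues.
#'
#' @param cfg A [sim_config()].
#' @param lengths Named integer vector of protein lengths.
#' @param planted_arm_runs Per-protein list of two-column matrices of
#'   half-open residue intervals to fill with K/R (each at least 3 long so
#'   its positions are ARM loci at the 5-aa window default).
#' @param planted_rbd Per-protein list of half-open intervals with
#'   occlusion Z < -1.
#' @param planted_idr Per-protein list of half-open intervals with
#'   disorder score > 0.4.
#' @param domains Optional data frame `(protein_id, class, start, end)`.
#' @param background_kr_freq Background K/R frequency.
#' @return List with `sequences` (named character vector), `tracks` (data
#'   frame in the `protein_tracks` schema), `domains` and `ground_truth`.
#' @export
simulate_proteins <- function(cfg, lengths, planted_arm_runs = list(),
                              planted_rbd = list(), planted_idr = list(),
                              domains = NULL, background_kr_freq = 0) {
  aa_bg <- setdiff(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], character(0))
  with_gen_seed(cfg, "proteins", {
    seqs <- character(length(lengths))
    names(seqs) <- names(lengths)
    tracks <- vector("list", length(lengths))
    for (i in seq_along(lengths)) {
      pid <- names(lengths)[i]; L <- lengths[[i]]
      aa <- sample(aa_bg, L, replace = TRUE)
      if (background_kr_freq > 0) {
        kr <- stats::runif(L) < background_kr_freq
        aa[kr] <- sample(c("K", "R"), sum(kr), TRUE)
      }
      for (iv in interval_rows(planted_arm_runs[[pid]])) {
        check_iv(iv, L, pid)
        aa[(iv[1] + 1):iv[2]] <- sample(c("K", "R"), iv[2] - iv[1], TRUE)
      }
      z <- pmax(stats::rnorm(L, 0.3, 0.5), -0.9)
      rbd_iv <- interval_rows(planted_rbd[[pid]])
      check_no_overlap(rbd_iv, pid)
      for (iv in rbd_iv) {
        check_iv(iv, L, pid)
        n <- iv[2] - iv[1]
        z[(iv[1] + 1):iv[2]] <- -1 - 0.1 - abs(stats::rnorm(n, 0.4, 0.3))
      }
      d <- stats::runif(L, 0, 0.4)
      for (iv in interval_rows(planted_idr[[pid]])) {
        check_iv(iv, L, pid)
        d[(iv[1] + 1):iv[2]] <- stats::runif(iv[2] - iv[1], 0.45, 0.95)
      }
      seqs[i] <- paste(aa, collapse = "")
      tracks[[i]] <- data.frame(protein_id = pid, position = seq_len(L) - 1L,
                                occlusion_z = round(z, 4),
                                disorder_score = round(d, 4),
                                stringsAsFactors = FALSE)
    }
    list(sequences = seqs, tracks = do.call(rbind, tracks),
         domains = domains,
         ground_truth = list(arm_runs = planted_arm_runs,
                             rbd = planted_rbd, idr = planted_idr))
  })
}

interval_rows <- function(m) {
  if (is.null(m) || length(m) == 0) return(list())
  m <- matrix(as.integer(m), ncol = 2)
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

check_iv <- function(iv, L, pid) {
  if (iv[1] < 0 || iv[2] > L || iv[1] >= iv[2]) {
    stop("planted interval [", iv[1], ",", iv[2], ") outside protein ", pid)
  }
}

check_no_overlap <- function(ivs, pid) {
  if (length(ivs) < 2) return(invisible())
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (any(m[-1, 1] < m[-nrow(m), 2])) {
    stop("overlapping contradictory plants for protein ", pid)
  }
}
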