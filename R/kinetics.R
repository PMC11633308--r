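# SLAM-seq decay kinetics (CPM filtering, first-order decay fits,
# half-life shift tests) and Ribo-STAMP edits-per-read statistics.

#' Filter SLAM-seq gene series by CPM and replicate support
#'
#' CPM is `tc_conversions * 1e6 / library_total`. A replicate passes for
#' a gene when its CPM exceeds `cpm_min` at every one of the four
#' timepoints; the gene is retained when at least `min_reps` replicates
#' pass, and only those replicates are kept. Genes missing a timepoint
#' are dropped and tallied.
#'
#' @param series Long data frame in the `slam` schema (one condition).
#' @param cpm_min CPM threshold (strict >).
#' @param min_reps Minimum passing replicates.
#' @param timepoints Required timepoints (hours).
#' @return List with `series` (retained rows), `retained` (data frame of
#'   gene, n_reps), `n_dropped_incomplete`.
#' @export
filter_slam_genes <- function(series, cpm_min = 5, min_reps = 2L,
                              timepoints = c(0, 2, 4, 8)) {
  series$cpm <- series$tc_conversions * 1e6 / series$library_total
  keep_rows <- logical(nrow(series))
  retained <- list()
  n_incomplete <- 0L
  for (gid in unique(series$gene_id)) {
    rows <- which(series$gene_id == gid)
    sub <- series[rows, , drop = FALSE]
    pass_reps <- c()
    complete <- TRUE
    for (r in unique(sub$replicate)) {
      rr <- sub[sub$replicate == r, , drop = FALSE]
      if (!all(timepoints %in% rr$timepoint_h)) { complete <- FALSE; next }
      if (all(vapply(timepoints, function(t) {
        any(rr$timepoint_h == t & rr$cpm > cpm_min)
      }, logical(1)))) {
        pass_reps <- c(pass_reps, r)
      }
    }
    if (!complete && length(pass_reps) < min_reps) {
      n_incomplete <- n_incomplete + 1L
      next
    }
    if (length(pass_reps) >= min_reps) {
      keep_rows[rows] <- series$replicate[rows] %in% pass_reps
      retained[[length(retained) + 1]] <- data.frame(
        gene_id = gid, n_reps = length(pass_reps), stringsAsFactors = FALSE)
    }
  }
  if (n_incomplete > 0) warning(n_incomplete,
                                " gene(s) with missing timepoints dropped")
  list(series = series[keep_rows, , drop = FALSE],
       retained = if (length(retained)) do.call(rbind, retained) else
         data.frame(gene_id = character(0), n_reps = integer(0)),
       n_dropped_incomplete = n_incomplete)
}

## sum of squares of (y - exp(-k t)); 1-D objective for the decay fit
decay_ss <- function(k, t, y) sum((y - exp(-k * t))^2)

#' Fit a first-order decay to a filtered SLAM-seq gene series
#'
#' Conversion counts are averaged over retained replicates per timepoint
#' and normalized to the t=0 mean; `y(t) = exp(-k t)` is then fitted by
#' least squares on the normalized points (the t=0 point, fixed at 1, is
#' included). `half_life = ln 2 / k`; `r_squared` is computed on the
#' normalized points; a fit passes when R^2 > 0.6 and k is positive.
#'
#' @param series Retained rows for one condition (several genes fine).
#' @param r2_min R-squared threshold for `passed`.
#' @param k_tol Positivity tolerance on k.
#' @return Data frame, one row per gene: `k`, `half_life`, `r_squared`,
#'   `passed`, `reason`.
#' @export
fit_decay <- function(series, r2_min = 0.6, k_tol = 1e-8) {
  rows <- lapply(unique(series$gene_id), function(gid) {
    sub <- series[series$gene_id == gid, , drop = FALSE]
    m <- tapply(sub$tc_conversions, sub$timepoint_h, mean)
    t <- as.numeric(names(m)); y <- as.numeric(m)
    o <- order(t); t <- t[o]; y <- y[o]
    if (t[1] != 0 || y[1] <= 0) {
      return(data.frame(gene_id = gid, condition = sub$condition[1],
                        k = NA_real_, half_life = NA_real_,
                        r_squared = NA_real_, passed = FALSE,
                        reason = "no t0 signal", stringsAsFactors = FALSE))
    }
    y <- y / y[1]
    opt <- stats::optimize(decay_ss, interval = c(-2, 50), t = t, y = y,
                           tol = 1e-12)
    k <- opt$minimum
    ss_res <- opt$objective
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    pos <- k > k_tol
    passed <- pos && !is.na(r2) && r2 > r2_min
    data.frame(gene_id = gid, condition = sub$condition[1], k = k,
               half_life = if (pos) log(2) / k else NA_real_,
               r_squared = r2, passed = passed,
               reason = if (passed) "" else if (!pos) "k <= 0"
                        else "low r_squared",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convenience wrapper: filter then fit one condition
#' @inheritParams filter_slam_genes
#' @inheritParams fit_decay
#' @return The [fit_decay()] frame for retained genes.
#' @export
slam_half_lives <- function(series, cpm_min = 5, min_reps = 2L,
                            r2_min = 0.6) {
  filt <- filter_slam_genes(series, cpm_min, min_reps)
  if (nrow(filt$series) == 0) {
    return(data.frame(gene_id = character(0), condition = character(0),
                      k = numeric(0), half_life = numeric(0),
                      r_squared = numeric(0), passed = logical(0),
                      reason = character(0)))
  }
  fit_decay(filt$series, r2_min)
}

#' Half-life shift test between knockdown and control
#'
#' Compares half-lives of passed fits for binding-target genes between
#' knockdown and control with a two-sided Mann-Whitney U test, and
#' reports the same test restricted to non-target genes as a
#' specificity control.
#'
#' @param fits_kd,fits_ctrl Frames from [fit_decay()].
#' @param target_genes Character vector of binding-target gene ids.
#' @param min_n Minimum passed fits per side among targets.
#' @return List with `p_value`, `median_shift` (KD - control, hours),
#'   `n_kd`, `n_ctrl` and `nontarget` (same fields for non-targets, or
#'   NULL when too few).
#' @export
half_life_shift_test <- function(fits_kd, fits_ctrl, target_genes,
                                 min_n = 5L) {
  take <- function(fits, genes, invert = FALSE) {
    sel <- fits$passed & !is.na(fits$half_life) &
      (if (invert) !(fits$gene_id %in% genes) else fits$gene_id %in% genes)
    fits$half_life[sel]
  }
  hk <- take(fits_kd, target_genes); hc <- take(fits_ctrl, target_genes)
  if (length(hk) < min_n || length(hc) < min_n) {
    stop("insufficient passed target fits: ", length(hk), " KD, ",
         length(hc), " control (need >= ", min_n, ")")
  }
  wt <- stats::wilcox.test(hk, hc, exact = FALSE)
  nt_k <- take(fits_kd, target_genes, invert = TRUE)
  nt_c <- take(fits_ctrl, target_genes, invert = TRUE)
  nontarget <- if (length(nt_k) >= min_n && length(nt_c) >= min_n) {
    wn <- stats::wilcox.test(nt_k, nt_c, exact = FALSE)
    list(p_value = wn$p.value,
         median_shift = stats::median(nt_k) - stats::median(nt_c),
         n_kd = length(nt_k), n_ctrl = length(nt_c))
  }
  list(p_value = wt$p.value,
       median_shift = stats::median(hk) - stats::median(hc),
       n_kd = length(hk), n_ctrl = length(hc), nontarget = nontarget)
}

# ---- Ribo-STAMP -------------------------------------------------------------

#' Compute edits-per-read (EPR) records
#'
#' `epr = edits / exon_reads`, defined only for positive exon read
#' counts; zero-read genes are excluded and tallied.
#'
#' @param table Long data frame in the `epr` schema
#'   (`gene_id, sample, edits, exon_reads`).
#' @return List with `records` (the table plus an `epr` column) and
#'   `n_excluded_zero_reads`.
#' @export
compute_epr <- function(table) {
  zero <- table$exon_reads <= 0
  if (any(zero)) warning(sum(zero), " record(s) with zero exon reads ",
                         "excluded")
  tab <- table[!zero, , drop = FALSE]
  tab$epr <- tab$edits / tab$exon_reads
  list(records = tab, n_excluded_zero_reads = sum(zero))
}

#' Differential EPR test (2 knockdown vs 2 control samples)
#'
#' Genes must have nonzero edits in all four samples to be tested. Each
#' gene gets an independent two-tailed t-test (pooled variance) on EPR
#' between knockdown and control samples; p-values are
#' Benjamini-Hochberg adjusted across tested genes and significance is
#' called at FDR < `fdr_cut`.
#'
#' @param records EPR records from [compute_epr()].
#' @param kd_samples,ctrl_samples Sample names of each condition.
#' @param fdr_cut FDR threshold.
#' @return Data frame per tested gene: mean EPRs, `log2_ratio`,
#'   `p_value`, `fdr`, `significant`; genes excluded for zero edits are
#'   counted in attribute `n_excluded_zero_edits`.
#' @export
differential_epr <- function(records, kd_samples = c("KD_1", "KD_2"),
                             ctrl_samples = c("CTL_1", "CTL_2"),
                             fdr_cut = 0.1) {
  samples <- c(kd_samples, ctrl_samples)
  if (length(samples) < 4) stop("need four samples (2 KD + 2 control)")
  rec <- records[records$sample %in% samples, , drop = FALSE]
  n_excluded <- 0L
  rows <- lapply(unique(rec$gene_id), function(gid) {
    sub <- rec[rec$gene_id == gid, , drop = FALSE]
    if (nrow(sub) < length(samples) || any(sub$edits == 0)) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    kd <- sub$epr[sub$sample %in% kd_samples]
    ct <- sub$epr[sub$sample %in% ctrl_samples]
    tt <- tryCatch(stats::t.test(kd, ct, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    data.frame(gene_id = gid, mean_epr_kd = mean(kd), mean_epr_ctrl = mean(ct),
               log2_ratio = log2(mean(kd) / mean(ct)),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), mean_epr_kd = numeric(0),
                      mean_epr_ctrl = numeric(0), log2_ratio = numeric(0),
                      p_value = numeric(0))
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < fdr_cut
  attr(res, "n_excluded_zero_edits") <- n_excluded
  res
}
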