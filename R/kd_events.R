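# Significant-event calling from knockdown differential tables, and
# detection of ZFPs with more events than an experimental-batch null
# predicts.

#' Call significant differential events for one knockdown
#'
#' Differentially expressed genes (DEGs) are genes with FDR < 0.05 and a
#' fold change exceeding 20% in either direction (|log2FC| > log2(1.2)).
#' Alternative splicing (ASE) and polyadenylation (APAE) events require
#' FDR < 0.05 and |delta PSI| > 0.2. Records with missing FDR are
#' excluded and tallied.
#'
#' @param expr Data frame with `gene_id`, `log2fc`, `fdr`.
#' @param splice Data frame with `event_id`, `gene_id`, `delta_psi`, `fdr`.
#' @param apa Data frame with `gene_id`, `delta_psi`, `fdr`.
#' @param fdr_cut FDR threshold.
#' @param fc_cut Fold-change threshold on the linear scale (1.2 = 20%).
#' @param dpsi_cut |delta PSI| threshold.
#' @return List with `deg`, `ase`, `apae` (the significant subsets),
#'   `counts` (named vector of cardinalities) and `n_na_fdr` (records
#'   dropped for missing FDR).
#' @export
call_significant_events <- function(expr, splice, apa, fdr_cut = 0.05,
                                    fc_cut = 1.2, dpsi_cut = 0.2) {
  pick <- function(df, effect_col, effect_cut) {
    if (is.null(df)) return(list(sig = NULL, n_na = 0L))
    stopifnot(all(c("fdr", effect_col) %in% names(df)))
    na <- is.na(df$fdr)
    ok <- !na & df$fdr < fdr_cut & abs(df[[effect_col]]) > effect_cut
    list(sig = df[ok, , drop = FALSE], n_na = sum(na))
  }
  deg <- pick(expr, "log2fc", log2(fc_cut))
  ase <- pick(splice, "delta_psi", dpsi_cut)
  apae <- pick(apa, "delta_psi", dpsi_cut)
  n_na <- deg$n_na + ase$n_na + apae$n_na
  if (n_na > 0) warning(n_na, " record(s) with missing FDR excluded")
  list(deg = deg$sig, ase = ase$sig, apae = apae$sig,
       counts = c(degs = NROW(deg$sig), ases = NROW(ase$sig),
                  apaes = NROW(apae$sig)),
       n_na_fdr = n_na)
}

#' Fit the batch model and compute per-dataset residual outlier statistics
#'
#' Significant-event counts are regressed on experimental batch by
#' ordinary least squares with cell-means coding (one indicator per batch,
#' no intercept), so the predicted count for each dataset is its batch
#' mean. The residual is reported as percent fold change relative to the
#' prediction, and each dataset's p-value comes from its externally
#' studentized residual referred to a t distribution with n - k - 1
#' degrees of freedom (k = number of batch coefficients), two-sided by
#' default. A dataset is flagged when p < 0.05 and the residual percent
#' fold change exceeds +20%.
#'
#' @param counts Event-count matrix: data frame with `zfp_id`, `batch` and
#'   one column per event type (e.g. `degs`, `ases`, `apaes`).
#' @param event_type Which count column to model.
#' @param p_cut,res_cut Flagging thresholds (p-value; residual percent
#'   fold change).
#' @param sided `"two"` (default) or `"one"` (upper tail).
#' @return Data frame of per-dataset results: observed, predicted,
#'   `residual_pct_fc`, `p_value`, `flagged`, plus the model F-test
#'   p-value as attribute `fit_p`.
#' @export
fit_batch_residuals <- function(counts, event_type = "degs", p_cut = 0.05,
                                res_cut = 20, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(all(c("zfp_id", "batch", event_type) %in% names(counts)))
  y <- counts[[event_type]]
  if (any(is.na(y)) || any(y < 0)) stop("counts must be non-negative")
  batch <- factor(counts$batch)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  if (any(table(batch) < 2)) {
    stop("every batch needs >= 2 datasets (no within-batch variance ",
         "otherwise)")
  }
  fit <- stats::lm(y ~ 0 + batch)
  predicted <- stats::fitted(fit)
  if (any(predicted <= 0)) stop("predicted count <= 0 for batch ",
                                counts$batch[predicted <= 0][1])
  resid_pct <- 100 * (y - predicted) / predicted
  tstat <- stats::rstudent(fit)
  ## a zero raw residual is never an outlier; guards against 0/0 and
  ## catastrophic cancellation when a batch fits perfectly
  tstat[is.nan(tstat) | abs(y - predicted) < 1e-8 * pmax(1, predicted)] <- 0
  df_t <- stats::df.residual(fit) - 1L
  p <- if (sided == "two") 2 * stats::pt(-abs(tstat), df_t)
       else stats::pt(tstat, df_t, lower.tail = FALSE)
  resf <- data.frame(zfp_id = counts$zfp_id, batch = counts$batch,
                     event_type = event_type, observed = y,
                     predicted = as.numeric(predicted),
                     residual_pct_fc = as.numeric(resid_pct),
                     p_value = as.numeric(p),
                     stringsAsFactors = FALSE)
  resf$flagged <- resf$p_value < p_cut & resf$residual_pct_fc > res_cut
  attr(resf, "fit_p") <- if (sum(stats::residuals(fit)^2) < 1e-10) {
    NA_real_   # perfect fit: F-test undefined
  } else {
    f <- summary(stats::lm(y ~ batch))$fstatistic
    if (is.null(f)) NA_real_ else
      unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  }
  resf
}

#' Subset the high-residual (flagged) datasets
#'
#' @param results Output of [fit_batch_residuals()], or several such
#'   frames rbind-ed.
#' @return The flagged subset.
#' @export
flag_high_residual <- function(results) {
  results[results$flagged, , drop = FALSE]
}
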