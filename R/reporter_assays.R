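# Tethering-assay statistics: firefly/Renilla normalization and one-tailed
# hit tests for the stability reporter and the splicing minigene reporters.

#' Normalize firefly/Renilla ratios to a control construct
#'
#' Each well's firefly/Renilla ratio is divided by the mean ratio of the
#' control construct's wells, so the control normalizes to mean 1.
#'
#' @param wells Data frame in the `tethering` schema.
#' @param control_construct Name of the baseline construct.
#' @return `wells` with `ratio` and `normalized` columns added.
#' @export
normalize_ratios <- function(wells, control_construct = "control") {
  if (any(wells$renilla <= 0)) stop("renilla must be positive in every well")
  wells$ratio <- wells$firefly / wells$renilla
  ctrl <- wells$ratio[wells$construct_id == control_construct]
  if (length(ctrl) < 2) stop("missing control construct '",
                             control_construct, "' (need >= 2 wells)")
  wells$normalized <- wells$ratio / mean(ctrl)
  wells
}

#' Inclusion proxy for the splicing minigene reporters
#'
#' The reporters read out cassette-exon inclusion as the share of firefly
#' signal: `100 * firefly / (firefly + renilla)` per well.
#'
#' @param wells Data frame with `firefly` and `renilla`.
#' @return Numeric vector of percent-inclusion proxies.
#' @export
inclusion_proxy <- function(wells) {
  100 * wells$firefly / (wells$firefly + wells$renilla)
}

#' One-tailed tethering hit test
#'
#' Independent two-sample t-test (pooled variance) of the test construct
#' against the control, one-tailed in the stated direction; a hit
#' requires p < `p_cut`.
#'
#' @param test_values,control_values Per-well normalized ratios (or
#'   inclusion proxies for the splicing reporters); at least 3 each.
#' @param direction `"increase"`, `"decrease"` or `"psi_increase"`
#'   (synonym of increase, used for the splicing reporters).
#' @param p_cut Significance threshold.
#' @return List with `p_value`, `t`, `df`, `hit`, `direction`.
#' @export
tethering_test <- function(test_values, control_values,
                           direction = c("increase", "decrease",
                                         "psi_increase"),
                           p_cut = 0.05) {
  direction <- match.arg(direction)
  if (length(test_values) < 3 || length(control_values) < 3) {
    stop("need >= 3 replicates per side")
  }
  alt <- if (direction == "decrease") "less" else "greater"
  tt <- stats::t.test(test_values, control_values, alternative = alt,
                      var.equal = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), hit = tt$p.value < p_cut,
       direction = direction)
}

#' Test every construct in a tethering plate against the control
#'
#' Stability wells are normalized with [normalize_ratios()] and tested on
#' the normalized ratio; splicing reporter wells (`splice_up`,
#' `splice_down`) are tested on the inclusion proxy.
#'
#' @param wells Data frame in the `tethering` schema (single reporter).
#' @param control_construct Baseline construct name.
#' @param direction Tail direction for every construct.
#' @return Data frame, one row per non-control construct.
#' @export
tethering_screen <- function(wells, control_construct = "control",
                             direction = "increase") {
  rep_type <- if (!is.null(wells$reporter)) wells$reporter[1] else "stability"
  if (rep_type == "stability") {
    wells <- normalize_ratios(wells, control_construct)
    value <- wells$normalized
  } else {
    value <- inclusion_proxy(wells)
  }
  ctrl <- value[wells$construct_id == control_construct]
  ids <- setdiff(unique(wells$construct_id), control_construct)
  do.call(rbind, lapply(ids, function(cid) {
    tv <- value[wells$construct_id == cid]
    res <- tethering_test(tv, ctrl, direction)
    data.frame(construct_id = cid, mean_value = mean(tv),
               p_value = res$p_value, hit = res$hit,
               stringsAsFactors = FALSE)
  }))
}
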