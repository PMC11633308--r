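# Protein-level feature calling: arginine/lysine-rich (ARM-like) loci,
# disordered regions from per-residue disorder scores, occlusion-derived
# putative RNA-binding regions, and the per-protein tally of which domain
# classes a predicted RBD overlaps.

#' Scan a protein for arginine/lysine-rich loci
#'
#' A residue (0-based position) is a locus when the `window`-residue
#' window centered on it contains K/R at a frequency strictly greater
#' than `min_frac` (> 2.5 of 5 at defaults, i.e. at least 3), and the
#' center lies at least `edge_skip` residues from either terminus.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window size (residues).
#' @param min_frac K/R frequency threshold (strict >).
#' @param edge_skip Residues disregarded at each terminus.
#' @return Integer vector of 0-based locus centers.
#' @export
scan_arm_loci <- function(sequence, window = 5L, min_frac = 0.5,
                          edge_skip = 2L) {
  if (window %% 2 == 0) stop("window must be odd")
  L <- nchar(sequence)
  if (L < window) return(integer(0))
  is_kr <- strsplit(toupper(sequence), "")[[1]] %in% c("K", "R")
  half <- window %/% 2L
  run <- stats::filter(as.numeric(is_kr), rep(1, window), sides = 2)
  centers <- which(!is.na(run) & run > min_frac * window) - 1L
  centers[centers >= edge_skip & centers <= L - 1L - edge_skip]
}

#' Merge consecutive ARM locus centers into intervals
#'
#' @param centers 0-based centers from [scan_arm_loci()].
#' @return Two-column matrix of half-open residue intervals.
#' @export
arm_intervals <- function(centers) {
  if (length(centers) == 0) return(matrix(integer(0), ncol = 2))
  centers <- sort(unique(centers))
  breaks <- c(0L, which(diff(centers) > 1L), length(centers))
  t(vapply(seq_len(length(breaks) - 1L), function(i) {
    c(centers[breaks[i] + 1L], centers[breaks[i + 1L]] + 1L)
  }, integer(2)))
}

## maximal runs where cond is TRUE, as half-open 0-based intervals
runs_to_intervals <- function(cond, min_len = 1L) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

#' Call disordered regions from a per-residue disorder score track
#'
#' @param disorder_score Numeric track, one value per residue.
#' @param threshold Disorder threshold (strict >, default 0.4).
#' @param sequence_length Optional check against the protein length.
#' @return Two-column matrix of half-open residue intervals.
#' @export
call_idr_regions <- function(disorder_score, threshold = 0.4,
                             sequence_length = NULL) {
  if (!is.null(sequence_length) &&
      length(disorder_score) != sequence_length) {
    stop("disorder track length != sequence length")
  }
  runs_to_intervals(!is.na(disorder_score) & disorder_score > threshold)
}

#' Call putative RNA-binding regions from an occlusion Z track
#'
#' Maximal runs of residues with occlusion Z strictly below `z_cut`
#' (default -1), of length at least `min_len`.
#'
#' @param occlusion_z Numeric track, one value per residue.
#' @param z_cut Z threshold (strict <).
#' @param min_len Minimum run length retained.
#' @param sequence_length Optional check against the protein length.
#' @return Two-column matrix of half-open residue intervals.
#' @export
call_rbd_intervals <- function(occlusion_z, z_cut = -1, min_len = 1L,
                               sequence_length = NULL) {
  if (!is.null(sequence_length) && length(occlusion_z) != sequence_length) {
    stop("occlusion track length != sequence length")
  }
  runs_to_intervals(!is.na(occlusion_z) & occlusion_z < z_cut, min_len)
}

#' Tabulate which feature classes a protein's predicted RBDs overlap
#'
#' A class is overlapped when any RBD interval shares at least one
#' residue with any interval of that class (half-open intervals; ARM
#' locus centers are treated as width-1 intervals). Domain labels in
#' `zf_labels` count as `ZF_domain`, all other labels as `other_domain`.
#'
#' @param protein_id Protein identifier.
#' @param rbds RBD intervals from [call_rbd_intervals()].
#' @param idrs IDR intervals from [call_idr_regions()].
#' @param arm_centers ARM locus centers from [scan_arm_loci()].
#' @param domains Optional data frame `(class, start, end)` of annotated
#'   domains on this protein.
#' @param zf_labels Domain labels treated as zinc-finger domains.
#' @return One-row data frame: `protein_id`, `has_rbd`, logical columns
#'   `IDR`, `ZF_domain`, `ARM_like`, `other_domain`.
#' @export
overlap_feature_classes <- function(protein_id, rbds, idrs = NULL,
                                    arm_centers = integer(0),
                                    domains = NULL,
                                    zf_labels = c("C2H2", "CCCH", "ZF",
                                                  "zf-C2H2")) {
  has_rbd <- NROW(rbds) > 0
  ov <- function(ivs) {
    if (!has_rbd || is.null(ivs) || NROW(ivs) == 0) return(FALSE)
    for (i in seq_len(nrow(rbds))) {
      if (any(pmax(rbds[i, 1], ivs[, 1]) < pmin(rbds[i, 2], ivs[, 2]))) {
        return(TRUE)
      }
    }
    FALSE
  }
  arm_iv <- if (length(arm_centers)) cbind(arm_centers, arm_centers + 1L)
  dom_iv <- function(labels) {
    if (is.null(domains) || nrow(domains) == 0) return(NULL)
    sel <- domains[domains$class %in% labels, , drop = FALSE]
    if (nrow(sel) == 0) NULL else cbind(sel$start, sel$end)
  }
  other_labels <- if (is.null(domains)) character(0) else
    setdiff(unique(domains$class), zf_labels)
  data.frame(protein_id = protein_id, has_rbd = has_rbd,
             IDR = ov(idrs), ZF_domain = ov(dom_iv(zf_labels)),
             ARM_like = ov(arm_iv), other_domain = ov(dom_iv(other_labels)),
             stringsAsFactors = FALSE)
}

#' Run the protein feature workflow over a simulated or loaded protein set
#'
#' @param sequences Named character vector of protein sequences.
#' @param tracks Data frame in the `protein_tracks` schema.
#' @param domains Optional data frame in the `domains` schema.
#' @return List with per-protein `arm_centers`, `idrs`, `rbds` and the
#'   combined `overlap` table.
#' @export
protein_feature_calls <- function(sequences, tracks, domains = NULL) {
  res <- lapply(names(sequences), function(pid) {
    tr <- tracks[tracks$protein_id == pid, , drop = FALSE]
    tr <- tr[order(tr$position), , drop = FALSE]
    L <- nchar(sequences[[pid]])
    arm <- scan_arm_loci(sequences[[pid]])
    idr <- call_idr_regions(tr$disorder_score, sequence_length = L)
    rbd <- call_rbd_intervals(tr$occlusion_z, sequence_length = L)
    dom <- if (!is.null(domains)) {
      domains[domains$protein_id == pid, , drop = FALSE]
    }
    list(protein_id = pid, arm_centers = arm, idrs = idr, rbds = rbd,
         overlap = overlap_feature_classes(pid, rbd, idr, arm, dom))
  })
  names(res) <- names(sequences)
  list(calls = res,
       overlap = do.call(rbind, lapply(res, `[[`, "overlap")))
}
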