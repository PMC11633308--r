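# End-to-end orchestration: simulate a full synthetic study, run every
# analysis module, and write per-module TSVs plus a deterministic run
# manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param n_genes,n_windows,n_peaks,n_rbns_reads Scenario sizes.
#' @return A named configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("zfpkit_run_"),
                            n_genes = 150L, n_windows = 2000L,
                            n_peaks = 400L, n_rbns_reads = 20000L) {
  list(seed = as.integer(seed), out_dir = out_dir,
       n_genes = as.integer(n_genes), n_windows = as.integer(n_windows),
       n_peaks = as.integer(n_peaks),
       n_rbns_reads = as.integer(n_rbns_reads))
}

KNOWN_CONFIG_KEYS <- c("seed", "out_dir", "n_genes", "n_windows", "n_peaks",
                       "n_rbns_reads")

#' Run the full synthetic-study pipeline
#'
#' Simulates an annotation, binding data, knockdown tables, RBNS pools,
#' SLAM-seq series, Ribo-STAMP counts, tethering plates and proteins from
#' the configured seed, runs every analysis module on them, and writes
#' the resulting tables plus `manifest.json` (package version, config
#' hash, seed) into `config$out_dir`. Reruns with the same configuration
#' are byte-identical.
#'
#' @param config List from [pipeline_config()]. Unknown keys are
#'   rejected.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  missing <- setdiff(KNOWN_CONFIG_KEYS, names(config))
  if (length(missing)) stop("missing config key: ", missing[1])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  cfg <- sim_config(seed = config$seed, n_genes = config$n_genes)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genes <- step("annotation", make_annotation(cfg, out("genes.bed12")))

  step("binding", {
    bind <- simulate_binding(cfg, genes, planted_feature = "3'UTR",
                             planted_or = 8, n_windows = config$n_windows,
                             n_background = config$n_windows,
                             n_peaks = config$n_peaks)
    write_windows(bind$windows, out("windows.bed"))
    peaks <- bind$peaks; peaks$planted_tss <- NULL
    write_narrowpeak(peaks, out("peaks.narrowPeak"))
    ann <- annotate_windows(bind$windows, genes)
    bg <- annotate_windows(bind$background, genes)
    write_table_tsv(ann, out("windows.annotated.tsv"))
    write_table_tsv(feature_enrichment_table(ann, bg), out("enrichment.tsv"))
    peaks2 <- assign_nearest_gene(peaks, genes)
    mode <- classify_binding_mode(peaks2, ann, threshold = 50)
    write_table_tsv(data.frame(n_dna_genes = mode$n_dna_genes,
                               n_rna_genes = mode$n_rna_genes,
                               mode = mode$mode), out("binding_mode.tsv"))
    dist <- peak_distance_profile(peaks2, ann, genes)
    write_table_tsv(dist, out("distances.tsv"))
    prof <- metagene_density(ann, genes)
    write_table_tsv(data.frame(bin = prof$bins, density = prof$density,
                               count = prof$counts), out("metagene.tsv"))
  })

  step("kd_events", {
    kd <- simulate_kd_tables(cfg, batch_means = c(A = 100, B = 800),
                             n_per_batch = 6L,
                             outliers = data.frame(zfp_id = "ZFP_OUT",
                                                   batch = "A",
                                                   excess = 0.5),
                             n_genes = 1000L)
    write_table_tsv(kd$counts, out("event_counts.tsv"))
    res <- do.call(rbind, lapply(c("degs", "ases", "apaes"), function(ev) {
      fit_batch_residuals(kd$counts, ev)
    }))
    write_table_tsv(res, out("residuals.tsv"))
    write_table_tsv(flag_high_residual(res), out("high_residual.tsv"))
  })

  step("rbns", {
    rb <- simulate_rbns(cfg, "GAAGA", planted_fraction = 0.3,
                        n_reads = config$n_rbns_reads)
    write_pool_fasta(rb$pulldown, out("rbns_pulldown.fa"))
    write_pool_fasta(rb$input, out("rbns_input.fa"))
    mot <- rbns_motifs(rb$pulldown, rb$input)
    write_table_tsv(utils::head(mot$enrichment, 100), out("rbns_enrichment.tsv"))
    pwm <- mot$pwms[[1]]
    write_table_tsv(data.frame(position = seq_len(ncol(pwm$probs)),
                               t(pwm$probs), consensus = pwm$consensus),
                    out("rbns_pwm.tsv"))
  })

  step("slam", {
    hl <- stats::setNames(seq(1, 12, length.out = 60),
                          sprintf("G%04d", 1:60))
    ctrl <- simulate_slam(cfg, hl, condition = "control")
    kd <- simulate_slam(cfg, hl * ifelse(seq_along(hl) <= 30, 1.5, 1),
                        condition = "kd")
    write_table_tsv(rbind(ctrl$series, kd$series), out("slam.tsv"))
    fits_c <- slam_half_lives(ctrl$series)
    fits_k <- slam_half_lives(kd$series)
    write_table_tsv(rbind(fits_c, fits_k), out("half_lives.tsv"))
    shift <- half_life_shift_test(fits_k, fits_c, names(hl)[1:30])
    write_table_tsv(data.frame(p_value = shift$p_value,
                               median_shift = shift$median_shift,
                               n_kd = shift$n_kd, n_ctrl = shift$n_ctrl),
                    out("half_life_shift.tsv"))
  })

  step("epr", {
    ep <- simulate_epr(cfg, n_genes = 300L,
                       effect_genes = stats::setNames(rep(2, 30),
                                                      sprintf("G%04d", 1:30)))
    write_table_tsv(ep$table, out("epr_counts.tsv"))
    recs <- compute_epr(ep$table)
    diff <- differential_epr(recs$records)
    write_table_tsv(diff, out("epr_differential.tsv"))
  })

  step("tethering", {
    te <- simulate_tethering(cfg, effect_constructs = c(ZFP_HIT = 2))
    write_table_tsv(te$wells, out("tethering.tsv"))
    write_table_tsv(tethering_screen(te$wells), out("tethering_hits.tsv"))
  })

  step("proteins", {
    pr <- simulate_proteins(cfg, lengths = c(P1 = 300L, P2 = 200L),
                            planted_arm_runs = list(P1 = rbind(c(100L, 105L))),
                            planted_rbd = list(P1 = rbind(c(30L, 50L))),
                            planted_idr = list(P2 = rbind(c(20L, 80L))))
    write_table_tsv(pr$tracks, out("protein_tracks.tsv"))
    calls <- protein_feature_calls(pr$sequences, pr$tracks)
    write_table_tsv(calls$overlap, out("protein_overlap.tsv"))
  })

  ## manifest: version, config hash, seed -- no timestamps, so reruns are
  ## byte-identical
  hashed <- config[setdiff(names(config), "out_dir")]
  cfg_json <- jsonlite::toJSON(hashed[order(names(hashed))],
                               auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package = "zfpkit",
    version = as.character(utils::packageVersion("zfpkit")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}
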