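test_that("annotation generation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 1, n_genes = 50)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  make_annotation(cfg, f1)
  make_annotation(cfg, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## and reading the emitted BED12 back reproduces the models
  genes <- make_annotation(cfg)
  back <- read_annotation(f1, "bed12")
  expect_equal(names(back), names(genes))
  expect_equal(back$G0001$exons, genes$G0001$exons)
  expect_equal(back$G0007$tss, genes$G0007$tss)
})

test_that("generators do not disturb the caller's RNG state", {
  set.seed(42)
  before <- .Random.seed
  invisible(make_annotation(sim_config(seed = 9, n_genes = 5)))
  expect_identical(.Random.seed, before)
})

test_that("single-exon genes have UTR5/CDS/UTR3 tiling the exon exactly", {
  cfg <- sim_config(seed = 2, n_genes = 20, n_exons_range = c(1L, 1L),
                    noncoding_frac = 0)
  genes <- make_annotation(cfg)
  for (g in genes) {
    parts <- rbind(g$utr5, g$cds, g$utr3)
    parts <- parts[order(parts[, 1]), , drop = FALSE]
    expect_equal(parts[1, 1], g$exons[1, 1])
    expect_equal(parts[nrow(parts), 2], g$exons[1, 2])
    expect_true(all(parts[-1, 1] == parts[-nrow(parts), 2]))
  }
})

test_that("infeasible exon requests are rejected", {
  expect_error(
    make_annotation(sim_config(seed = 1, n_genes = 1,
                               gene_length_range = c(200L, 200L),
                               n_exons_range = c(10L, 10L))),
    "too small")
})

test_that("null binding simulation matches genomic feature fractions", {
  cfg <- sim_config(seed = 5, n_genes = 100)
  genes <- make_annotation(cfg)
  b <- simulate_binding(cfg, genes, planted_feature = "3'UTR",
                        planted_or = 1, n_windows = 10000,
                        n_background = 100)
  ann <- annotate_windows(b$windows, genes, use_ss_classes = FALSE)
  frac_obs <- mean(ann$feature_class == "3'UTR")
  frac_exp <- b$ground_truth$in_len /
    (b$ground_truth$in_len + b$ground_truth$out_len)
  se <- sqrt(frac_exp * (1 - frac_exp) / 10000)
  expect_lt(abs(frac_obs - frac_exp), 3 * se)
})

test_that("binding simulation validates the planted feature", {
  cfg <- sim_config(seed = 5, n_genes = 10, noncoding_frac = 0)
  genes <- make_annotation(cfg)
  expect_error(simulate_binding(cfg, genes, planted_feature = "noncoding"),
               "absent")
  expect_error(simulate_binding(cfg, genes, planted_or = 0.5), ">= 1")
})

test_that("knockdown count simulation is Poisson around batch means", {
  cfg <- sim_config(seed = 7)
  kd <- simulate_kd_tables(cfg, batch_means = c(A = 100, B = 1000),
                           n_per_batch = 30, make_tables = FALSE)
  for (b in c("A", "B")) {
    mu <- c(A = 100, B = 1000)[[b]]
    obs <- mean(kd$counts$degs[kd$counts$batch == b])
    expect_lt(abs(obs - mu), 3 * sqrt(mu / 30))
  }
  ## determinism
  kd2 <- simulate_kd_tables(cfg, batch_means = c(A = 100, B = 1000),
                            n_per_batch = 30, make_tables = FALSE)
  expect_identical(kd$counts, kd2$counts)
  expect_error(
    simulate_kd_tables(cfg, outliers = data.frame(zfp_id = "x", batch = "Z",
                                                  excess = 0.5)),
    "unknown batch")
})

test_that("significant-event counts in simulated tables match the matrix", {
  cfg <- sim_config(seed = 8)
  kd <- simulate_kd_tables(cfg, batch_means = c(A = 50), n_per_batch = 2,
                           n_genes = 500)
  z <- kd$counts$zfp_id[1]
  ev <- suppressWarnings(call_significant_events(
    kd$tables[[z]]$expr, kd$tables[[z]]$splice, kd$tables[[z]]$apa))
  expect_equal(unname(ev$counts["degs"]), kd$counts$degs[1])
  expect_equal(unname(ev$counts["ases"]), kd$counts$ases[1])
  expect_equal(unname(ev$counts["apaes"]), kd$counts$apaes[1])
})

test_that("noise-free SLAM counts follow the decay closed form", {
  cfg <- sim_config(seed = 3)
  sl <- simulate_slam(cfg, half_lives = c(gX = 4), reps = 1,
                      depth = 1000, noise = "none")
  s <- sl$series
  y0 <- s$tc_conversions[s$timepoint_h == 0]
  y4 <- s$tc_conversions[s$timepoint_h == 4]
  expect_equal(y4 / y0, 0.5)
  ## low-depth gene flagged as expected CPM-filter failure
  sl2 <- simulate_slam(cfg, half_lives = c(lo = 4), depth = 1,
                       library_total = 4e5)
  expect_true(sl2$ground_truth$expected_filter_fail[["lo"]])
  expect_error(simulate_slam(cfg, half_lives = c(g = -1)), "positive")
})

test_that("null RBNS pools are exchangeable and generation deterministic", {
  cfg <- sim_config(seed = 4)
  rb <- simulate_rbns(cfg, "GAAGA", planted_fraction = 0, n_reads = 5000)
  enr <- kmer_enrichment(count_kmers(rb$pulldown), count_kmers(rb$input))
  ## all enrichments near 1 at zero planted signal
  expect_lt(max(abs(log(enr$R))), 1)
  expect_gt(mean(abs(log(enr$R)) < 0.5), 0.99)
  rb2 <- simulate_rbns(cfg, "GAAGA", planted_fraction = 0, n_reads = 5000)
  expect_identical(rb$pulldown, rb2$pulldown)
  expect_error(simulate_rbns(cfg, "GAAGAGAAGAGAAGAGAAGAGAAGA",
                             read_len = 20), "longer than read_len")
})

test_that("EPR and tethering simulations enforce their preconditions", {
  cfg <- sim_config(seed = 4)
  expect_error(simulate_epr(cfg, reps = 1), ">= 2")
  expect_error(simulate_epr(cfg, effect_genes = c(G0001 = -2)), "> 0")
  expect_error(simulate_tethering(cfg, effect_constructs = c(x = 0)), "> 0")
})

test_that("protein plants are recovered exactly by the callers", {
  cfg <- sim_config(seed = 6)
  pr <- simulate_proteins(cfg, lengths = c(P1 = 100L),
                          planted_arm_runs = list(P1 = rbind(c(10L, 15L))),
                          planted_rbd = list(P1 = rbind(c(30L, 50L))),
                          planted_idr = list(P1 = rbind(c(60L, 80L))))
  expect_equal(scan_arm_loci(pr$sequences[["P1"]]), 10:14)
  tr <- pr$tracks
  expect_equal(unname(call_rbd_intervals(tr$occlusion_z)),
               unname(cbind(30L, 50L)))
  expect_equal(unname(call_idr_regions(tr$disorder_score)),
               unname(cbind(60L, 80L)))
  ## no plants -> no calls
  pr0 <- simulate_proteins(cfg, lengths = c(P2 = 80L))
  expect_length(scan_arm_loci(pr0$sequences[["P2"]]), 0)
  expect_equal(nrow(call_rbd_intervals(pr0$tracks$occlusion_z)), 0L)
  ## contradictory overlapping plants rejected
  expect_error(
    simulate_proteins(cfg, lengths = c(P1 = 100L),
                      planted_rbd = list(P1 = rbind(c(10L, 30L),
                                                    c(20L, 40L)))),
    "overlapping")
})
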