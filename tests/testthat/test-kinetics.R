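test_that("CPM and replicate filters follow the retention rule", {
  ## all replicates at CPM 2.5: dropped (threshold is strict > 5)
  s <- mk_series(matrix(2.5, nrow = 3, ncol = 4))
  expect_equal(nrow(filter_slam_genes(s)$retained), 0L)
  ## 3 reps, one failing at t=8 only: retained with exactly 2 reps
  cpm <- matrix(50, nrow = 3, ncol = 4)
  cpm[2, 4] <- 4
  f <- filter_slam_genes(mk_series(cpm))
  expect_equal(f$retained$n_reps, 2L)
  expect_false(2 %in% f$series$replicate)
  ## 3 reps, two failing at t=0: dropped
  cpm2 <- matrix(50, nrow = 3, ncol = 4)
  cpm2[1:2, 1] <- 1
  expect_equal(nrow(filter_slam_genes(mk_series(cpm2))$retained), 0L)
  ## missing timepoint: replicate cannot pass; gene dropped with tally
  s3 <- mk_series(matrix(50, nrow = 2, ncol = 4))
  s3 <- s3[!(s3$replicate == 1 & s3$timepoint_h == 8), ]
  expect_warning(f3 <- filter_slam_genes(s3), "missing timepoints")
  expect_equal(f3$n_dropped_incomplete, 1L)
})

test_that("noiseless exponential series recover k to 1e-6 relative", {
  for (hl in c(0.5, 1, 2, 4, 8, 24)) {
    t <- c(0, 2, 4, 8)
    y <- 1000 * 2^(-t / hl)
    s <- data.frame(gene_id = "g", condition = "c", timepoint_h = t,
                    replicate = 1, tc_conversions = y,
                    library_total = 4e5)
    fit <- fit_decay(s)
    expect_equal(fit$half_life, hl, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(fit$passed)
  }
  ## expected k for hl = 4: ln2/4
  s4 <- data.frame(gene_id = "g", condition = "c",
                   timepoint_h = c(0, 2, 4, 8), replicate = 1,
                   tc_conversions = 1000 * 2^(-c(0, 2, 4, 8) / 4),
                   library_total = 4e5)
  expect_equal(fit_decay(s4)$k, log(2) / 4, tolerance = 1e-6)
})

test_that("flat or rising series do not pass the decay fit", {
  s <- data.frame(gene_id = "g", condition = "c",
                  timepoint_h = c(0, 2, 4, 8), replicate = 1,
                  tc_conversions = rep(100, 4), library_total = 4e5)
  fit <- fit_decay(s)
  expect_false(fit$passed)
  expect_lt(abs(fit$k), 1e-3)
  up <- s; up$tc_conversions <- c(100, 150, 220, 500)
  fitu <- fit_decay(up)
  expect_false(fitu$passed)
})

test_that("simulated decay is recovered within 15% for passing genes", {
  cfg <- sim_config(seed = 61)
  hl <- setNames(runif(50, 1, 12), sprintf("G%04d", 1:50))
  ## independent of the generator's own stream
  hl[] <- seq(1, 12, length.out = 50)
  sim <- simulate_slam(cfg, hl, depth = 1000)
  fits <- slam_half_lives(sim$series)
  ok <- fits[fits$passed, ]
  expect_gt(nrow(ok), 30)
  rel_err <- abs(ok$half_life - hl[ok$gene_id]) / hl[ok$gene_id]
  expect_gte(mean(rel_err <= 0.15), 0.9)
})

test_that("half-life shift test finds a planted 1.5x slowdown", {
  cfg <- sim_config(seed = 62)
  hl <- setNames(seq(1, 10, length.out = 120), sprintf("G%04d", 1:120))
  targets <- names(hl)[1:60]
  ctrl <- simulate_slam(cfg, hl, condition = "control")
  kd_hl <- hl; kd_hl[targets] <- kd_hl[targets] * 1.5
  kd <- simulate_slam(cfg, kd_hl, condition = "kd")
  fits_c <- slam_half_lives(ctrl$series)
  fits_k <- slam_half_lives(kd$series)
  res <- half_life_shift_test(fits_k, fits_c, targets)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$median_shift, 0)
  ## specificity: non-targets show no shift
  expect_gt(res$nontarget$p_value, 0.05)
  expect_error(half_life_shift_test(fits_k[1:3, ], fits_c, targets),
               "insufficient")
})

test_that("EPR arithmetic and exclusions match the contract", {
  tab <- data.frame(gene_id = "g1", sample = "KD_1", edits = 10,
                    exon_reads = 1000)
  rec <- compute_epr(tab)
  expect_equal(rec$records$epr, 0.01)
  tab0 <- rbind(tab, data.frame(gene_id = "g2", sample = "KD_1",
                                edits = 5, exon_reads = 0))
  expect_warning(rec0 <- compute_epr(tab0), "zero exon reads")
  expect_equal(rec0$n_excluded_zero_reads, 1L)
  ## a gene with zero edits in any of the four samples is not tested
  four <- expand.grid(gene_id = c("g1", "g2"),
                      sample = c("KD_1", "KD_2", "CTL_1", "CTL_2"),
                      stringsAsFactors = FALSE)
  four$exon_reads <- 1000
  four$edits <- ifelse(four$gene_id == "g2" & four$sample == "CTL_2",
                       0, 20 + seq_len(8))
  recs <- compute_epr(four)$records
  res <- differential_epr(recs)
  expect_false("g2" %in% res$gene_id)
  expect_equal(attr(res, "n_excluded_zero_edits"), 1L)
})

test_that("differential EPR detects planted 2x ratios at FDR 0.1", {
  cfg <- sim_config(seed = 63)
  eff <- setNames(rep(2, 100), sprintf("G%04d", 1:100))
  ep <- simulate_epr(cfg, n_genes = 1000, effect_genes = eff)
  recs <- compute_epr(ep$table)
  res <- differential_epr(recs$records)
  sens <- mean(names(eff) %in% res$gene_id[res$significant])
  expect_gte(sens, 0.8)
  ## null genes rarely called
  null_hits <- sum(res$significant & !(res$gene_id %in% names(eff)))
  expect_lt(null_hits / 900, 0.05)
})

test_that("null EPR simulations stay near the nominal FDR", {
  hit_fracs <- vapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed)
    ep <- simulate_epr(cfg, n_genes = 200)
    res <- differential_epr(compute_epr(ep$table)$records)
    mean(res$significant)
  }, numeric(1))
  ## t-test on n=2 is anti-conservative; calibration bound is documented
  expect_lte(mean(hit_fracs), 0.15)
})
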