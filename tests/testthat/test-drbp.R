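test_that("binding mode thresholds are strict and exclude far peaks", {
  mk_windows <- function(n) data.frame(gene_id = paste0("g", seq_len(n)))
  mk_peaks <- function(n, dist = 0) {
    data.frame(gene_id = paste0("g", seq_len(n)), gene_dist = dist)
  }
  expect_equal(classify_binding_mode(mk_peaks(501), mk_windows(501))$mode,
               "DRBP")
  expect_equal(classify_binding_mode(mk_peaks(501), mk_windows(300))$mode,
               "DNA_only")
  expect_equal(classify_binding_mode(mk_peaks(300), mk_windows(501))$mode,
               "RNA_only")
  ## exactly 500 is not "more than 500"
  expect_equal(classify_binding_mode(mk_peaks(500), mk_windows(500))$mode,
               "neither")
  ## peaks beyond 100 kb of the nearest gene leave the DNA count
  p <- mk_peaks(501)
  p$gene_dist[1] <- 150000
  res <- classify_binding_mode(p, mk_windows(501))
  expect_equal(res$n_dna_genes, 500L)
  expect_equal(res$mode, "RNA_only")
  expect_error(classify_binding_mode(data.frame(chrom = "chr1", start = 1,
                                                end = 2),
                                     mk_windows(1)), "annotation")
})

test_that("nearest-gene assignment reports gap and signed TSS distance", {
  genes <- list(gplus = tiny_gene_plus())   # span [100,600), TSS 100
  p <- data.frame(chrom = "chr1", start = c(150L, 700L, 0L),
                  end = c(250L, 800L, 40L), name = c("a", "b", "c"),
                  stringsAsFactors = FALSE)
  out <- assign_nearest_gene(p, genes)
  expect_equal(out$gene_dist, c(0, 100, 60))
  ## midpoints 200, 750, 20 vs TSS 100 on '+': downstream positive
  expect_equal(out$dist_to_tss, c(100, 650, -80))
  gm <- list(gminus = tiny_gene_minus())    # TSS at 599
  out2 <- assign_nearest_gene(p[1, ], gm)
  expect_equal(out2$dist_to_tss, 399)       # upstream -> positive on '-'? no:
  ## peak mid 200 is 399 bp 5'-ward... sign flips with strand
  expect_equal(sign(out2$dist_to_tss), 1)
})

test_that("peak-to-window signed distances follow strand orientation", {
  genes <- list(gplus = tiny_gene_plus(), gminus = tiny_gene_minus())
  ## '+' gene: peak mid 110, window mid 210 -> +100
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 120L,
                      name = "p1", gene_id = "gplus",
                      stringsAsFactors = FALSE)
  w <- window_at(205, 215, gene_id = "gplus")
  expect_equal(peak_distance_profile(peaks, w, genes)$distance, 100)
  ## '-' gene: peak mid 210, window mid 110 -> +100 (window is 3' there)
  peaks2 <- data.frame(chrom = "chr1", start = 200L, end = 220L,
                       name = "p2", gene_id = "gminus",
                       stringsAsFactors = FALSE)
  w2 <- window_at(105, 115, gene_id = "gminus")
  expect_equal(peak_distance_profile(peaks2, w2, genes)$distance, 100)
  ## nearest by |distance|: +100 beats -400
  w3 <- rbind(window_at(605, 615, gene_id = "gplus"),    # mid 610
              window_at(105, 115, gene_id = "gplus"))    # mid 110
  peaks3 <- data.frame(chrom = "chr1", start = 500L, end = 520L,
                       name = "p3", gene_id = "gplus",
                       stringsAsFactors = FALSE)
  expect_equal(peak_distance_profile(peaks3, w3, genes)$distance, 100)
  ## peaks on window-less genes are omitted
  expect_equal(nrow(peak_distance_profile(peaks, w2, genes)), 0L)
})

test_that("metagene positions are exact on hand-placed windows", {
  gp <- gene_model("gp", "chr1", "+", 1000L, 3000L,
                   exons = rbind(c(1000L, 3000L)))
  gm <- gene_model("gm", "chr1", "-", 1000L, 3000L,
                   exons = rbind(c(1000L, 3000L)))
  genes <- list(gp = gp, gm = gm)
  ## '+' gene [1000,3000), window mid 1500 -> position 25
  prof <- metagene_density(window_at(1495, 1505, gene_id = "gp"), genes)
  expect_equal(prof$bins[prof$counts == 1], 25)
  ## '-' gene [1000,3000), window mid 2500 -> position 25
  prof2 <- metagene_density(window_at(2495, 2505, gene_id = "gm"), genes)
  expect_equal(prof2$bins[prof2$counts == 1], 25)
  ## all windows at the TSS: everything in bin 0, density sums to 1
  w <- do.call(rbind, replicate(5, window_at(1000, 1002, gene_id = "gp"),
                                simplify = FALSE))
  prof3 <- metagene_density(w, genes)
  expect_equal(prof3$density[1], 1)
  expect_equal(sum(prof3$density), 1)
})

test_that("metagene density is invariant under translation and mirroring", {
  cfg <- sim_config(seed = 41, n_genes = 40)
  genes <- make_annotation(cfg)
  b <- simulate_binding(cfg, genes, planted_or = 1, n_windows = 300,
                        n_background = 10)
  prof <- metagene_density(b$windows, genes)
  ## translate everything by +10 kb
  shift <- 10000L
  genes_t <- lapply(genes, function(g) {
    gene_model(g$gene_id, g$chrom, g$strand, g$start + shift,
               g$end + shift, g$exons + shift,
               if (nrow(g$utr5)) g$utr5 + shift,
               if (nrow(g$cds)) g$cds + shift,
               if (nrow(g$utr3)) g$utr3 + shift)
  })
  w_t <- b$windows
  w_t$start <- w_t$start + shift; w_t$end <- w_t$end + shift
  prof_t <- metagene_density(w_t, genes_t)
  expect_equal(prof_t$density, prof$density)
  ## mirror the genome: flip coordinates and strands around a pivot
  piv <- 2000000L
  genes_m <- lapply(genes, function(g) {
    flip <- function(iv) {
      if (is.null(iv) || nrow(iv) == 0) return(NULL)
      m <- cbind(piv - iv[, 2], piv - iv[, 1])
      m[order(m[, 1]), , drop = FALSE]
    }
    gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
               piv - g$end, piv - g$start, flip(g$exons), flip(g$utr5),
               flip(g$cds), flip(g$utr3))
  })
  w_m <- b$windows
  s <- piv - b$windows$end; e <- piv - b$windows$start
  w_m$start <- s; w_m$end <- e
  prof_m <- metagene_density(w_m, genes_m)
  expect_equal(prof_m$density, prof$density)
})

test_that("TSS/TTS proximity test detects a planted TSS bias", {
  cfg0 <- sim_config(seed = 51, n_genes = 60)
  genes <- make_annotation(cfg0)
  mk_prof <- function(seed, bias) {
    cfg <- sim_config(seed = seed, n_genes = 60)
    b <- simulate_binding(cfg, genes, planted_or = 1,
                          planted_tss_bias = bias, n_windows = 300,
                          n_background = 10)
    metagene_density(b$windows, genes)
  }
  grpA <- lapply(1:12, mk_prof, bias = 3)
  grpB <- lapply(13:24, mk_prof, bias = 1)
  res <- tss_tts_enrichment_test(grpA, grpB)
  expect_lt(res$p_value[res$end == "TSS"], 0.01)
  expect_gt(res$median_a[res$end == "TSS"],
            res$median_b[res$end == "TSS"])
  ## planted bias is ~3x the uniform expectation in bins 0-2
  dens <- mean(vapply(grpA, function(p) sum(p$density[1:3]), numeric(1)))
  expect_gt(dens / 0.03, 2.2)
  expect_lt(dens / 0.03, 3.8)
  expect_error(tss_tts_enrichment_test(grpA[1], grpB), ">= 2")
})
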