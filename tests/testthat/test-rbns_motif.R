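test_that("sliding-window k-mer counting covers every window once", {
  k <- count_kmers("GAAGAA", 5)
  expect_equal(sort(names(k)), c("AAGAA", "GAAGA"))
  expect_equal(unname(k[c("GAAGA", "AAGAA")]), c(1L, 1L))
  ## a 20-nt read yields 16 pentamer windows
  r20 <- paste(rep("ACGU", 5), collapse = "")
  expect_equal(sum(count_kmers(r20, 5)), 16L)
  ## totals: sum over reads of (len - k + 1)
  set.seed(1)
  reads <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(5:30, 1), TRUE),
          collapse = "")
  }, "")
  expect_equal(sum(count_kmers(reads, 5)),
               sum(pmax(nchar(reads) - 4L, 0L)))
  ## empty pool and invalid symbols
  expect_length(count_kmers(character(0), 5), 0)
  kk <- count_kmers(c("GAAGAN", "GAAGAA"), 5)
  expect_equal(attr(kk, "n_skipped"), 1L)
  expect_equal(sum(kk), 2L)
  expect_error(count_kmers("ACGU", 0), "positive")
})

test_that("k-mer enrichment is 1 for identical pools and always finite", {
  counts <- count_kmers(c("GAAGAACGUA", "CCCGGGUUUA"), 5)
  enr <- kmer_enrichment(counts, counts)
  expect_true(all(enr$R == 1))
  ## pseudocount keeps R finite for k-mers absent from one pool
  enr2 <- kmer_enrichment(c(GAAGA = 10L), c(CCCCC = 10L), pseudocount = 1)
  expect_true(all(is.finite(enr2$R)))
  expect_gt(enr2$R[enr2$kmer == "GAAGA"], 1)
  expect_error(kmer_enrichment(c(GAAGA = 1L), c(ACG = 1L)), "mismatched k")
  ## sorted by R descending, ties lexicographic
  expect_true(all(diff(enr2$R) <= 0))
})

test_that("alignment to the anchor follows the category priority", {
  ## 1 mismatch at offset 0
  al <- zfpkit:::align_one_kmer("GAUGA", "GAAGA")
  expect_equal(al$category, "1mm")
  expect_equal(al$offset, 0L)
  ## pure offset +1 (4-nt overlap, 0 mismatches)
  al <- zfpkit:::align_one_kmer("AAGAA", "GAAGA")
  expect_equal(al$category, "1off")
  expect_equal(al$offset, 1L)
  ## unalignable
  expect_null(zfpkit:::align_one_kmer("CUCUC", "GAAGA"))
  ## exact beats everything
  expect_equal(zfpkit:::align_one_kmer("GAAGA", "GAAGA")$category, "exact")
})

test_that("alignment matches the brute-force enumeration oracle", {
  set.seed(77)
  for (i in 1:1000) {
    a <- random_kmer(); b <- random_kmer()
    got <- zfpkit:::align_one_kmer(b, a)
    want <- oracle_align(b, a)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[c("offset", "n_mismatch", "category")],
                   want[c("offset", "n_mismatch", "category")])
    }
  }
})

test_that("unalignable k-mers seed a second group recursively", {
  enr <- data.frame(kmer = c("GAAGA", "AAGAA", "CUCUC", "CUCUA"),
                    R = c(5, 3, 2.5, 2), stringsAsFactors = FALSE)
  groups <- align_top_kmers(enr, top_n = 4)
  expect_length(groups, 2)
  expect_equal(groups[[1]]$anchor, "GAAGA")
  expect_equal(sort(groups[[1]]$members$kmer), c("AAGAA", "GAAGA"))
  expect_equal(groups[[2]]$anchor, "CUCUC")
  expect_equal(sort(groups[[2]]$members$kmer), c("CUCUA", "CUCUC"))
  expect_error(align_top_kmers(enr, top_n = 1), ">= 2")
})

test_that("weighted PWM accumulates enrichment and normalizes per column", {
  enr <- data.frame(kmer = c("GAAGA", "GAUGA"), R = c(5, 3),
                    stringsAsFactors = FALSE)
  groups <- align_top_kmers(enr, top_n = 2)
  pwm <- build_weighted_pwm(groups[[1]])
  ## position 3: A gets the anchor's R=5, U the candidate's R=3
  expect_equal(unname(pwm$weights["A", 3]), 5)
  expect_equal(unname(pwm$weights["U", 3]), 3)
  expect_equal(unname(pwm$probs["A", 3]), 0.625)
  expect_equal(unname(pwm$probs["U", 3]), 0.375)
  ## retained column weights sum to their support
  expect_equal(colSums(pwm$weights), pwm$support, ignore_attr = TRUE)
  expect_equal(pwm$consensus, "GAAGA")
})

test_that("singleton groups give a one-hot matrix scaled by R", {
  g <- list(anchor = "GAAGA",
            members = data.frame(kmer = "GAAGA", R = 4, offset = 0L,
                                 n_mismatch = 0L, category = "exact"))
  pwm <- build_weighted_pwm(g)
  expect_equal(dim(pwm$weights), c(4L, 5L))
  expect_equal(sum(pwm$weights), 20)
  expect_true(all(pwm$support == 4))
  expect_equal(pwm$consensus, "GAAGA")
})

test_that("edge columns below the support threshold are trimmed", {
  ## candidate at offset +1 creates a right edge column carried by it alone
  g <- list(anchor = "GAAGA",
            members = data.frame(kmer = c("GAAGA", "AAGAA"),
                                 R = c(10, 1), offset = c(0L, 1L),
                                 n_mismatch = c(0L, 0L),
                                 category = c("exact", "1off")))
  pwm <- build_weighted_pwm(g, trim_frac = 0.25)
  ## right edge support 1 < 0.25 * 11 -> trimmed; 5 columns remain
  expect_equal(ncol(pwm$weights), 5L)
  expect_equal(pwm$offsets, 0:4)
  pwm2 <- build_weighted_pwm(g, trim_frac = 0.05)
  expect_equal(ncol(pwm2$weights), 6L)
  ## interior columns are never removed even when weak
  expect_true(all(diff(pwm2$offsets) == 1))
})

test_that("planted RBNS motifs are recovered end to end", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed)
    rb <- simulate_rbns(cfg, "GAAGA", planted_fraction = 0.3,
                        n_reads = 20000)
    mot <- rbns_motifs(rb$pulldown, rb$input)
    top <- mot$enrichment$kmer[1]
    cons <- mot$pwms[[1]]$consensus
    if (top == "GAAGA" && grepl("GAAGA", cons, fixed = TRUE)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})
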