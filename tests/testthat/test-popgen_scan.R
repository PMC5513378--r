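# per-site diversity, weighted FST, smoothing, outliers, summaries

test_that("pi_site matches pairwise enumeration", {
  expect_equal(pi_site(c(A = 4, C = 0)), 0)
  expect_equal(pi_site(c(A = 2, C = 2)), 4 / 6)
  expect_equal(pi_site(c(A = 6, C = 2)), 12 / 28)
  expect_true(is.na(pi_site(c(A = 1))))
  for (i in 1:50) {
    cnt <- random_counts()[[1]]
    expect_equal(pi_site(cnt), brute_pi(rep(names(cnt), cnt)))
  }
})

test_that("heterozygosity returns observed and expected components", {
  expect_equal(heterozygosity(c(1L, 1L, 1L))$h_obs, 1)
  h <- heterozygosity(c(0L, 1L, 2L, 1L))
  expect_equal(h$h_obs, 0.5)
  expect_equal(h$h_exp, 0.5)
  expect_true(is.na(heterozygosity(c(NA_integer_, NA_integer_))$h_obs))
})

test_that("weighted FST reproduces hand-computed configurations", {
  expect_equal(weighted_fst(list(c(A = 4), c(C = 4))), 1)
  expect_equal(weighted_fst(list(c(A = 6, C = 2), c(A = 2, C = 6))),
               11 / 56)  # 0.19643
  expect_equal(weighted_fst(list(c(A = 9, C = 1), c(A = 1, C = 3))),
               948 / 2040)  # 0.46471, unequal weights C(10,2), C(4,2)
  # negative values are reported, not clamped
  fst_neg <- weighted_fst(list(c(A = 1, C = 1), c(A = 1, C = 1)))
  expect_lt(fst_neg, 0)
  expect_equal(weighted_fst(list(c(A = 1, C = 1), c(A = 1, C = 1)),
                            clamp_negative = TRUE), 0)
})

test_that("weighted FST agrees with the brute-force pair enumeration", {
  set.seed(11)
  for (i in 1:200) {
    counts <- random_counts()
    expect_equal(weighted_fst(counts), brute_weighted_fst(counts),
                 tolerance = 1e-12)
  }
})

test_that("FST is invariant to population and allele label swaps", {
  set.seed(12)
  for (i in 1:50) {
    counts <- random_counts()
    fst <- weighted_fst(counts)
    expect_equal(weighted_fst(rev(counts)), fst)
    swapped <- lapply(counts, function(x) stats::setNames(x, rev(names(x))))
    expect_equal(weighted_fst(swapped), fst)
    if (!is.na(fst)) {
      p1 <- counts[[1]]; p2 <- counts[[2]]
      both_fixed_diff <- length(unique(rep(names(p1), p1))) == 1 &&
        length(unique(rep(names(p2), p2))) == 1 &&
        !setequal(names(p1)[p1 > 0], names(p2)[p2 > 0])
      expect_equal(isTRUE(all.equal(fst, 1)), both_fixed_diff)
    }
  }
})

test_that("kernel smoothing is a truncated-Gaussian weighted mean", {
  pos <- c(0, 50000, 120000, 500000)
  expect_equal(kernel_smooth(pos, rep(0.2, 4)), rep(0.2, 4))
  # two sites one sigma apart
  sm <- kernel_smooth(c(0, 50000), c(0, 1), sigma_bp = 50000)
  expect_equal(sm[1], exp(-0.5) / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(sm[1], 0.37754, tolerance = 1e-5)
  # isolated site keeps its own value
  sm2 <- kernel_smooth(c(0, 1e6), c(0.9, 0.1), sigma_bp = 50000)
  expect_equal(sm2, c(0.9, 0.1))
  # convex combination within each window
  set.seed(3)
  p <- sort(runif(40, 0, 2e6)); x <- runif(40)
  sm3 <- kernel_smooth(p, x)
  expect_true(all(sm3 >= min(x) - 1e-12 & sm3 <= max(x) + 1e-12))
  expect_error(kernel_smooth(c(2, 1), c(0, 0)), "sorted")
})

test_that("quantile outlier detection uses a strict threshold", {
  det <- detect_outliers(rep(0.3, 1000), 0.999)
  expect_equal(det$threshold, 0.3)
  expect_equal(sum(det$outlier), 0L)

  det2 <- detect_outliers(c(rep(0.01, 9999), 0.9), 0.999)
  expect_equal(sum(det2$outlier), 1L)
  expect_true(det2$outlier[10000])
})

test_that("outlier intervals are reported per linkage group", {
  rec <- data.frame(chrom = c("LG23", "LG23", "LG23", "LG5"),
                    pos = c(9190077L, 11065693L, 5e6, 100L),
                    outlier = c(TRUE, TRUE, FALSE, TRUE))
  iv <- outlier_interval(rec, "LG23")
  expect_equal(iv$width_bp, 1875616L)
  expect_equal(iv$n_outliers, 2L)

  both <- outlier_interval(rec)
  expect_equal(nrow(both), 2L)
  expect_equal(both$width_bp[both$chrom == "LG5"], 0L)

  rec$outlier <- FALSE
  expect_equal(nrow(outlier_interval(rec)), 0L)
})

test_that("per-linkage-group summaries aggregate correctly", {
  rec <- data.frame(chrom = c(rep("LG1", 3), rep("LG2", 4)),
                    fst = c(0, 0.1, 0.2, rep(0.05, 4)))
  s <- summarize_by_lg(rec)
  expect_equal(s$mean[s$chrom == "LG1"], 0.1)
  expect_equal(s$median[s$chrom == "LG1"], 0.1)
  expect_equal(s$sd[s$chrom == "LG2"], 0)
  expect_equal(sum(s$n), nrow(rec))
})

test_that("fst_scan composes counts, smoothing and outliers per site", {
  # two populations of 4; site 2 is a fixed difference
  gm <- make_gm(c("020", "121", "221", "020",
                  "100", "000", "101", "201"),
                pos = c(1000L, 2000L, 3000L))
  pm <- make_pmap(gm, n_case = 4)
  scan <- fst_scan(gm, pm, scan_config(sigma_bp = 300))
  expect_equal(scan$fst[scan$pos == 2000], 1)
  expect_equal(scan$n_alleles_p1, rep(8L, 3))
  # sigma small enough that no neighbour falls in any 3-sigma window
  expect_equal(scan$fst_smooth, scan$fst)
  # monomorphic pooled sites are skipped
  gm2 <- make_gm(c("00", "01", "00", "01"), pos = c(10L, 20L))
  pm2 <- make_pmap(gm2, n_case = 2)
  expect_message(scan2 <- fst_scan(gm2, pm2), "skipped")
  expect_equal(nrow(scan2), 1L)
})
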