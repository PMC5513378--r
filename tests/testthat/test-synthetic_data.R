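# family simulator: map function, founders, meiosis, penetrance, datasets

test_that("the Haldane map function behaves at its landmarks", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(3), (1 - exp(-0.06)) / 2)
  expect_equal(haldane_r(3), 0.02912, tolerance = 1e-4)
  expect_equal(haldane_r(1e6), 0.5)
  expect_true(all(diff(haldane_r(seq(0, 200, by = 5))) > 0))  # monotone
})

test_that("founders have the configured dimensions and causal heterozygosity", {
  cfg <- small_sim_config(snps_per_lg = 10L)
  set.seed(5)
  fdr <- make_founders(cfg)
  expect_equal(nrow(fdr$sites), 20L)
  expect_length(fdr$families, 3L)
  for (fam in fdr$families) {
    expect_equal(dim(fam$sire), c(2L, 20L))
    expect_equal(dim(fam$dam), c(2L, 20L))
    expect_equal(sum(fam$sire[, fdr$causal_index]), 1L)  # heterozygous
    expect_equal(sum(fam$dam[, fdr$causal_index]), 1L)
  }
  expect_equal(fdr$sites$pos[fdr$causal_index], 5000000L)
  expect_equal(fdr$sites$alt[fdr$causal_index], "C")

  # degenerate founder frequency interval pins every neutral frequency
  cfg2 <- small_sim_config(founder_maf_range = c(0.5, 0.5))
  set.seed(5)
  fdr2 <- make_founders(cfg2)
  expect_true(all(fdr2$sites$freq == 0.5))
})

test_that("meiosis transmits only parental alleles and respects linkage", {
  cfg <- small_sim_config()
  set.seed(6)
  fdr <- make_founders(cfg)
  parent <- fdr$families[[1]]$sire
  for (i in 1:20) {
    gamete <- meiosis(parent, fdr$sites, cfg)
    expect_true(all(gamete == parent[1, ] | gamete == parent[2, ]))
  }
  # zero recombination: each linkage group is copied from a single haplotype
  cfg0 <- small_sim_config(cm_per_mb = 0)
  parent0 <- rbind(rep(0L, 100), rep(1L, 100))
  set.seed(7)
  for (i in 1:10) {
    g <- meiosis(parent0, fdr$sites, cfg0)
    for (lg in split(seq_len(100), fdr$sites$chrom)) {
      expect_length(unique(g[lg]), 1L)
    }
  }
})

test_that("phenotype assignment follows the genotype penetrances", {
  pen <- c(CC = 0.853, CG = 0.368, GG = 0.0)
  set.seed(8)
  expect_false(any(assign_phenotype(rep("GG", 5000), pen)))
  frac_cc <- mean(assign_phenotype(rep("CC", 10000), pen))
  expect_lt(abs(frac_cc - 0.853), 0.02)
  expect_false(any(assign_phenotype(rep("CG", 100), c(CC = 0, CG = 0, GG = 0))))
  expect_error(assign_phenotype("CT", pen), "no penetrance")
})

test_that("the default study has the design's dimensions and classes", {
  ds <- default_sim()
  expect_equal(n_individuals(ds$genotypes), 120L)
  expect_equal(n_sites(ds$genotypes), 8800L)
  expect_equal(length(unique(ds$genotypes$sites$chrom)), 22L)
  expect_equal(sum(ds$popmap$phenotype == 2L), 60L)
  expect_equal(sum(ds$popmap$phenotype == 1L), 60L)
  # truth is consistent with the emitted genotypes at the causal site
  ci <- which(ds$genotypes$sites$chrom == "LG23" &
                ds$genotypes$sites$pos == 9441132L)
  expect_length(ci, 1L)
  dosage <- ds$genotypes$calls[, ci]
  key <- c("GG", "CG", "CC")[dosage + 1L]
  ok <- !is.na(dosage)
  expect_identical(key[ok], ds$truth$causal_genotype[ok])
  # no homozygous-protective case under zero GG penetrance
  expect_false(any(ds$truth$causal_genotype == "GG" & ds$truth$masculinized))
})

test_that("missingness and depth follow the configuration", {
  ds <- simulate_dataset(small_sim_config(missing_rate = 0))
  expect_false(anyNA(ds$genotypes$calls))
  ds2 <- simulate_dataset(small_sim_config(missing_rate = 0.2, seed = 3))
  expect_gt(mean(is.na(ds2$genotypes$calls)), 0.15)
  expect_true(all(ds2$genotypes$depth[is.na(ds2$genotypes$calls)] == 0L))
})

test_that("identical configuration and seed give identical studies", {
  a <- simulate_dataset(small_sim_config(seed = 9))
  b <- simulate_dataset(small_sim_config(seed = 9))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$genotypes$depth, b$genotypes$depth)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(small_sim_config(seed = 10))
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("the masculinizing allele is enriched among cases across seeds", {
  for (seed in 1:20) {
    ds <- simulate_dataset(small_sim_config(seed = seed))
    ci <- which(ds$genotypes$sites$chrom == "LG2" &
                  ds$genotypes$sites$pos == 5e6)
    cases <- ds$popmap$individual[ds$popmap$phenotype == 2L]
    ctrls <- ds$popmap$individual[ds$popmap$phenotype == 1L]
    f_case <- mean(ds$genotypes$calls[cases, ci], na.rm = TRUE) / 2
    f_ctrl <- mean(ds$genotypes$calls[ctrls, ci], na.rm = TRUE) / 2
    expect_gt(f_case, f_ctrl)
  }
})

test_that("an unreachable class aborts generation with a clear error", {
  cfg <- small_sim_config(penetrance = c(CC = 0, CG = 0, GG = 0))
  expect_error(simulate_dataset(cfg), "could not collect")
})
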