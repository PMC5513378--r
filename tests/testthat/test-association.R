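# case-control allelic association: tables, chi-square, OR, Bonferroni

# the five internally consistent published example rows used throughout:
# N cases / N controls, minor-allele frequency in cases / controls, and the
# printed chi-square, OR and CI they must reproduce
example_rows <- data.frame(
  n_case = c(43, 43, 43, 53, 43),
  n_ctrl = c(44, 45, 46, 53, 45),
  f_case = c(0.163, 0.349, 0.163, 0.170, 0.488),
  f_ctrl = c(0.614, 0.133, 0.391, 0.387, 0.233),
  chisq = c(37.13, 11.24, 11.49, 12.42, 12.45),
  or = c(0.122, 3.482, 0.303, 0.324, 3.136),
  l95 = c(0.060, 1.641, 0.149, 0.171, 1.644),
  u95 = c(0.250, 7.389, 0.615, 0.615, 5.984))

reconstruct_tables <- function(rows) {
  a <- counts_from_frequencies(rows$n_case, rows$f_case)
  b <- counts_from_frequencies(rows$n_ctrl, rows$f_ctrl)
  list(a = a, b = b, c = 2 * rows$n_case - a, d = 2 * rows$n_ctrl - b)
}

test_that("counts reconstruct from printed frequencies with half-up ties", {
  expect_equal(counts_from_frequencies(44, 0.614), 54L)
  expect_equal(counts_from_frequencies(43, 0.163), 14L)
  expect_equal(counts_from_frequencies(10, 0), 0L)
  expect_equal(counts_from_frequencies(1, 0.25), 1L)  # 0.5 rounds up
})

test_that("allele tables are built from genotypes with the pooled-minor rule", {
  # 2 cases {CC, CG}, 2 controls {GG, GG}; ref = G, alt = C
  gm <- make_gm(c("2", "1", "0", "0"), ref = "G", alt = "C")
  pm <- make_pmap(gm, n_case = 2)
  tab <- table_from_genotypes(gm, pm, 1)
  expect_equal(tab[c("a", "b", "c", "d")], list(a = 3L, b = 0L, c = 1L, d = 4L))
  expect_equal(tab$minor_allele, "C")
  expect_equal(tab$major_allele, "G")

  # all-missing cases are skipped
  gm2 <- make_gm(c(".", ".", "1", "0"))
  expect_message(res <- table_from_genotypes(gm2, make_pmap(gm2, 2), 1),
                 "skipped")
  expect_null(res)

  # pooled 4:4 tie resolves to the lexicographically smaller allele
  gm3 <- make_gm(c("1", "1", "1", "1"), ref = "T", alt = "A")
  tab3 <- table_from_genotypes(gm3, make_pmap(gm3, 2), 1)
  expect_equal(tab3$minor_allele, "A")
})

test_that("the allelic chi-square reproduces the published example rows", {
  tabs <- reconstruct_tables(example_rows)
  res <- allelic_chisq(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(res$chisq, example_rows$chisq, tolerance = 0.01 / 11)
  expect_true(all(abs(res$chisq - example_rows$chisq) <= 0.01))

  # zero-association table
  flat <- allelic_chisq(10, 10, 30, 30)
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p, 1)
  # zero margin
  expect_equal(allelic_chisq(0, 0, 5, 5)$chisq, 0)
})

test_that("allelic chi-square equals the generic Pearson statistic", {
  set.seed(21)
  for (i in 1:50) {
    cell <- sample(1:80, 4)
    mine <- allelic_chisq(cell[1], cell[2], cell[3], cell[4])$chisq
    pearson <- suppressWarnings(
      stats::chisq.test(matrix(cell, 2, byrow = TRUE), correct = FALSE))
    expect_equal(mine, unname(pearson$statistic), tolerance = 1e-10)
  }
})

test_that("odds ratios and Woolf intervals reproduce the example rows", {
  tabs <- reconstruct_tables(example_rows)
  orci <- odds_ratio_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(abs(orci$or - example_rows$or) <= 0.001))
  expect_true(all(abs(orci$l95 - example_rows$l95) <= 0.001))
  expect_true(all(abs(orci$u95 - example_rows$u95) <= 0.001))

  sym <- odds_ratio_ci(10, 10, 10, 10)
  expect_equal(sym$or, 1)
  expect_equal(sym$l95, exp(-stats::qnorm(0.975) * sqrt(0.4)), tolerance = 1e-10)
  expect_equal(sym$l95, 0.2895, tolerance = 1e-4)
  expect_equal(sym$u95, 3.4540, tolerance = 1e-4)

  # zero cells: NA unless the Haldane correction is requested
  z <- odds_ratio_ci(0, 5, 10, 5)
  expect_true(is.na(z$or) && is.na(z$l95))
  zh <- odds_ratio_ci(0, 5, 10, 5, haldane = TRUE)
  expect_equal(zh$or, (0.5 * 5.5) / (5.5 * 10.5))
})

test_that("label swaps behave as the 2x2 symmetry dictates", {
  set.seed(22)
  for (i in 1:25) {
    cell <- sample(1:60, 4)
    a <- cell[1]; b <- cell[2]; c <- cell[3]; d <- cell[4]
    base_chi <- allelic_chisq(a, b, c, d)
    base_or <- odds_ratio_ci(a, b, c, d)
    # minor <-> major swap
    swap_chi <- allelic_chisq(c, d, a, b)
    swap_or <- odds_ratio_ci(c, d, a, b)
    expect_equal(swap_chi$chisq, base_chi$chisq)
    expect_equal(swap_chi$p, base_chi$p)
    expect_equal(swap_or$or, 1 / base_or$or)
    expect_equal(swap_or$l95, 1 / base_or$u95)
    expect_equal(swap_or$u95, 1 / base_or$l95)
    # case <-> control swap
    cc_chi <- allelic_chisq(b, a, d, c)
    expect_equal(cc_chi$chisq, base_chi$chisq)
    expect_equal(odds_ratio_ci(b, a, d, c)$or, 1 / base_or$or)
  }
})

test_that("Bonferroni adjustment is min(1, m p) and validates input", {
  expect_equal(bonferroni_adjust(0, m = 9104), 0)
  expect_equal(bonferroni_adjust(0.0008, m = 9104), 1)
  expect_equal(bonferroni_adjust(1e-6, m = 9104), 0.009104)
  expect_equal(bonferroni_adjust(c(0.01, 0.002)), c(0.02, 0.004))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("assoc_scan tests per site with m = sites tested", {
  gm <- make_gm(c("2", "2", "0", "1"))
  pm <- make_pmap(gm, n_case = 2)
  res <- assoc_scan(gm, pm)
  expect_equal(res$m, 1L)
  expect_equal(res$records$p_bonf, res$records$p)
  expect_identical(colnames(res$records),
                   c("chrom", "snp", "pos", "a1", "f_a", "f_u", "a2",
                     "chisq", "p", "or", "l95", "u95", "p_bonf"))
})
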