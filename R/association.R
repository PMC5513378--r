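#' Build a 2x2 allele table for a case-control site
#'
#' Counts minor- and major-allele copies among genotyped cases (phenotype 2)
#' and controls (phenotype 1) at one site. The minor allele is the rarer
#' allele of the *pooled* sample (PLINK convention); a pooled tie resolves to
#' the lexicographically smaller nucleotide.
#'
#' @param gm a [genotype_matrix].
#' @param pmap a [population_map] (phenotype codes 1/2).
#' @param site site index, or a site id present in `gm$sites$id`.
#' @return list with counts `a` (minor in cases), `b` (minor in controls),
#'   `c` (major in cases), `d` (major in controls), labels `minor_allele` /
#'   `major_allele`, frequencies `f_case` / `f_control`, and sample sizes
#'   `n_case` / `n_control` (genotyped individuals). `NULL` if one class has
#'   no genotyped individual (with a message).
#' @export
table_from_genotypes <- function(gm, pmap, site) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(site)) site <- match(site, gm$sites$id)
  stopifnot(length(site) == 1L, !is.na(site), site >= 1L, site <= n_sites(gm))
  pmap <- match_popmap(gm, pmap)
  g_case <- gm$calls[match(pmap$individual[pmap$phenotype == 2L], gm$individuals), site]
  g_ctrl <- gm$calls[match(pmap$individual[pmap$phenotype == 1L], gm$individuals), site]
  g_case <- g_case[!is.na(g_case)]
  g_ctrl <- g_ctrl[!is.na(g_ctrl)]
  if (length(g_case) == 0L || length(g_ctrl) == 0L) {
    message("site ", gm$sites$id[site], " skipped: a class has no genotyped individuals")
    return(NULL)
  }
  alt_case <- sum(g_case)
  alt_ctrl <- sum(g_ctrl)
  n_case_al <- 2L * length(g_case)
  n_ctrl_al <- 2L * length(g_ctrl)
  ref <- gm$sites$ref[site]
  alt <- gm$sites$alt[site]
  alt_tot <- alt_case + alt_ctrl
  ref_tot <- n_case_al + n_ctrl_al - alt_tot
  minor_is_alt <- if (alt_tot != ref_tot) alt_tot < ref_tot else alt < ref
  if (minor_is_alt) {
    a <- alt_case; b <- alt_ctrl
    minor <- alt; major <- ref
  } else {
    a <- n_case_al - alt_case; b <- n_ctrl_al - alt_ctrl
    minor <- ref; major <- alt
  }
  list(a = a, b = b, c = n_case_al - a, d = n_ctrl_al - b,
       minor_allele = minor, major_allele = major,
       f_case = a / n_case_al, f_control = b / n_ctrl_al,
       n_case = length(g_case), n_control = length(g_ctrl))
}

#' Reconstruct an allele count from a printed frequency
#'
#' Published association tables usually print the number of genotyped
#' individuals and the minor-allele frequency per class; the underlying
#' integer allele count is `round(freq * 2n)` (ties rounded half-up). This
#' inverse is what lets printed tables be re-tested exactly.
#'
#' @param n_individuals genotyped individuals in the class.
#' @param freq minor-allele frequency in `[0, 1]`.
#' @return integer allele count.
#' @examples
#' counts_from_frequencies(44, 0.614)  # 54
#' @export
counts_from_frequencies <- function(n_individuals, freq) {
  stopifnot(all(freq >= 0), all(freq <= 1), all(n_individuals >= 0))
  as.integer(floor(freq * 2 * n_individuals + 0.5))
}

#' Basic allelic chi-square test (1 df)
#'
#' Pearson chi-square on the 2x2 allele-count table without continuity
#' correction: `chisq = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `N = a+b+c+d`; the p-value is the upper tail of the chi-square
#' distribution with one degree of freedom. A zero margin yields
#' `chisq = 0, p = 1`. All arguments are vectorised.
#'
#' @param a,b,c,d allele counts: minor allele in cases (`a`) and controls
#'   (`b`); major allele in cases (`c`) and controls (`d`).
#' @return list with `chisq` and `p`.
#' @examples
#' allelic_chisq(14, 54, 72, 34)
#' @export
allelic_chisq <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chisq <- ifelse(denom == 0, 0, n * (a * d - b * c)^2 / denom)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc`; the Woolf interval is computed on the log scale with
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. With any zero cell the OR
#' and interval are reported as `NA` unless `haldane = TRUE`, which adds 0.5
#' to every cell (Haldane-Anscombe correction). Vectorised.
#'
#' @inheritParams allelic_chisq
#' @param level confidence level, default 0.95.
#' @param haldane apply the 0.5 cell correction. Default `FALSE`.
#' @return list with `or`, `l95`, `u95` (bounds named after the default
#'   level).
#' @export
odds_ratio_ci <- function(a, b, c, d, level = 0.95, haldane = FALSE) {
  stopifnot(level > 0, level < 1)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  or <- ifelse(zero, NA_real_, a * d / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, l95 = exp(log(or) - z * se), u95 = exp(log(or) + z * se))
}

#' Bonferroni correction
#'
#' Maps each p-value to `min(1, m * p)`, preserving order. `m` defaults to
#' the number of p-values but may be larger (e.g. the number of sites tested
#' genome-wide when adjusting a subset).
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of tests; must be at least `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

#' Case-control allelic association scan
#'
#' Runs the basic allelic test at every site of a (filtered) genotype matrix:
#' 2x2 minor/major x case/control table, 1-df chi-square, asymptotic p,
#' odds ratio with Woolf 95% CI, and Bonferroni adjustment with `m` equal to
#' the number of sites actually tested. Sites with no genotyped individual in
#' a class are skipped.
#'
#' @param gm a [genotype_matrix].
#' @param pmap a [population_map]; phenotype 2 = case, 1 = control.
#' @param suggestive_p threshold for the suggestive-hit list. Default 0.001.
#' @param alpha threshold on the Bonferroni-adjusted p for the significant
#'   list. Default 0.05.
#' @param haldane passed to [odds_ratio_ci()].
#' @return object of class `assoc_scan`: list with `records` (data.frame
#'   `chrom, snp, pos, a1, f_a, f_u, a2, chisq, p, or, l95, u95, p_bonf`),
#'   `m` (tests performed), `suggestive` and `significant` (subsets sorted by
#'   p).
#' @export
assoc_scan <- function(gm, pmap, suggestive_p = 0.001, alpha = 0.05,
                       haldane = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pmap <- match_popmap(gm, pmap)
  if (!any(pmap$phenotype == 2L) || !any(pmap$phenotype == 1L)) {
    stop("association requires at least one case and one control")
  }
  g_case <- gm$calls[match(pmap$individual[pmap$phenotype == 2L], gm$individuals), ,
                     drop = FALSE]
  g_ctrl <- gm$calls[match(pmap$individual[pmap$phenotype == 1L], gm$individuals), ,
                     drop = FALSE]
  n_case_al <- 2 * colSums(!is.na(g_case))
  n_ctrl_al <- 2 * colSums(!is.na(g_ctrl))
  alt_case <- colSums(g_case, na.rm = TRUE)
  alt_ctrl <- colSums(g_ctrl, na.rm = TRUE)

  keep <- n_case_al > 0 & n_ctrl_al > 0
  if (any(!keep)) {
    message(sum(!keep), " site(s) skipped: a class has no genotyped individuals")
  }

  alt_tot <- alt_case + alt_ctrl
  ref_tot <- n_case_al + n_ctrl_al - alt_tot
  minor_is_alt <- alt_tot < ref_tot |
    (alt_tot == ref_tot & gm$sites$alt < gm$sites$ref)
  a <- ifelse(minor_is_alt, alt_case, n_case_al - alt_case)
  b <- ifelse(minor_is_alt, alt_ctrl, n_ctrl_al - alt_ctrl)
  cc <- n_case_al - a
  dd <- n_ctrl_al - b

  test <- allelic_chisq(a, b, cc, dd)
  orci <- odds_ratio_ci(a, b, cc, dd, haldane = haldane)

  rec <- data.frame(
    chrom = gm$sites$chrom, snp = gm$sites$id, pos = gm$sites$pos,
    a1 = ifelse(minor_is_alt, gm$sites$alt, gm$sites$ref),
    f_a = a / n_case_al, f_u = b / n_ctrl_al,
    a2 = ifelse(minor_is_alt, gm$sites$ref, gm$sites$alt),
    chisq = test$chisq, p = test$p,
    or = orci$or, l95 = orci$l95, u95 = orci$u95,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rec) <- NULL
  m <- nrow(rec)
  rec$p_bonf <- bonferroni_adjust(rec$p, m)

  by_p <- rec[order(rec$p), , drop = FALSE]
  structure(list(records = rec, m = m,
                 suggestive = by_p[by_p$p < suggestive_p, , drop = FALSE],
                 significant = by_p[by_p$p_bonf < alpha, , drop = FALSE]),
            class = "assoc_scan")
}

#' @exportS3Method base::print
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d sites tested; %d suggestive, %d Bonferroni-significant\n",
              x$m, nrow(x$suggestive), nrow(x$significant)))
  if (nrow(x$suggestive) > 0) {
    print(utils::head(x$suggestive[, c("chrom", "pos", "chisq", "p", "or", "p_bonf")], 10))
  }
  invisible(x)
}
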