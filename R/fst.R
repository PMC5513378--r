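#' Scan configuration
#'
#' @param sigma_bp Gaussian smoothing bandwidth in base pairs; the smoothing
#'   window is hard-truncated at 3 sigma to each side, so the default
#'   `sigma_bp = 50000` gives a 150 kb window.
#' @param outlier_quantile empirical quantile of raw per-site FST above which
#'   a site is flagged as an outlier (strictly greater). Default 0.999.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(sigma_bp = 50000, outlier_quantile = 0.999) {
  stopifnot(sigma_bp > 0, outlier_quantile > 0, outlier_quantile < 1)
  structure(list(sigma_bp = sigma_bp, outlier_quantile = outlier_quantile),
            class = "scan_config")
}

#' Single-site nucleotide diversity
#'
#' The probability that two alleles drawn without replacement at one site
#' differ: `pi = sum_{a<b} c(a) c(b) / choose(n, 2)`, the average pairwise
#' difference restricted to a single position.
#'
#' @param counts numeric vector of allele counts at the site (one entry per
#'   allele; names optional).
#' @return `pi` in `[0, 1]`, or `NA` when fewer than two alleles were sampled.
#' @examples
#' pi_site(c(A = 2, C = 2))  # 4/6
#' @export
pi_site <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  (n^2 - sum(counts^2)) / (n * (n - 1))
}

#' Observed and expected heterozygosity at one site
#'
#' @param genotypes integer vector of alternate-allele dosages (0/1/2, NA for
#'   missing) for one population at one site.
#' @return list with `h_obs` (fraction of non-missing genotypes that are
#'   heterozygous) and `h_exp` (`1 - sum p(a)^2` on this population's allele
#'   frequencies), both `NA` if every genotype is missing.
#' @export
heterozygosity <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L) return(list(h_obs = NA_real_, h_exp = NA_real_))
  p <- sum(g) / (2 * length(g))
  list(h_obs = mean(g == 1L), h_exp = 1 - p^2 - (1 - p)^2)
}

#' Sample-size-weighted fixation index at one site
#'
#' `FST = 1 - sum_j C(n_j, 2) pi_j / (pi_tot * sum_j C(n_j, 2))`, where `n_j`
#' is the number of alleles sampled in population `j`, `pi_j` the within-
#' population single-site nucleotide diversity and `pi_tot` the diversity of
#' the pooled sample. The binomial-coefficient weights account for unequal
#' sample sizes between populations. The value is not clamped: small samples
#' whose within-population diversity exceeds the pooled diversity yield
#' (legitimately) negative estimates; use `clamp_negative = TRUE` to floor at
#' zero.
#'
#' @param counts list of per-population named allele-count vectors (two or
#'   more populations; names identify alleles and are matched across
#'   populations).
#' @param clamp_negative floor negative estimates at 0. Default `FALSE`.
#' @return FST, or `NA` when any population has fewer than two alleles or the
#'   pooled sample is monomorphic.
#' @examples
#' weighted_fst(list(c(A = 4), c(C = 4)))            # fixed difference: 1
#' weighted_fst(list(c(A = 6, C = 2), c(A = 2, C = 6)))
#' @export
weighted_fst <- function(counts, clamp_negative = FALSE) {
  stopifnot(is.list(counts), length(counts) >= 2L)
  alleles <- unique(unlist(lapply(counts, names)))
  if (is.null(alleles)) {
    # unnamed vectors: positions identify alleles
    len <- max(lengths(counts))
    counts <- lapply(counts, function(x) c(x, rep(0, len - length(x))))
    pooled <- Reduce(`+`, counts)
  } else {
    counts <- lapply(counts, function(x) {
      full <- stats::setNames(rep(0, length(alleles)), alleles)
      full[names(x)] <- x
      full
    })
    pooled <- Reduce(`+`, counts)
  }
  n_j <- vapply(counts, sum, numeric(1))
  if (any(n_j < 2)) return(NA_real_)
  pi_tot <- pi_site(pooled)
  if (is.na(pi_tot) || pi_tot == 0) return(NA_real_)
  w <- choose(n_j, 2)
  fst <- 1 - sum(w * vapply(counts, pi_site, numeric(1))) / (pi_tot * sum(w))
  if (clamp_negative) fst <- max(fst, 0)
  fst
}

# vectorised biallelic FST over sites: alt-allele counts c1, c2 and allele
# totals n1, n2 per population; returns list(fst, pi_p1, pi_p2, pi_total)
fst_biallelic <- function(c1, n1, c2, n2) {
  pi1 <- (n1^2 - c1^2 - (n1 - c1)^2) / (n1 * (n1 - 1))
  pi2 <- (n2^2 - c2^2 - (n2 - c2)^2) / (n2 * (n2 - 1))
  n <- n1 + n2
  ct <- c1 + c2
  pit <- (n^2 - ct^2 - (n - ct)^2) / (n * (n - 1))
  w1 <- n1 * (n1 - 1) / 2
  w2 <- n2 * (n2 - 1) / 2
  fst <- 1 - (w1 * pi1 + w2 * pi2) / (pit * (w1 + w2))
  list(fst = fst, pi_p1 = pi1, pi_p2 = pi2, pi_total = pit)
}

#' Gaussian kernel smoothing along one linkage group
#'
#' Distance-weighted moving average of a per-site statistic:
#' `smooth(c) = sum_k w_k x_k / sum_k w_k` over sites `k` with
#' `|pos_k - pos_c| <= 3 sigma`, with `w_k = exp(-(pos_k - pos_c)^2 / (2 sigma^2))`.
#' The focal site contributes with weight 1; weights beyond 3 sigma are
#' exactly zero, and smoothing never crosses linkage-group boundaries (this
#' function takes sites of a single group).
#'
#' @param pos sorted positions (bp) of the sites on one linkage group.
#' @param x per-site statistic (e.g. raw FST).
#' @param sigma_bp bandwidth in bp.
#' @return smoothed values, same length as `x`.
#' @export
kernel_smooth <- function(pos, x, sigma_bp = 50000) {
  stopifnot(length(pos) == length(x), sigma_bp > 0)
  if (length(pos) == 0L) return(numeric(0))
  if (is.unsorted(pos)) stop("positions must be sorted within a linkage group")
  d <- outer(pos, pos, `-`)
  w <- exp(-d^2 / (2 * sigma_bp^2))
  w[abs(d) > 3 * sigma_bp] <- 0
  as.numeric((w %*% x) / rowSums(w))
}

#' Flag empirical-quantile outliers
#'
#' Computes the genome-wide empirical quantile of the raw per-site FST values
#' (linear interpolation between order statistics, [stats::quantile()] type 7)
#' and flags sites whose FST is strictly above it.
#'
#' @param fst numeric vector of raw per-site FST values (length >= 2).
#' @param outlier_quantile quantile level, e.g. 0.999.
#' @return list with `threshold` and logical vector `outlier`.
#' @export
detect_outliers <- function(fst, outlier_quantile = 0.999) {
  stopifnot(length(fst) >= 2L)
  q <- unname(stats::quantile(fst, outlier_quantile, type = 7, na.rm = TRUE))
  list(threshold = q, outlier = !is.na(fst) & fst > q)
}

#' Genomic interval spanned by flagged outlier sites
#'
#' @param records scan data.frame (from [fst_scan()]) with columns `chrom`,
#'   `pos`, `outlier`.
#' @param chrom optional linkage group to restrict to.
#' @return data.frame with one row per linkage group carrying at least one
#'   flagged site: `chrom`, `start`, `end`, `width_bp`, `n_outliers`. Zero
#'   rows when nothing is flagged.
#' @export
outlier_interval <- function(records, chrom = NULL) {
  stopifnot(all(c("chrom", "pos", "outlier") %in% names(records)))
  flagged <- records[records$outlier, , drop = FALSE]
  if (!is.null(chrom)) flagged <- flagged[flagged$chrom %in% chrom, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      width_bp = integer(), n_outliers = integer()))
  }
  out <- do.call(rbind, lapply(split(flagged$pos, flagged$chrom), function(p) {
    data.frame(start = min(p), end = max(p), width_bp = max(p) - min(p),
               n_outliers = length(p))
  }))
  data.frame(chrom = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-linkage-group summary of a scan
#'
#' @param records scan data.frame with columns `chrom` and `fst`.
#' @return data.frame per linkage group: `n`, `mean`, `sd` (sample SD) and the
#'   five-number summary (`min`, `q25`, `median`, `q75`, `max`) of raw FST.
#' @export
summarize_by_lg <- function(records) {
  stopifnot(all(c("chrom", "fst") %in% names(records)))
  parts <- split(records$fst, factor(records$chrom, unique(records$chrom)))
  out <- do.call(rbind, lapply(parts, function(v) {
    v <- v[!is.na(v)]
    q <- unname(stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7))
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
  }))
  data.frame(chrom = names(parts), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Weighted FST genome scan between two populations
#'
#' For every site computes per-population allele counts, within-population and
#' pooled nucleotide diversity, observed/expected heterozygosity and the
#' sample-size-weighted FST; then kernel-smooths FST along each linkage group
#' and flags genome-wide empirical-quantile outliers on the *raw* FST values.
#' Sites where either population has fewer than two sampled alleles, or where
#' the pooled sample is monomorphic, are skipped (a message reports how many).
#'
#' @param gm a filtered [genotype_matrix].
#' @param pmap a [population_map] with exactly two population labels; the
#'   first label in order of appearance becomes population 1.
#' @param cfg a [scan_config].
#' @param clamp_negative floor negative FST estimates at zero (off by
#'   default; the weighted estimator legitimately goes negative).
#' @return data.frame of class `fst_scan` with one row per retained site:
#'   `chrom, pos, n_alleles_p1, n_alleles_p2, pi_p1, pi_p2, pi_total,
#'   hobs_p1, hobs_p2, hexp, fst, fst_smooth, outlier`, with the outlier
#'   threshold in attribute `"threshold"`.
#' @export
fst_scan <- function(gm, pmap, cfg = scan_config(), clamp_negative = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "scan_config"))
  pmap <- match_popmap(gm, pmap)
  pops <- unique(pmap$pop)
  if (length(pops) != 2L) stop("scan requires exactly two populations")
  r1 <- match(pmap$individual[pmap$pop == pops[1]], gm$individuals)
  r2 <- match(pmap$individual[pmap$pop == pops[2]], gm$individuals)

  g1 <- gm$calls[r1, , drop = FALSE]
  g2 <- gm$calls[r2, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(g1))
  n2 <- 2 * colSums(!is.na(g2))
  c1 <- colSums(g1, na.rm = TRUE)
  c2 <- colSums(g2, na.rm = TRUE)

  keep <- n1 >= 2 & n2 >= 2
  comp <- fst_biallelic(c1, n1, c2, n2)
  poly <- !is.na(comp$pi_total) & comp$pi_total > 0
  skip <- sum(!(keep & poly))
  if (skip > 0) {
    message(skip, " site(s) skipped (undersampled or pooled-monomorphic)")
  }
  keep <- which(keep & poly)

  p1 <- c1 / n1
  p2 <- c2 / n2
  pt <- (c1 + c2) / (n1 + n2)
  fst <- comp$fst
  if (clamp_negative) fst <- pmax(fst, 0)

  rec <- data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    n_alleles_p1 = n1, n_alleles_p2 = n2,
    pi_p1 = comp$pi_p1, pi_p2 = comp$pi_p2, pi_total = comp$pi_total,
    hobs_p1 = colMeans(g1 == 1L, na.rm = TRUE),
    hobs_p2 = colMeans(g2 == 1L, na.rm = TRUE),
    hexp = 1 - pt^2 - (1 - pt)^2,
    fst = fst, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rec) <- NULL

  rec$fst_smooth <- stats::ave(seq_len(nrow(rec)),
                               factor(rec$chrom, unique(rec$chrom)),
                               FUN = function(i) {
                                 kernel_smooth(rec$pos[i], rec$fst[i], cfg$sigma_bp)
                               })
  if (nrow(rec) >= 2L) {
    det <- detect_outliers(rec$fst, cfg$outlier_quantile)
    rec$outlier <- det$outlier
    attr(rec, "threshold") <- det$threshold
  } else {
    rec$outlier <- FALSE
    attr(rec, "threshold") <- NA_real_
  }
  attr(rec, "populations") <- pops
  class(rec) <- c("fst_scan", "data.frame")
  rec
}
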