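#' Site and genotype filter configuration
#'
#' Mirrors the Stacks-style filters applied ahead of any statistic:
#' a per-genotype minimum read depth (`-m`), a per-population call-rate
#' threshold (`-r`), presence of the site in every population (`-p`), a pooled
#' minor-allele-frequency cutoff (`--min_maf`, strict inequality) and a
#' user-supplied coordinate blacklist (`-B`). Rules are applied in the fixed,
#' documented order blacklist -> call rate -> presence in all populations ->
#' MAF, and each removed site is attributed to the first rule it fails.
#'
#' @param min_depth minimum per-genotype read depth; genotypes below it are
#'   masked to missing by [mask_low_depth()]. Default 5.
#' @param min_maf pooled minor-allele frequency a site must *exceed* to be
#'   kept. Default 0.01.
#' @param min_call_rate minimum fraction of non-missing genotypes required
#'   within *each* population (`>=`). Default 0.7.
#' @param require_all_pops require at least one non-missing genotype in every
#'   population. Default `TRUE`.
#' @param blacklist data.frame with columns `chrom`, `pos` of sites to drop,
#'   or `NULL`.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5L, min_maf = 0.01, min_call_rate = 0.7,
                          require_all_pops = TRUE, blacklist = NULL) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_call_rate >= 0, min_call_rate <= 1,
            min_depth >= 0, is.logical(require_all_pops))
  if (!is.null(blacklist)) {
    stopifnot(is.data.frame(blacklist), all(c("chrom", "pos") %in% names(blacklist)))
  }
  structure(list(min_depth = as.integer(min_depth), min_maf = min_maf,
                 min_call_rate = min_call_rate,
                 require_all_pops = require_all_pops, blacklist = blacklist),
            class = "filter_config")
}

#' Read a site blacklist
#'
#' Two-column tab- or whitespace-delimited text: linkage group, position.
#'
#' @param path path to the blacklist file.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_blacklist <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "pos"))
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Mask low-depth genotypes
#'
#' Sets genotype calls with read depth below `min_depth` to missing,
#' emulating the Stacks `-m` minimum stack depth applied per genotype.
#'
#' @param gm a [genotype_matrix] carrying depth.
#' @param min_depth minimum depth for a call to be kept.
#' @return the masked [genotype_matrix].
#' @export
mask_low_depth <- function(gm, min_depth = 5L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$depth)) {
    stop("genotype matrix has no depth; skip the depth-masking stage")
  }
  low <- !is.na(gm$depth) & gm$depth < min_depth
  gm$calls[low] <- NA_integer_
  gm
}

#' Filter sites against a two-population study
#'
#' Applies the configured site filters (see [filter_config()]) and returns the
#' surviving matrix together with a report attributing every removed site to
#' the first rule it failed, in application order.
#'
#' @param gm a [genotype_matrix].
#' @param pmap a [population_map] with exactly two population labels.
#' @param cfg a [filter_config].
#' @return list with elements `genotypes` (filtered [genotype_matrix]) and
#'   `report` (list: `n_input`, `n_output`, `removed` = per-rule counts in
#'   order blacklist, call_rate, all_pops, maf).
#' @export
filter_sites <- function(gm, pmap, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "filter_config"))
  pmap <- match_popmap(gm, pmap)
  pops <- unique(pmap$pop)
  if (length(pops) != 2L) {
    stop("filtering requires exactly two populations, got ", length(pops))
  }
  rows <- lapply(pops, function(p) match(pmap$individual[pmap$pop == p],
                                         gm$individuals))

  n_in <- n_sites(gm)
  failed <- rep(NA_character_, n_in)

  if (!is.null(cfg$blacklist)) {
    key <- paste(gm$sites$chrom, gm$sites$pos)
    bad <- key %in% paste(cfg$blacklist$chrom, cfg$blacklist$pos)
    failed[is.na(failed) & bad] <- "blacklist"
  }

  called <- lapply(rows, function(r) colSums(!is.na(gm$calls[r, , drop = FALSE])))
  low_rate <- called[[1]] / length(rows[[1]]) < cfg$min_call_rate |
    called[[2]] / length(rows[[2]]) < cfg$min_call_rate
  failed[is.na(failed) & low_rate] <- "call_rate"

  if (cfg$require_all_pops) {
    absent <- called[[1]] == 0L | called[[2]] == 0L
    failed[is.na(failed) & absent] <- "all_pops"
  }

  use <- match(pmap$individual, gm$individuals)
  sub <- gm$calls[use, , drop = FALSE]
  n_alleles <- 2L * colSums(!is.na(sub))
  alt <- colSums(sub, na.rm = TRUE)
  maf <- ifelse(n_alleles > 0, pmin(alt, n_alleles - alt) / n_alleles, 0)
  failed[is.na(failed) & maf <= cfg$min_maf] <- "maf"

  keep <- is.na(failed)
  report <- list(
    n_input = n_in,
    n_output = sum(keep),
    removed = list(blacklist = sum(failed == "blacklist", na.rm = TRUE),
                   call_rate = sum(failed == "call_rate", na.rm = TRUE),
                   all_pops = sum(failed == "all_pops", na.rm = TRUE),
                   maf = sum(failed == "maf", na.rm = TRUE)))
  out <- if (all(keep)) gm else subset_sites(gm, which(keep))
  list(genotypes = out, report = report)
}
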