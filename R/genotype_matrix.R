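#' Construct a genotype matrix
#'
#' The central container of the package: unphased diploid genotypes for a set
#' of individuals at a set of biallelic SNP sites, with optional per-genotype
#' read depth. Genotypes are stored as the count of copies of the alternate
#' allele (0, 1 or 2); missing genotypes are `NA`.
#'
#' Sites are kept sorted by position within each linkage group. If the input
#' site table is out of order within a linkage group it is sorted with a
#' warning; the relative order of linkage groups follows first appearance.
#'
#' @param sites data.frame with columns `chrom` (linkage-group identifier),
#'   `pos` (1-based base-pair coordinate), `ref` and `alt` (single-letter
#'   nucleotides) and optionally `id` (site name; defaults to `chrom_pos`).
#' @param individuals character vector of unique individual identifiers.
#' @param calls integer matrix, individuals x sites, entries in
#'   `c(0L, 1L, 2L, NA)` counting copies of the alternate allele.
#' @param depth optional non-negative integer matrix of per-genotype read
#'   depth, same dimensions as `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `individuals`, `calls`, `depth`.
#' @examples
#' sites <- data.frame(chrom = "LG1", pos = c(100L, 200L), ref = "A", alt = "C")
#' gm <- genotype_matrix(sites, c("i1", "i2"),
#'                       matrix(c(0L, 1L, 2L, NA), nrow = 2))
#' n_sites(gm)
#' @export
genotype_matrix <- function(sites, individuals, calls, depth = NULL) {
  stopifnot(is.data.frame(sites))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (is.null(sites$id)) sites$id <- paste(sites$chrom, sites$pos, sep = "_")
  sites <- sites[, c("chrom", "pos", "id", "ref", "alt")]

  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")

  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")

  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(individuals) || ncol(calls) != nrow(sites)) {
    stop(sprintf("calls must be %d individuals x %d sites, got %d x %d",
                 length(individuals), nrow(sites), nrow(calls), ncol(calls)))
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")

  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(calls))) {
      stop("depth must have the same dimensions as calls")
    }
    if (any(depth < 0L, na.rm = TRUE)) stop("depth must be non-negative")
  }

  # enforce sorted positions within each linkage group (chrom order preserved)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (is.unsorted(ord)) {
    warning("sites out of order within a linkage group; sorting by position")
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
    rownames(sites) <- NULL
  }
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) stop("duplicate site coordinates: ",
                     paste(sites$id[dup], collapse = ", "))

  dimnames(calls) <- list(individuals, sites$id)
  if (!is.null(depth)) dimnames(depth) <- dimnames(calls)

  structure(list(sites = sites, individuals = individuals,
                 calls = calls, depth = depth),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(gm) length(gm$individuals)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites on %d linkage group(s)\n",
              n_individuals(x), n_sites(x), length(unique(x$sites$chrom))))
  cat(sprintf("  missing genotypes: %.2f%%; depth: %s\n",
              100 * mean(is.na(x$calls)),
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

# keep a subset of site columns, preserving depth and invariants
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$sites[keep, , drop = FALSE], gm$individuals,
                  gm$calls[, keep, drop = FALSE],
                  if (!is.null(gm$depth)) gm$depth[, keep, drop = FALSE])
}

#' Construct a population map
#'
#' Assigns each individual to a population label and a binary phenotype code
#' using the PLINK convention: 1 = unaffected control (here, temperature-treated
#' but non-masculinized female), 2 = affected case (temperature-induced
#' pseudomale). A three-column map (individual, population, phenotype) drives
#' both the differentiation scan and the association test.
#'
#' @param individual character vector of individual ids (unique).
#' @param pop population labels; a scan requires exactly two distinct labels.
#' @param phenotype integer codes, 1 (control) or 2 (case).
#' @return data.frame of class `population_map` with columns
#'   `individual`, `pop`, `phenotype`.
#' @export
population_map <- function(individual, pop, phenotype) {
  individual <- as.character(individual)
  pop <- as.character(pop)
  phenotype <- as.integer(phenotype)
  if (anyDuplicated(individual)) {
    stop("duplicate individual id(s): ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  }
  if (!all(phenotype %in% c(1L, 2L))) {
    stop("phenotype codes must be 1 (control) or 2 (case)")
  }
  if (length(pop) != length(individual) || length(phenotype) != length(individual)) {
    stop("individual, pop and phenotype must have equal length")
  }
  structure(data.frame(individual = individual, pop = pop,
                       phenotype = phenotype, stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

# individuals shared between a genotype matrix and a popmap, erroring on
# an empty intersection; returns the popmap restricted and re-ordered
match_popmap <- function(gm, pmap) {
  keep <- pmap$individual %in% gm$individuals
  if (!any(keep)) stop("no individuals shared between genotypes and population map")
  pmap[keep, , drop = FALSE]
}
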