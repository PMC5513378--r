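#' Read genotypes from a VCF file
#'
#' Loads biallelic SNP records from a VCF (4.x) into a [genotype_matrix].
#' Genotypes are recoded as the count of alternate-allele copies; `./.` (or any
#' genotype containing a missing allele) becomes `NA`. Per-genotype `DP` is
#' loaded into the depth slot when the FORMAT declares it. Multi-allelic
#' records and non-SNP records (indels, symbolic alleles) are excluded, with
#' the number of exclusions reported via [message()]. Phase separators (`|`)
#' are accepted and discarded: all downstream analyses are phase-free.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_matrix].
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (is.null(v@gt) || ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)

  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  nuc <- c("A", "C", "G", "T")
  is_snp <- !is.na(fix$ALT) & fix$REF %in% nuc & fix$ALT %in% nuc
  n_excluded <- sum(!is_snp)
  if (n_excluded > 0) {
    message(n_excluded, " multi-allelic or non-SNP record(s) excluded at load")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  calls <- t(apply(gt, 2L, gt_to_dosage))
  if (nrow(gt) == 1L) calls <- matrix(calls, ncol = 1L,
                                      dimnames = list(colnames(gt), NULL))

  depth <- NULL
  if (any(grepl("(^|:)DP(:|$)", v@gt[, "FORMAT"]))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[is_snp, , drop = FALSE]
    depth <- t(dp)
    if (nrow(gt) == 1L) depth <- matrix(depth, ncol = 1L)
  }

  sites <- data.frame(chrom = fix$CHROM[is_snp],
                      pos = as.integer(fix$POS[is_snp]),
                      ref = fix$REF[is_snp], alt = fix$ALT[is_snp],
                      stringsAsFactors = FALSE)
  id <- fix$ID[is_snp]
  has_id <- !is.na(id) & id != "."
  sites$id <- ifelse(has_id, id, paste(sites$chrom, sites$pos, sep = "_"))

  genotype_matrix(sites, colnames(gt), calls, depth)
}

# "0/1", "1|0", "./." ... -> dosage of ALT allele (NA if any allele missing)
gt_to_dosage <- function(gt) {
  codes <- unique(gt[!is.na(gt)])
  lookup <- vapply(codes, function(g) {
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(alleles == ".") || length(alleles) != 2L) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1))
  out <- lookup[gt]
  names(out) <- NULL
  out
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with `GT` (and `DP` when depth is present) per
#' genotype. The round trip `read_vcf(write_vcf(gm))` reproduces calls, depth,
#' positions and alleles exactly. Genotypes are written unphased (`0/0`, `0/1`,
#' `1/1`, `./.`).
#'
#' @param gm a non-empty [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_sites(gm) == 0L || n_individuals(gm) == 0L) {
    stop("refusing to write an empty genotype matrix")
  }
  has_dp <- !is.null(gm$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tsdscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t"))

  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_sites(gm)), function(j) {
    g <- gm$calls[, j]
    cell <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    if (has_dp) {
      d <- gm$depth[, j]
      cell <- paste(cell, ifelse(is.na(d), ".", d), sep = ":")
    }
    paste(c(gm$sites$chrom[j], gm$sites$pos[j], gm$sites$id[j],
            gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", cell), collapse = "\t")
  }, character(1))

  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read and write population maps
#'
#' A population map is a whitespace- or tab-delimited three-column text file:
#' individual id, population label, phenotype code (1 = control, 2 = case).
#' It is a superset of the two-column Stacks popmap, so a single file drives
#' both the differentiation scan and the case-control association test.
#'
#' @param path path to the map file.
#' @return [read_popmap()] returns a [population_map];
#'   [write_popmap()] returns `path` invisibly.
#' @export
read_popmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields != 3L)) {
    stop("popmap line ", which(n_fields != 3L)[1],
         " does not have 3 fields (individual, population, phenotype)")
  }
  m <- do.call(rbind, fields)
  pheno_raw <- m[, 3]
  bad <- !pheno_raw %in% c("1", "2")
  if (any(bad)) {
    stop("popmap line ", which(bad)[1], ": phenotype code '",
         pheno_raw[which(bad)[1]], "' is not 1 or 2")
  }
  population_map(m[, 1], m[, 2], as.integer(pheno_raw))
}

#' @rdname read_popmap
#' @param pmap a [population_map].
#' @export
write_popmap <- function(pmap, path) {
  utils::write.table(as.data.frame(pmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
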