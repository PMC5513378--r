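#' Write scan or association results as a tab-separated table
#'
#' Result tables use fixed headers. Differentiation-scan records are written
#' with columns `CHR, BP, N_ALLELES_P1, N_ALLELES_P2, PI_P1, PI_P2, PI_TOTAL,
#' HOBS_P1, HOBS_P2, HEXP, FST, FST_SMOOTH, OUTLIER`; association records with
#' the PLINK-compatible columns `CHR, SNP, BP, A1, F_A, F_U, A2, CHISQ, P, OR,
#' L95, U95` plus `P_BONF`. The record type is detected from the columns; a
#' data.frame matching neither schema is an error.
#'
#' @param records a data.frame of scan records (from [fst_scan()]) or
#'   association records (from [assoc_scan()]), or an `assoc_scan` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (inherits(records, "assoc_scan")) records <- records$records
  stopifnot(is.data.frame(records))
  if (all(scan_cols$internal %in% names(records))) {
    out <- records[, scan_cols$internal, drop = FALSE]
    names(out) <- scan_cols$header
    out$OUTLIER <- as.integer(out$OUTLIER)
  } else if (all(assoc_cols$internal %in% names(records))) {
    out <- records[, assoc_cols$internal, drop = FALSE]
    names(out) <- assoc_cols$header
  } else {
    stop("records match neither the scan nor the association table schema")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

scan_cols <- list(
  internal = c("chrom", "pos", "n_alleles_p1", "n_alleles_p2", "pi_p1",
               "pi_p2", "pi_total", "hobs_p1", "hobs_p2", "hexp", "fst",
               "fst_smooth", "outlier"),
  header = c("CHR", "BP", "N_ALLELES_P1", "N_ALLELES_P2", "PI_P1", "PI_P2",
             "PI_TOTAL", "HOBS_P1", "HOBS_P2", "HEXP", "FST", "FST_SMOOTH",
             "OUTLIER"))

assoc_cols <- list(
  internal = c("chrom", "snp", "pos", "a1", "f_a", "f_u", "a2", "chisq", "p",
               "or", "l95", "u95", "p_bonf"),
  header = c("CHR", "SNP", "BP", "A1", "F_A", "F_U", "A2", "CHISQ", "P", "OR",
             "L95", "U95", "P_BONF"))

#' Read back result tables written by [write_table()]
#'
#' @param path path to a scan or association TSV.
#' @return data.frame with the package-internal column names.
#' @export
read_scan_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), scan_cols$header)) {
    stop("'", path, "' is not a scan table")
  }
  names(tab) <- scan_cols$internal
  tab$outlier <- as.logical(tab$outlier)
  tab
}

#' @rdname read_scan_table
#' @export
read_assoc_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(CHR = "character", A1 = "character",
                                          A2 = "character", SNP = "character"))
  if (!identical(names(tab), assoc_cols$header)) {
    stop("'", path, "' is not an association table")
  }
  names(tab) <- assoc_cols$internal
  tab
}
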