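#' Find restriction recognition sites on one strand
#'
#' Returns every (possibly overlapping) 1-based start position of `pattern`
#' in `seq`. `N` bases never match. For Taq-alpha-I the recognition sequence
#' TCGA is its own reverse complement, so a single-strand search covers both
#' strands.
#'
#' @param seq nucleotide string over `A, C, G, T, N`.
#' @param pattern recognition sequence over `A, C, G, T`.
#' @return integer vector of start positions (empty when absent).
#' @examples
#' find_sites("AATCGAA", "TCGA")
#' find_sites("TCGATCGA", "TCGA")
#' @export
find_sites <- function(seq, pattern) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains non-nucleotide characters (other than N)")
  }
  if (grepl("[^ACGT]", pattern)) stop("pattern must be over A, C, G, T")
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = TRUE)
  Biostrings::start(m)
}

# "TCGA@1" -> list(pattern, offset); Taq-alpha-I default
parse_enzyme <- function(enzyme) {
  if (is.list(enzyme)) return(enzyme)
  parts <- strsplit(enzyme, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("enzyme spec must be 'PATTERN@offset'")
  offset <- suppressWarnings(as.integer(parts[2]))
  if (is.na(offset) || offset < 0L || offset > nchar(parts[1])) {
    stop("cut offset must lie within the recognition pattern")
  }
  list(pattern = parts[1], offset = offset)
}

#' In-silico restriction digest of an amplicon
#'
#' Locates recognition sites, derives cut coordinates as site start + offset,
#' and returns the ordered fragment lengths between successive cuts and the
#' amplicon ends. Fragment lengths always sum to the amplicon length.
#'
#' @param seq amplicon nucleotide string.
#' @param enzyme enzyme spec `"PATTERN@offset"` (default `"TCGA@1"`,
#'   Taq-alpha-I cutting T^CGA) or a list with `pattern` and `offset`.
#' @return list of class `digest_result` with `enzyme`, `cut_positions` and
#'   `fragment_lengths`.
#' @examples
#' digest("AATCGAA")  # fragments 4 and 3
#' @export
digest <- function(seq, enzyme = "TCGA@1") {
  enz <- parse_enzyme(enzyme)
  len <- nchar(seq)
  cuts <- find_sites(seq, enz$pattern) + enz$offset
  cuts <- cuts[cuts >= 1L & cuts < len]
  structure(list(enzyme = enz, cut_positions = cuts,
                 fragment_lengths = diff(c(0L, cuts, len))),
            class = "digest_result")
}

#' Classify amh / amh-deltaY status from digest fragment patterns
#'
#' The Y-specific amh-deltaY allele carries a 5 bp exon-VI insertion (ATGTC)
#' creating a Taq-alpha-I site, so its 1252 bp amplicon digests into ~829 and
#' ~423 bp fragments while amh (and amhy) amplicons stay uncut. Given the
#' fragment-length lists observed for one individual's amplicon pool, the
#' call is: only uncut amplicons -> `no_amhdy`; only the cleaved pattern ->
#' `amhdy_present`; both -> `amhdy_heterozygous_pattern`; anything else ->
#' `ambiguous`. Fragment sizes are matched within `tolerance_bp` (gel-reading
#' tolerance); the cleaved pair is accepted in either order.
#'
#' @param fragments list of numeric vectors, one per observed amplicon
#'   pattern.
#' @param uncut_length expected uncut amplicon length (default 1252).
#' @param cut_lengths expected cleaved fragment pair (default `c(829, 423)`).
#' @param tolerance_bp size-matching tolerance (default 10).
#' @return one of `"no_amhdy"`, `"amhdy_present"`,
#'   `"amhdy_heterozygous_pattern"`, `"ambiguous"`.
#' @export
classify_amh <- function(fragments, uncut_length = 1252,
                         cut_lengths = c(829, 423), tolerance_bp = 10) {
  if (!is.list(fragments) || length(fragments) == 0L) {
    stop("fragments must be a non-empty list of fragment-length vectors")
  }
  near <- function(x, y) abs(x - y) <= tolerance_bp
  is_uncut <- vapply(fragments, function(f) {
    length(f) == 1L && near(f, uncut_length)
  }, logical(1))
  is_cut <- vapply(fragments, function(f) {
    length(f) == 2L && (all(near(f, cut_lengths)) || all(near(f, rev(cut_lengths))))
  }, logical(1))
  if (any(!is_uncut & !is_cut)) return("ambiguous")
  if (all(is_uncut)) return("no_amhdy")
  if (all(is_cut)) return("amhdy_present")
  "amhdy_heterozygous_pattern"
}

#' Call genetic sex from the LG1 marker genotypes
#'
#' In populations with an LG1 XX/XY system, genetic females carry G/G and T/T
#' at loci Oni23063 and Oni28137 while genetic males are heterozygous A/G and
#' G/T. Any other combination is reported as inconsistent with the LG1 rules.
#'
#' @param genotype_23063 unordered allele pair at Oni23063, as `"G/G"` or
#'   `c("G", "G")`.
#' @param genotype_28137 unordered allele pair at Oni28137.
#' @return `"XX_consistent"`, `"XY_consistent"` or `"inconsistent"`.
#' @examples
#' call_lg1_sex("G/G", "T/T")
#' call_lg1_sex("A/G", "T/G")
#' @export
call_lg1_sex <- function(genotype_23063, genotype_28137) {
  norm <- function(g, locus) {
    if (is.character(g) && length(g) == 1L) g <- strsplit(g, "/", fixed = TRUE)[[1]]
    g <- toupper(g)
    if (length(g) != 2L || !all(g %in% c("A", "C", "G", "T"))) {
      stop("malformed genotype for ", locus, ": expected two alleles in A/C/G/T")
    }
    paste(sort(g), collapse = "/")
  }
  g1 <- norm(genotype_23063, "Oni23063")
  g2 <- norm(genotype_28137, "Oni28137")
  if (g1 == "G/G" && g2 == "T/T") return("XX_consistent")
  if (g1 == "A/G" && g2 == "G/T") return("XY_consistent")
  "inconsistent"
}

#' Synthetic amh / amh-deltaY amplicon pair
#'
#' The real amplicon sequence is not published, so this generator builds a
#' synthetic stand-in pair reproducing the assay's observable behaviour: a
#' 1252 bp `amh` amplicon free of Taq-alpha-I (TCGA) sites, and a 1252 bp
#' `amhdy` amplicon derived from the same core by inserting the 5 bp ATGTC
#' motif immediately before a GA dinucleotide, which creates exactly one TCGA
#' site positioned so the cut coordinate is 829 from the 5' end (fragments
#' 829 + 423 bp). Orientation of the long fragment is a convention;
#' [classify_amh()] accepts either order.
#'
#' @param seed optional integer seed for reproducible sequences.
#' @param length_bp amplicon length (default 1252).
#' @param cut_at cut coordinate for the deltaY allele (default 829).
#' @return list with character sequences `amh` and `amhdy`.
#' @export
amh_amplicon_set <- function(seed = NULL, length_bp = 1252L, cut_at = 829L) {
  stopifnot(cut_at > 5L, cut_at < length_bp - 1L)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  core_len <- length_bp - 5L
  ins_at <- cut_at - 4L  # ATGTC occupies ins_at..ins_at+4; TCGA starts at cut_at - 1
  repeat {
    core <- sample(bases, core_len, replace = TRUE)
    core[ins_at:(ins_at + 1L)] <- c("G", "A")  # dinucleotide completing TCGA
    core_str <- paste(core, collapse = "")
    if (length(find_sites(core_str, "TCGA")) > 0L) next
    amhdy <- paste0(substr(core_str, 1L, ins_at - 1L), "ATGTC",
                    substr(core_str, ins_at, core_len))
    if (!identical(find_sites(amhdy, "TCGA"), cut_at - 1L)) next
    tail5 <- paste(sample(bases, 5L, replace = TRUE), collapse = "")
    amh <- paste0(core_str, tail5)
    if (length(find_sites(amh, "TCGA")) > 0L) next
    break
  }
  list(amh = amh, amhdy = amhdy)
}

#' Read amplicons from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_amplicons <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
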