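#' Configuration of a synthetic temperature-masculinization study
#'
#' Describes a full synthetic study matching the design the analysis assumes:
#' several full-sib families of genetically female (XX) fish, each founded by
#' one temperature-induced pseudomale sire and one treated dam, contributing a
#' fixed number of temperature-masculinized cases and non-masculinized
#' controls; a causal biallelic locus whose genotype sets the masculinization
#' penetrance under treatment; and neutral SNPs spread along the linkage
#' groups, linked through Mendelian transmission with a Haldane map.
#'
#' Defaults reproduce the reference study design: 3 families x (20 cases +
#' 20 controls), 22 linkage groups (numbered to LG23 with LG21 absent, as in
#' the tilapia assembly), a causal C/G locus on LG23 at 9,441,132 bp with
#' penetrances CC 0.853, CG 0.368, GG 0.0, 400 uniformly spaced SNPs per
#' 40 Mb linkage group, 3 cM/Mb, 5% missing genotypes and Poisson(20) depth.
#'
#' @param n_families number of full-sib families.
#' @param n_cases_per_family,n_controls_per_family sampled offspring per
#'   family and class.
#' @param n_linkage_groups,lg_length_bp,snps_per_lg genome layout.
#' @param causal_lg,causal_pos_bp coordinate of the causal locus; the nearest
#'   uniformly spaced SNP on `causal_lg` is moved to `causal_pos_bp`, keeping
#'   the total site count at `n_linkage_groups * snps_per_lg`.
#' @param causal_alleles ordered pair `c(masculinizing, protective)`.
#' @param penetrance named probabilities of masculinization under treatment
#'   for the three causal genotypes (names built from `causal_alleles`).
#' @param cm_per_mb recombination rate (centimorgan per megabase).
#' @param founder_maf_range interval from which each neutral site's founder
#'   allele frequency is drawn.
#' @param missing_rate per-genotype missingness probability.
#' @param mean_depth mean of the Poisson read-depth distribution.
#' @param positions `"uniform"` (equal spacing; analytic smoothing windows)
#'   or `"random"` (uniform-random positions).
#' @param seed integer seed making the whole study reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 3L, n_cases_per_family = 20L,
                       n_controls_per_family = 20L, n_linkage_groups = 22L,
                       lg_length_bp = 40e6, snps_per_lg = 400L,
                       causal_lg = "LG23", causal_pos_bp = 9441132L,
                       causal_alleles = c("C", "G"),
                       penetrance = c(CC = 0.853, CG = 0.368, GG = 0.0),
                       cm_per_mb = 3.0, founder_maf_range = c(0.05, 0.5),
                       missing_rate = 0.05, mean_depth = 20,
                       positions = c("uniform", "random"), seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              n_cases_per_family = as.integer(n_cases_per_family),
              n_controls_per_family = as.integer(n_controls_per_family),
              n_linkage_groups = as.integer(n_linkage_groups),
              lg_length_bp = lg_length_bp, snps_per_lg = as.integer(snps_per_lg),
              causal_lg = causal_lg, causal_pos_bp = as.integer(causal_pos_bp),
              causal_alleles = causal_alleles, penetrance = penetrance,
              cm_per_mb = cm_per_mb, founder_maf_range = founder_maf_range,
              missing_rate = missing_rate, mean_depth = mean_depth,
              positions = match.arg(positions, c("uniform", "random")),
              seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1L, cfg$n_cases_per_family >= 0L,
            cfg$n_controls_per_family >= 0L, cfg$n_linkage_groups >= 1L,
            cfg$snps_per_lg >= 1L, cfg$lg_length_bp >= cfg$snps_per_lg,
            cfg$causal_pos_bp >= 1L, cfg$causal_pos_bp <= cfg$lg_length_bp,
            length(cfg$causal_alleles) == 2L,
            cfg$causal_alleles[1] != cfg$causal_alleles[2],
            all(cfg$penetrance >= 0), all(cfg$penetrance <= 1),
            length(cfg$founder_maf_range) == 2L,
            cfg$founder_maf_range[1] >= 0, cfg$founder_maf_range[2] <= 0.5,
            diff(cfg$founder_maf_range) >= 0,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$mean_depth >= 0, cfg$cm_per_mb >= 0)
  keys <- genotype_keys(cfg$causal_alleles)
  if (!all(keys %in% names(cfg$penetrance))) {
    stop("penetrance must be named for all three causal genotypes: ",
         paste(keys, collapse = ", "))
  }
  if (!cfg$causal_lg %in% lg_names(cfg)) {
    stop("causal_lg '", cfg$causal_lg, "' is not among the simulated linkage groups")
  }
  structure(cfg, class = "sim_config")
}

# genotype keys (protective-hom, het, masculinizing-hom order not assumed):
# built by sorting allele letters within a genotype
genotype_keys <- function(alleles) {
  m <- alleles[1]; p <- alleles[2]
  c(paste(rep(p, 2), collapse = ""),
    paste(sort(c(m, p)), collapse = ""),
    paste(rep(m, 2), collapse = ""))
}

# linkage-group names: numbered to 23 skipping LG21 for the default 22-group
# genome (tilapia convention); plain LG1..LGn otherwise
lg_names <- function(cfg) {
  n <- cfg$n_linkage_groups
  if (n == 22L && identical(cfg$causal_lg, "LG23")) {
    paste0("LG", setdiff(1:23, 21L))
  } else {
    paste0("LG", seq_len(n))
  }
}

#' Haldane map function
#'
#' Recombination fraction between two loci separated by `d_cm` centimorgan
#' under a no-interference (Haldane) map: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cm genetic distance in centimorgan.
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(3)  # 1 Mb at 3 cM/Mb
#' @export
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' Build the founder generation of a synthetic study
#'
#' Lays out the site map and draws, for every family, two diploid founders
#' (sire and dam, both genetically XX) as two haplotypes each over all
#' linkage groups. Neutral alleles are drawn per haplotype from a per-site
#' founder frequency sampled once from `founder_maf_range`; at the causal
#' site every founder is heterozygous (masculinizing/protective), so all
#' three offspring genotypes segregate in every family.
#'
#' @param cfg a [sim_config]. The caller controls the RNG state (this
#'   function does not seed).
#' @return list with `sites` (site table including `freq` and the alternate
#'   allele = masculinizing allele at the causal site), `causal_index`, and
#'   `families`: per family a list with `sire` and `dam`, each a 2 x n_sites
#'   0/1 haplotype matrix (1 = alternate allele).
#' @export
make_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- lg_names(cfg)
  s <- cfg$snps_per_lg
  pos1 <- if (cfg$positions == "uniform") {
    as.integer(round(cfg$lg_length_bp / s) * seq_len(s))
  } else NULL

  sites <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- if (is.null(pos1)) sort(sample.int(cfg$lg_length_bp, s)) else pos1
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))

  # drop the causal LG's nearest site onto the causal coordinate
  on_lg <- which(sites$chrom == cfg$causal_lg)
  causal_index <- on_lg[which.min(abs(sites$pos[on_lg] - cfg$causal_pos_bp))]
  sites$pos[causal_index] <- cfg$causal_pos_bp
  sites <- sites[order(match(sites$chrom, chroms), sites$pos), ]
  rownames(sites) <- NULL
  causal_index <- which(sites$chrom == cfg$causal_lg &
                          sites$pos == cfg$causal_pos_bp)

  n_sites <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  # causal site: alt = masculinizing allele, ref = protective allele
  alt[causal_index] <- cfg$causal_alleles[1]
  ref[causal_index] <- cfg$causal_alleles[2]
  sites$ref <- unname(ref)
  sites$alt <- unname(alt)
  sites$id <- paste(sites$chrom, sites$pos, sep = "_")
  sites$freq <- stats::runif(n_sites, cfg$founder_maf_range[1],
                             cfg$founder_maf_range[2])
  sites$freq[causal_index] <- 0.5

  families <- lapply(seq_len(cfg$n_families), function(f) {
    founder <- function() {
      h <- matrix(stats::rbinom(2L * n_sites, 1L, rep(sites$freq, each = 2L)),
                  nrow = 2L)
      h[, causal_index] <- c(1L, 0L)  # heterozygous by construction
      h
    }
    list(sire = founder(), dam = founder())
  })

  list(sites = sites, causal_index = causal_index, families = families)
}

# inter-site recombination fractions, 0.5 across linkage-group boundaries
# (independent assortment realised as a fair switch)
recomb_fractions <- function(sites, cfg) {
  n <- nrow(sites)
  if (n < 2L) return(numeric(0))
  same <- sites$chrom[-1] == sites$chrom[-n]
  d_cm <- (sites$pos[-1] - sites$pos[-n]) / 1e6 * cfg$cm_per_mb
  ifelse(same, haldane_r(d_cm), 0.5)
}

#' Simulate one meiosis
#'
#' Produces a gamete haplotype from a diploid parent: within each linkage
#' group the starting haplotype is chosen uniformly and the copied haplotype
#' switches between adjacent sites with the Haldane recombination fraction
#' `r = (1 - exp(-2 d / 100)) / 2`, `d` in centimorgan from the physical
#' spacing and `cm_per_mb`. Linkage groups assort independently.
#'
#' @param parent 2 x n_sites haplotype matrix (rows = the parent's two
#'   haplotypes).
#' @param sites site table (columns `chrom`, `pos`) matching the columns of
#'   `parent`.
#' @param cfg a [sim_config] (only `cm_per_mb` is used).
#' @param r optional precomputed inter-site recombination fractions (length
#'   n_sites - 1), as returned by the internal layout; supplying it avoids
#'   recomputation in tight loops.
#' @return integer vector: the gamete's allele (0/1) at every site.
#' @export
meiosis <- function(parent, sites, cfg, r = NULL) {
  n <- ncol(parent)
  if (is.null(r)) r <- recomb_fractions(sites, cfg)
  start <- stats::rbinom(1L, 1L, 0.5)
  switches <- if (n > 1L) stats::rbinom(n - 1L, 1L, r) else integer(0)
  hap <- (start + cumsum(c(0L, switches))) %% 2L
  parent[cbind(hap + 1L, seq_len(n))]
}

#' Draw a masculinization outcome from a causal genotype
#'
#' Bernoulli draw with the genotype's penetrance: the probability that a
#' treated individual of that causal genotype develops as a male.
#'
#' @param genotype causal genotype key(s), e.g. `"CC"`, `"CG"`, `"GG"`
#'   (alleles in sorted order).
#' @param penetrance named probability vector covering all genotypes present.
#' @return logical vector: `TRUE` = masculinized, `FALSE` = female.
#' @export
assign_phenotype <- function(genotype,
                             penetrance = c(CC = 0.853, CG = 0.368, GG = 0.0)) {
  unknown <- setdiff(unique(genotype), names(penetrance))
  if (length(unknown) > 0) {
    stop("no penetrance defined for genotype(s): ", paste(unknown, collapse = ", "))
  }
  unname(stats::runif(length(genotype)) < penetrance[genotype])
}

#' Simulate a complete synthetic study
#'
#' Generates offspring family by family — each a Mendelian cross of the two
#' founders via [meiosis()] — assigning the masculinization outcome from the
#' causal genotype's penetrance, until the configured number of cases
#' (masculinized) and controls (female) per family is collected. Per-genotype
#' read depth is Poisson(`mean_depth`); each genotype is independently set
#' missing with probability `missing_rate` (its depth then 0). The whole
#' study is a deterministic function of the configuration, including its
#' seed.
#'
#' @param cfg a [sim_config].
#' @return list with `genotypes` (a [genotype_matrix]), `popmap` (a
#'   [population_map]; cases are population `"pseudomale"`, phenotype 2,
#'   controls `"female"`, phenotype 1), `truth` (data.frame: individual,
#'   family, causal chrom/pos, causal genotype, outcome) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fdr <- make_founders(cfg)
  sites <- fdr$sites
  ci <- fdr$causal_index
  r <- recomb_fractions(sites, cfg)
  keys <- genotype_keys(cfg$causal_alleles)  # dosage 0, 1, 2 of masculinizing allele
  pen <- cfg$penetrance

  n_fam_off <- cfg$n_cases_per_family + cfg$n_controls_per_family
  per_family <- lapply(seq_len(cfg$n_families), function(f) {
    fam <- fdr$families[[f]]
    calls <- matrix(NA_integer_, nrow = n_fam_off, ncol = nrow(sites))
    geno <- character(n_fam_off)
    outcome <- logical(n_fam_off)
    n_case <- 0L; n_ctrl <- 0L
    attempts <- 0L
    max_attempts <- 1000L + 200L * n_fam_off
    while ((n_case < cfg$n_cases_per_family ||
            n_ctrl < cfg$n_controls_per_family) && attempts < max_attempts) {
      attempts <- attempts + 1L
      g <- meiosis(fam$sire, sites, cfg, r) + meiosis(fam$dam, sites, cfg, r)
      key <- keys[g[ci] + 1L]
      masc <- assign_phenotype(key, pen)
      if (masc && n_case < cfg$n_cases_per_family) {
        n_case <- n_case + 1L
        slot <- n_case
      } else if (!masc && n_ctrl < cfg$n_controls_per_family) {
        n_ctrl <- n_ctrl + 1L
        slot <- cfg$n_cases_per_family + n_ctrl
      } else {
        next
      }
      calls[slot, ] <- g
      geno[slot] <- key
      outcome[slot] <- masc
    }
    if (n_case < cfg$n_cases_per_family || n_ctrl < cfg$n_controls_per_family) {
      stop("family ", f, ": could not collect ", cfg$n_cases_per_family,
           " cases and ", cfg$n_controls_per_family, " controls within ",
           max_attempts, " offspring; check the penetrance configuration")
    }
    ids <- c(sprintf("fam%d_case%02d", f, seq_len(cfg$n_cases_per_family)),
             sprintf("fam%d_ctrl%02d", f, seq_len(cfg$n_controls_per_family)))
    list(calls = calls, ids = ids, geno = geno, outcome = outcome,
         family = rep(f, n_fam_off))
  })

  calls <- do.call(rbind, lapply(per_family, `[[`, "calls"))
  ids <- unlist(lapply(per_family, `[[`, "ids"))
  n_ind <- length(ids)
  n_st <- nrow(sites)

  depth <- matrix(stats::rpois(n_ind * n_st, cfg$mean_depth),
                  nrow = n_ind, ncol = n_st)
  miss <- matrix(stats::runif(n_ind * n_st) < cfg$missing_rate,
                 nrow = n_ind, ncol = n_st)
  calls[miss] <- NA_integer_
  depth[miss] <- 0L

  truth <- data.frame(
    individual = ids,
    family = unlist(lapply(per_family, `[[`, "family")),
    chrom = cfg$causal_lg, pos = cfg$causal_pos_bp,
    causal_genotype = unlist(lapply(per_family, `[[`, "geno")),
    masculinized = unlist(lapply(per_family, `[[`, "outcome")),
    stringsAsFactors = FALSE)

  pmap <- population_map(ids,
                         ifelse(truth$masculinized, "pseudomale", "female"),
                         ifelse(truth$masculinized, 2L, 1L))

  gm <- genotype_matrix(sites[, c("chrom", "pos", "id", "ref", "alt")],
                        ids, calls, depth)
  list(genotypes = gm, popmap = pmap, truth = truth, config = cfg)
}

#' Write the truth table of a simulated study
#'
#' @param truth the `truth` element of [simulate_dataset()]'s result.
#' @param path output path (TSV with header).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
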