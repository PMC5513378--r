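# small in-code fixtures shared across test files

# genotype matrix from a compact spec: one string per individual, one char
# per site ('0','1','2' or '.'), default alleles ref=G / alt=C everywhere
make_gm <- function(geno_strings, chrom = "LG1", pos = NULL, ref = "G",
                    alt = "C", depth = NULL, ids = NULL) {
  rows <- lapply(strsplit(geno_strings, ""), function(ch) {
    as.integer(ifelse(ch == ".", NA, ch))
  })
  calls <- do.call(rbind, rows)
  n_st <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_st) * 1000L
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(nrow(calls)))
  sites <- data.frame(chrom = rep_len(chrom, n_st), pos = pos,
                      ref = rep_len(ref, n_st), alt = rep_len(alt, n_st),
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, ids, calls, depth)
}

# two-population map over the individuals of a genotype matrix: first half
# cases (pop "case", phenotype 2), second half controls
make_pmap <- function(gm, n_case = ceiling(n_individuals(gm) / 2)) {
  n <- n_individuals(gm)
  population_map(gm$individuals,
                 rep(c("case", "control"), c(n_case, n - n_case)),
                 rep(c(2L, 1L), c(n_case, n - n_case)))
}

# memoised default-configuration simulation (seed 1), shared where a full
# study is needed but its identity does not matter
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 1))
    cache
  }
})

# a small, fast simulation configuration: 2 linkage groups, causal on LG2
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_families = 3L, n_cases_per_family = 10L,
               n_controls_per_family = 10L, n_linkage_groups = 2L,
               lg_length_bp = 10e6, snps_per_lg = 50L, causal_lg = "LG2",
               causal_pos_bp = 5e6, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
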