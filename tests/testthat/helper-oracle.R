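# brute-force pairwise-difference oracle for the weighted fixation index:
# enumerates every allele pair within each population and in the pooled
# sample, independent of the closed-form path in the package

brute_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      diff_pairs <- diff_pairs + (alleles[i] != alleles[j])
    }
  }
  diff_pairs / choose(n, 2)
}

brute_weighted_fst <- function(counts) {
  pops <- lapply(counts, function(x) rep(names(x), x))
  n_j <- lengths(pops)
  pi_j <- vapply(pops, brute_pi, numeric(1))
  pi_tot <- brute_pi(unlist(pops))
  if (any(n_j < 2) || is.na(pi_tot) || pi_tot == 0) return(NA_real_)
  w <- choose(n_j, 2)
  1 - sum(w * pi_j) / (pi_tot * sum(w))
}

# random biallelic two-population allele counts with n_j <= max_n alleles
random_counts <- function(max_n = 12) {
  make_pop <- function() {
    n <- sample(2:max_n, 1)
    k <- sample(0:n, 1)
    c(A = k, C = n - k)
  }
  list(make_pop(), make_pop())
}
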