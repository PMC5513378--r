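---
title: "Mapping temperature-dependent sex reversal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping temperature-dependent sex reversal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdscan)
```

## The problem

In Nile tilapia, genetic sex determination (XX/XY, with the male-determining
*amh* duplication on LG23 in some populations) can be overridden by
temperature: rearing genetically female (XX) fry at 36&nbsp;°C during days
10&ndash;20 post fertilisation masculinizes a heritable fraction into fertile
pseudomales. `tsdscan` locates the genomic region underlying that
sensitivity by contrasting SNP genotypes of temperature-masculinized
pseudomales with their temperature-treated but non-masculinized full sisters,
via two complementary per-site analyses: a differentiation
(F~ST~) outlier scan and a case-control allelic association test. Because the
two groups are full sibs split by phenotype, any locus influencing
sensitivity shows an allele-frequency shift between them, while the rest of
the genome differs only by Mendelian sampling noise.

## The differentiation scan

At a biallelic site, the within-population nucleotide diversity is the
single-site average pairwise difference

$$\pi_j = \frac{\sum_{a<b} c_j(a)\,c_j(b)}{\binom{n_j}{2}},$$

with $c_j(a)$ the count of allele $a$ and $n_j$ the number of alleles
sampled (twice the genotyped individuals) in population $j$. The fixation
index compares within-population to pooled diversity, weighting populations
by their number of allele pairs so that unequal sample sizes are handled
without bias toward the smaller group:

$$F_{ST} \;=\; 1 \;-\;
\frac{\sum_j \binom{n_j}{2}\,\pi_j}{\pi_\cdot\,\sum_j \binom{n_j}{2}}.$$

Three numerical decisions matter:

* **Negative values are reported, not clamped.** The estimator goes negative
  when within-population diversity exceeds pooled diversity, as happens by
  chance in small samples. Clamping at zero would bias genome-wide means
  upward; a `clamp_negative` option reproduces the clamped convention where
  needed.
* **Undefined sites are skipped, with a logged count**: any population with
  fewer than two sampled alleles, or a pooled-monomorphic site
  ($\pi_\cdot = 0$). The MAF filter normally removes the latter first.
* **`weighted_fst()` accepts more than two populations and multi-allelic
  counts**; the vectorised scan path is biallelic/two-population, and the
  two implementations are held together by a brute-force pair-enumeration
  oracle in the test suite (agreement to $10^{-12}$).

Raw per-site F~ST~ is then smoothed along each linkage group with a
Gaussian kernel, $w_k = \exp(-(p_k-p_c)^2/2\sigma^2)$, truncated **hard** at
$3\sigma$ (weights beyond are exactly zero) and never crossing a
linkage-group boundary. The default $\sigma = 50$&nbsp;kb gives a 150&nbsp;kb
half-window, matching the scale at which family-based linkage
disequilibrium makes neighbouring ddRAD SNPs informative about the same
signal. Smoothing is a convex combination, so smoothed values stay inside
the local range of raw values.

Outliers are sites whose **raw** (not smoothed) F~ST~ lies strictly above
the genome-wide empirical quantile (default 99.9&nbsp;%). With roughly
$10^4$&ndash;$2\times10^4$ sites the quantile definition is not innocent; we
fix linear interpolation between order statistics (`stats::quantile`
type&nbsp;7, the common default of scientific software) and document that
a run of identical values yields zero outliers under the strict inequality.
The outlier quantile is computed on raw values because published per-SNP
outlier tables report raw F~ST~; the smoothed track is for localization,
and the reported peak is the argmax of the smoothed values.

## The association test

Sex is coded as a binary trait (1 = non-masculinized female control, 2 =
pseudomale case) and each site is tested with the basic allelic test: the
2×2 table of minor/major allele counts in cases and controls, Pearson
$\chi^2$ with one degree of freedom and **no continuity correction**
(the choice is verified in the tests: the published example tables
reproduce their printed $\chi^2$ only without correction). The odds ratio
is $ad/bc$ with a Woolf (log-scale) confidence interval,
$\exp(\ln \mathrm{OR} \pm z\,\sqrt{1/a+1/b+1/c+1/d})$.

Conventions, each of which has an alternative we deliberately did not take:

* **Minor allele on the pooled sample** (PLINK convention), with a pooled
  tie broken toward the lexicographically smaller nucleotide so results are
  deterministic.
* **Zero-cell odds ratios are `NA`**, not Haldane-corrected; a
  `haldane = TRUE` option adds 0.5 to every cell for users who prefer the
  corrected estimate.
* **Bonferroni $m$ is the number of sites actually tested** after filtering
  and per-site skips, not the pre-filter count; each $p$ maps to
  $\min(1, mp)$.
* p-values come from the $\chi^2_1$ upper tail (`pchisq(..., lower.tail =
  FALSE)`), i.e. the regularized incomplete gamma function.
* Counts reconstructed from printed frequencies use `round(freq * 2N)` with
  ties half-up &mdash; the rounding that makes published tables reproducible
  to their printed precision.

## Site and genotype filters

The filters mirror a Stacks-style workflow: per-genotype minimum read depth
(`-m`, applied as a mask setting sub-threshold calls to missing &mdash; the
per-genotype reading of the option, documented because tool versions differ
on per-genotype vs per-locus semantics), per-population call rate $\ge$ 0.7
(`-r`), presence of the site in both populations (`-p 2`), pooled minor
allele frequency strictly $> 0.01$ (`--min_maf`), and a user-supplied
coordinate blacklist (`-B`; upstream this catches artefactual alleles from
read padding, here it is a generic exclusion list). Since no canonical rule
order exists, we fix and document one &mdash; blacklist, call rate,
presence, MAF &mdash; and attribute each removed site to the *first* rule it
fails, so removal counts always partition the removed set. Filtering is
idempotent and monotone in its thresholds; both properties are tested.

## The synthetic study generator

The generator emulates the study design the analyses assume, not raw
sequencing. Per family it creates two diploid founders (a pseudomale sire
and a treated dam, both XX) as two haplotypes over all linkage groups, and
produces offspring by Mendelian meiosis under a **Haldane (no interference)
map**: between adjacent sites $d$ cM apart, the copied haplotype switches
with probability $r = (1 - e^{-2d/100})/2$, with $d$ derived from physical
spacing at `cm_per_mb` (default 3&nbsp;cM/Mb, a typical fish genome-wide
average). Haldane is the simplest standard choice; interference would
slightly reduce double-crossovers at these spacings without affecting any
statistic the pipeline computes.

Key defaults and why:

* **3 families × (20 cases + 20 controls)**, the reference design: offspring
  are generated *until* each class quota is met, mirroring a fixed sampling
  design rather than simulating sex ratios and subsampling. An unreachable
  class (e.g. zero penetrance everywhere with cases requested) aborts with
  an explicit error after a bounded number of attempts.
* **Causal locus** on LG23 at 9,441,132&nbsp;bp with alleles C
  (masculinizing) and G (protective) and penetrances **CC 0.853, CG 0.368,
  GG 0.0** &mdash; the genotype-dependent male proportions the design
  targets. Both founders are heterozygous C/G: the parents of such crosses
  (a temperature-induced pseudomale and a treated female) plausibly carry
  sensitivity alleles, and het × het segregates all three offspring
  genotypes, which is what gives the case/control contrast its signal. This
  is an assumption, not an observation &mdash; parental genotypes at the
  causal region are not known &mdash; and it is configurable.
* **Penetrances are applied uniformly across families.** Whether the
  observed genotype-specific male proportions are partly confounded by
  family cannot be resolved from published summaries; the simulator takes
  them as marginal penetrances.
* **22 linkage groups** of 40&nbsp;Mb with 400 uniformly spaced SNPs each
  (8&nbsp;800 sites; named to LG23 with LG21 absent, following the tilapia
  assembly's numbering). Uniform spacing makes kernel-window contents
  analytic in tests; uniform-random positions are an option. The site
  nearest the causal coordinate is moved onto it, keeping the count exact.
* **Neutral founder allele frequencies** drawn per site from
  U(0.05,&nbsp;0.5) &mdash; a flat reduced-representation SNP frequency
  spectrum after a MAF-ascertainment cut.
* **Depth is Poisson(20)** and genotypes go missing independently with
  probability 0.05 (their depth then 0). Depth exists solely so the depth
  filter has something to act on; the exact law is immaterial and
  swappable.

What the generator does **not** emulate: read-level artefacts (the
blacklist's upstream cause), genotyping error from low-depth calls,
linked-read haplotype structure beyond the family LD that meiosis creates,
population-level LD decay (founders are drawn in linkage equilibrium),
selection, and any epigenetic contribution to masculinization. Passing
simulation-based checks therefore validates the statistical machinery and
its power under the stated family design &mdash; it does not certify
performance on population samples with unknown structure.

The causal site itself carries the full association signal in every family,
while a neutral site tracks it only insofar as founder haplotypes happen to
align with the causal alleles; with two founders per family that alignment
is random. This is why localization checks use the smoothed argmax and the
minimum-p site rather than expecting a clean monotone decay around the
peak.

## Marker assays

Taq&alpha;I recognizes TCGA &mdash; its own reverse complement, so
single-strand search is complete. The enzyme spec is `"PATTERN@offset"`;
cut coordinates are site start + offset and fragments are the differences
between successive cuts and the amplicon ends, so fragment lengths always
sum to the amplicon length. The published assay digests a 1252&nbsp;bp
amplicon into 829 + 423&nbsp;bp when the Y-specific 5&nbsp;bp insertion
(ATGTC) is present; since the amplicon sequence itself is not published,
`amh_amplicon_set()` builds a synthetic pair that reproduces exactly this
observable behaviour, placing the insertion immediately before a GA
dinucleotide so that exactly one TCGA site appears with its cut at
coordinate 829. Which side of the cut the long fragment lies on is a
convention; the classifier accepts the pair in either order and matches
sizes within a 10&nbsp;bp tolerance, mimicking fragment calls from agarose
gels.

## Pipeline determinism and problem sizes

`run_pipeline()` is a deterministic function of its configuration and seed:
the manifest omits wall-clock time, result tables are written at full
precision, and the test suite checksums two runs byte against byte. The
command-line interface (`inst/scripts/tsdscan`) is a thin wrapper over the
same functions, so staged runs compose to the same artifacts.

Test and acceptance problem sizes are chosen to exercise every code path at
comfortable desk scale: the full default design (120 × 8&nbsp;800) for
end-to-end checks, 20 seeds for localization and calibration rates, 1&nbsp;000
random small sites for the F~ST~ oracle, 5&nbsp;000 draws per genotype for
penetrance recovery, and 20 × 200 permuted tests for type-I error. Real
ddRAD studies are a few times larger in sites but identical in structure.

## Known limitations

* The allelic test treats the $2N$ alleles as independent; in full-sib
  material this is an approximation (sibs are correlated and sites need not
  be in Hardy&ndash;Weinberg proportions within families). The permutation
  calibration check bounds the practical consequence under the simulated
  design, but for confirmatory work on family data a transmission-based or
  mixed-model test would be the rigorous choice &mdash; both out of scope
  here.
* F~ST~ p-values, haplotype-based F-statistics and Bayesian outlier models
  are deliberately not provided; the outlier definition is purely
  empirical-quantile.
* The scan's smoothing bandwidth is a fixed physical scale; it does not
  adapt to local SNP density.
* Starting point is a genotype matrix: read mapping, locus assembly and
  genotype calling live upstream.
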