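#' Run the full scan pipeline
#'
#' Orchestrates simulate (or load) -> depth masking -> site filters ->
#' weighted-FST scan -> case-control association, writing every artifact to
#' `out_dir`: the (simulated) input VCF, population map and truth table, the
#' filtered VCF, the filter report (JSON), the scan and association tables
#' (TSV) and a run manifest embedding the resolved configuration. Rerunning
#' with the same configuration and seed reproduces every artifact
#' byte-identically (the manifest deliberately carries no wall-clock
#' timestamp).
#'
#' Exactly one input source must be given: either a simulation configuration
#' or a VCF plus population map.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config], or `NULL` when loading real data.
#' @param vcf,popmap paths to an input VCF and population map, or `NULL` when
#'   simulating.
#' @param filters a [filter_config].
#' @param scan a [scan_config].
#' @param suggestive_p,alpha association reporting thresholds.
#' @param seed optional integer overriding the simulation seed.
#' @return invisibly, a list with the in-memory results (`genotypes`,
#'   `popmap`, `filter_report`, `scan`, `assoc`, optionally `truth`) and
#'   `paths` to the artifacts.
#' @export
run_pipeline <- function(out_dir, sim = NULL, vcf = NULL, popmap = NULL,
                         filters = filter_config(), scan = scan_config(),
                         suggestive_p = 0.001, alpha = 0.05, seed = NULL) {
  simulating <- !is.null(sim)
  loading <- !is.null(vcf) || !is.null(popmap)
  if (simulating == loading) {
    stop("provide exactly one input source: a simulation config, or vcf + popmap")
  }
  if (loading && (is.null(vcf) || is.null(popmap))) {
    stop("loading real data requires both a VCF and a population map")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  result <- list()

  if (simulating) {
    stopifnot(inherits(sim, "sim_config"))
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    message("[simulate] seed ", sim$seed)
    ds <- simulate_dataset(sim)
    gm <- ds$genotypes
    pm <- ds$popmap
    paths$input_vcf <- file.path(out_dir, "simulated.vcf")
    paths$popmap <- file.path(out_dir, "popmap.tsv")
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_vcf(gm, paths$input_vcf)
    write_popmap(pm, paths$popmap)
    write_truth(ds$truth, paths$truth)
    result$truth <- ds$truth
  } else {
    message("[load] ", vcf)
    gm <- read_vcf(vcf)
    pm <- read_popmap(popmap)
    paths$input_vcf <- vcf
    paths$popmap <- popmap
  }
  message(sprintf("[input] %d individuals x %d sites", n_individuals(gm), n_sites(gm)))

  if (!is.null(gm$depth)) {
    gm <- mask_low_depth(gm, filters$min_depth)
    message("[mask] genotypes below depth ", filters$min_depth, " set missing")
  }
  fs <- filter_sites(gm, pm, filters)
  gm <- fs$genotypes
  rep <- fs$report
  message(sprintf("[filter] %d -> %d sites (blacklist %d, call_rate %d, all_pops %d, maf %d)",
                  rep$n_input, rep$n_output, rep$removed$blacklist,
                  rep$removed$call_rate, rep$removed$all_pops, rep$removed$maf))
  paths$filtered_vcf <- file.path(out_dir, "filtered.vcf")
  paths$filter_report <- file.path(out_dir, "filter_report.json")
  write_vcf(gm, paths$filtered_vcf)
  jsonlite::write_json(rep, paths$filter_report, auto_unbox = TRUE, pretty = TRUE)

  scan_res <- fst_scan(gm, pm, scan)
  message(sprintf("[scan] %d sites; FST threshold (q=%.4g) = %.4f; %d outlier(s)",
                  nrow(scan_res), scan$outlier_quantile,
                  attr(scan_res, "threshold"), sum(scan_res$outlier)))
  paths$scan <- file.path(out_dir, "scan.tsv")
  write_table(scan_res, paths$scan)

  assoc_res <- assoc_scan(gm, pm, suggestive_p = suggestive_p, alpha = alpha)
  message(sprintf("[assoc] %d tests; %d suggestive (p < %g), %d significant (Bonferroni %g)",
                  assoc_res$m, nrow(assoc_res$suggestive), suggestive_p,
                  nrow(assoc_res$significant), alpha))
  paths$assoc <- file.path(out_dir, "assoc.tsv")
  write_table(assoc_res, paths$assoc)

  manifest <- list(
    package = "tsdscan",
    version = as.character(utils::packageVersion("tsdscan")),
    r_version = R.version.string,
    input = if (simulating) "simulated" else "loaded",
    simulation = if (simulating) unclass(sim),
    filters = unclass(filters)[setdiff(names(filters), "blacklist")],
    scan = unclass(scan),
    association = list(suggestive_p = suggestive_p, alpha = alpha),
    artifacts = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)

  invisible(c(result, list(genotypes = gm, popmap = pm, filter_report = rep,
                           scan = scan_res, assoc = assoc_res, paths = paths)))
}

#' Summarize pipeline result tables
#'
#' Reads a scan TSV and an association TSV (as written by [write_table()])
#' and produces a human-readable summary: genome-wide and per-linkage-group
#' mean +/- SD of FST, the outlier interval per linkage group (or a note that
#' nothing was flagged), and the suggestive and Bonferroni-significant
#' association hits.
#'
#' @param scan_path path to the scan table.
#' @param assoc_path path to the association table.
#' @param suggestive_p,alpha reporting thresholds (matching the scan that
#'   produced the tables).
#' @return object of class `run_report`: list with `text` (character lines)
#'   and the underlying `summary` components. Printing shows the text.
#' @export
run_report <- function(scan_path, assoc_path, suggestive_p = 0.001,
                       alpha = 0.05) {
  scan <- read_scan_table(scan_path)
  assoc <- read_assoc_table(assoc_path)

  by_lg <- summarize_by_lg(scan)
  intervals <- outlier_interval(scan)
  sugg <- assoc[assoc$p < suggestive_p, , drop = FALSE]
  sugg <- sugg[order(sugg$p), , drop = FALSE]
  sig <- assoc[assoc$p_bonf < alpha, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]

  fmt_lg <- sprintf("  %-6s n=%5d  mean=%8.4f  sd=%7.4f  median=%8.4f",
                    by_lg$chrom, by_lg$n, by_lg$mean, by_lg$sd, by_lg$median)
  text <- c(
    sprintf("Genome-wide FST: %.4f +/- %.4f over %d sites",
            mean(scan$fst), stats::sd(scan$fst), nrow(scan)),
    "Per linkage group:", fmt_lg,
    if (nrow(intervals) == 0) "Outliers: none flagged" else c(
      "Outlier intervals:",
      sprintf("  %-6s %d-%d (%d bp, %d SNPs)", intervals$chrom,
              intervals$start, intervals$end, intervals$width_bp,
              intervals$n_outliers)),
    sprintf("Association: %d sites tested; %d suggestive (p < %g); %d Bonferroni-significant (adj. p < %g)",
            nrow(assoc), nrow(sugg), suggestive_p, nrow(sig), alpha),
    if (nrow(sugg) > 0) c(
      "Top hits:",
      sprintf("  %-6s bp %-10d chisq=%7.2f  p=%.3g  OR=%s  p_bonf=%.3g",
              utils::head(sugg$chrom, 10), utils::head(sugg$pos, 10),
              utils::head(sugg$chisq, 10), utils::head(sugg$p, 10),
              formatC(utils::head(sugg$or, 10), format = "fg", digits = 3),
              utils::head(sugg$p_bonf, 10))))

  structure(list(text = text,
                 summary = list(genome_mean_fst = mean(scan$fst),
                                genome_sd_fst = stats::sd(scan$fst),
                                by_lg = by_lg, intervals = intervals,
                                suggestive = sugg, significant = sig)),
            class = "run_report")
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
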