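## End-to-end orchestration and cross-dataset comparison.

default_thresholds <- function() {
  list(min_site_calls = 5, min_window_calls = 50, window = 2000,
       tss_width = 200, exclude_5prime = 1000, flank = 10000,
       smooth_k = 100, scaffold_min = 277000, mapq_min = 60)
}

threshold_hash <- function(thresholds) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(names(thresholds), unlist(thresholds), sep = "=",
                   collapse = ";"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full downstream methylome analysis
#'
#' Executes the complete quantitation sequence on one dataset: scaffold
#' filtering, symmetric-CG pooling, global and per-site summaries with
#' conversion efficiency, genome-wide 2 kb running windows, TSS and gene-body
#' methylation, trend profiles over genes and TE classes, TE distributions,
#' and (when expression counts are supplied) quintile stratification of TSS
#' and gene-body methylation. Every threshold is taken from one `thresholds`
#' block, echoed verbatim into the report together with its hash, so two
#' reports are comparable only when computed under identical definitions.
#'
#' @param calls a [site_call_table()].
#' @param genes gene models ([read_gene_annotation()]), or NULL.
#' @param repeats repeat elements ([read_repeat_annotation()]), or NULL.
#' @param counts per-gene expression counts: data.frame (gene_id, count), or
#'   NULL to skip the expression stages.
#' @param read_positions optional RNA-seq read positions; when supplied and
#'   `counts` is NULL, counts are computed with [count_exonic_reads()] and
#'   contamination-corrected.
#' @param thresholds named list; see `default_thresholds` entries in the
#'   report. Missing entries take the defaults.
#' @param dataset label recorded in the report.
#' @return a `methylome_report` list; stage-level record counts are logged
#'   via `message()`.
#' @export
run_pipeline <- function(calls, genes = NULL, repeats = NULL, counts = NULL,
                         read_positions = NULL,
                         thresholds = list(), dataset = "dataset") {
  th <- utils::modifyList(default_thresholds(), thresholds)
  stage <- function(name, n_in, n_out)
    message(sprintf("[%s] %s: %d -> %d records", dataset, name, n_in, n_out))

  n0 <- nrow(calls)
  filtered <- filter_scaffolds(calls, min_length_bp = th$scaffold_min)
  stage("filter_scaffolds", n0, nrow(filtered))

  cpg <- merge_symmetric_cg(filtered)
  stage("merge_symmetric_cg", sum(filtered$context == "CG"), nrow(cpg))
  sites <- site_methylation(cpg, min_calls = th$min_site_calls)
  stage("site_threshold", nrow(sites), sum(sites$included))

  global <- global_methylation(filtered)
  eff <- tryCatch(conversion_efficiency(filtered), error = function(e) {
    message("[", dataset, "] conversion efficiency undefined: ",
            conditionMessage(e))
    NA_real_
  })
  site_dist <- site_category_distribution(sites$M)

  manifest <- genome_manifest(filtered)
  kept <- manifest[manifest > th$scaffold_min |
                     names(manifest) %in% mito_ids(filtered)]
  wins <- running_windows(kept, size = th$window)
  winq <- quantify_windows(sites, wins, min_calls = th$min_site_calls)
  window_summary <- list(
    n_windows = nrow(winq), n_included = sum(winq$included),
    median = median(winq$percent, na.rm = TRUE),
    percents = winq$percent[winq$included])

  report <- list(dataset = dataset, thresholds = th,
                 threshold_hash = threshold_hash(th),
                 n_input_records = n0, n_filtered_records = nrow(filtered),
                 global = global, conversion_efficiency = eff,
                 site_distribution = site_dist,
                 window_summary = window_summary)

  if (!is.null(genes) && nrow(genes)) {
    tssq <- tss_methylation(sites, genes, min_calls = th$min_site_calls,
                            width = th$tss_width, manifest = manifest)
    stage("tss_threshold", nrow(tssq), sum(tssq$included))
    body <- gene_body_methylation(sites, genes, window = th$window,
                                  exclude_5prime = th$exclude_5prime,
                                  min_calls_per_window = th$min_window_calls)
    stage("gene_body", nrow(body), sum(!is.na(body$percent)))
    report$tss <- tssq
    report$gene_body <- body
    report$gene_trend <- feature_trend(sites, genes, flank = th$flank,
                                       smooth_k = th$smooth_k)
  }
  if (!is.null(repeats) && nrow(repeats)) {
    report$te_distribution <- te_distribution(sites, repeats,
                                              min_calls = th$min_site_calls)
    report$te_trend <- te_trend(sites, repeats, flank = th$flank,
                                smooth_k = th$smooth_k)
  }
  if (is.null(counts) && !is.null(read_positions) && !is.null(genes)) {
    raw <- count_exonic_reads(read_positions, genes, mapq_min = th$mapq_min)
    corr <- contamination_correct(raw, genes, read_positions, manifest,
                                  mapq_min = th$mapq_min)
    counts <- data.frame(gene_id = names(corr$corrected),
                         count = corr$corrected)
  }
  if (!is.null(counts) && !is.null(genes)) {
    cnt <- setNames(counts$count, counts$gene_id)
    expr <- length_correct(cnt, genes)
    quint <- assign_quintiles(expr)
    tss_val <- setNames(report$tss$percent, report$tss$gene_id)
    body_val <- setNames(report$gene_body$percent, report$gene_body$gene_id)
    report$quintiles <- quint
    report$tss_by_quintile <- stratify_methylation(tss_val, quint)
    report$body_by_quintile <- stratify_methylation(body_val, quint)
  }
  structure(report, class = "methylome_report")
}

#' @export
print.methylome_report <- function(x, ...) {
  g <- x$global
  cg <- g$percent[g$compartment == "nuclear" & g$context == "CG"]
  ncg <- g$percent[g$compartment == "nuclear" & g$context == "non-CG"]
  cat(sprintf("methylome_report '%s'\n", x$dataset))
  cat(sprintf("  nuclear CG %.1f%%, non-CG %.2f%%; conversion >= %.1f%%\n",
              cg, ncg, x$conversion_efficiency))
  cat(sprintf("  sites >= 80%%: %.1f%%; unmethylated (<10%%): %.1f%%\n",
              100 * x$site_distribution$frac_high,
              100 * x$site_distribution$frac_low))
  cat(sprintf("  2 kb window median: %.1f%% over %d windows\n",
              x$window_summary$median, x$window_summary$n_included))
  if (!is.null(x$tss_by_quintile))
    cat("  TSS median by quintile (1..5):",
        paste(sprintf("%.1f", x$tss_by_quintile$summary$median),
              collapse = " "), "\n")
  invisible(x)
}

report_key_stats <- function(r) {
  g <- r$global
  out <- c(
    global_cg = g$percent[g$compartment == "nuclear" & g$context == "CG"],
    global_noncg = g$percent[g$compartment == "nuclear" &
                               g$context == "non-CG"],
    conversion_efficiency = r$conversion_efficiency,
    frac_sites_ge80 = r$site_distribution$frac_high,
    frac_sites_unmeth = r$site_distribution$frac_low,
    window_median = r$window_summary$median)
  if (!is.null(r$tss_by_quintile)) {
    tm <- r$tss_by_quintile$summary$median
    bm <- r$body_by_quintile$summary$median
    out <- c(out, setNames(tm, paste0("tss_median_q", 1:5)),
             setNames(bm, paste0("body_median_q", 1:5)))
  }
  out
}

#' Align key statistics across datasets
#'
#' Builds a cross-dataset table of the headline statistics of two or more
#' [run_pipeline()] reports (global CG and non-CG percent, fraction of sites
#' >= 80% methylated, window median, quintile medians). Reports computed
#' under different threshold blocks are refused, with the differing entries
#' listed: comparisons are only meaningful under identical statistic
#' definitions. Statistics whose range across datasets exceeds
#' `flag_range` percentage points are flagged.
#'
#' @param reports list of `methylome_report`s (>= 2).
#' @param flag_range range in points beyond which a row is flagged.
#' @return list with `table` (statistic x dataset matrix), `flagged`
#'   (statistic names), `threshold_hash`.
#' @export
compare_datasets <- function(reports, flag_range = 30) {
  if (length(reports) < 2) stop("need at least 2 reports")
  hashes <- vapply(reports, `[[`, character(1), "threshold_hash")
  if (length(unique(hashes)) > 1) {
    ref <- reports[[1L]]$thresholds
    diffs <- character()
    for (i in seq_along(reports)[-1L]) {
      th <- reports[[i]]$thresholds
      for (k in union(names(ref), names(th)))
        if (!identical(ref[[k]], th[[k]]))
          diffs <- c(diffs, sprintf("%s: %s vs %s (report %d)", k,
                                    deparse(ref[[k]]), deparse(th[[k]]), i))
    }
    stop("threshold blocks differ between reports:\n  ",
         paste(diffs, collapse = "\n  "))
  }
  stats_list <- lapply(reports, report_key_stats)
  rows <- Reduce(union, lapply(stats_list, names))
  tab <- vapply(stats_list, function(s) s[rows], numeric(length(rows)))
  rownames(tab) <- rows
  colnames(tab) <- vapply(reports, `[[`, character(1), "dataset")
  rng <- apply(tab, 1, function(v) diff(range(v, na.rm = TRUE)))
  pct_rows <- !grepl("^frac_", rows)
  flagged <- rows[pct_rows & !is.na(rng) & rng > flag_range]
  list(table = tab, flagged = flagged,
       threshold_hash = unique(hashes))
}
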