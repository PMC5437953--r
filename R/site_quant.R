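## Per-site and global methylation summaries.

#' Pool symmetric CpG calls into dinucleotide sites
#'
#' A CpG dinucleotide carries a methylatable cytosine on each strand: the +
#' strand C at position p and the - strand C at p+1. Both are pooled into one
#' site anchored at p (the + strand C). Records lacking their partner become
#' singleton sites at the same anchor.
#'
#' @param table a [site_call_table()]; only CG-context records are used.
#' @return data.frame with columns `chrom`, `pos` (anchor), `n_meth`,
#'   `n_unmeth`, sorted by (chrom, pos).
#' @export
merge_symmetric_cg <- function(table) {
  cg <- as.data.frame(table)[table$context == "CG", , drop = FALSE]
  if (!nrow(cg))
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer()))
  key <- paste(cg$chrom, cg$pos, cg$strand)
  if (anyDuplicated(key))
    stop("duplicate strand records at ", key[which(duplicated(key))[1L]])
  anchor <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  dt <- data.table::data.table(chrom = cg$chrom, pos = anchor,
                               n_meth = cg$n_meth, n_unmeth = cg$n_unmeth)
  out <- dt[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
            by = c("chrom", "pos")]
  data.table::setorderv(out, c("chrom", "pos"))
  as.data.frame(out)
}

#' Per-site methylation percentage with a minimum-call threshold
#'
#' Computes M = 100 * n_meth / (n_meth + n_unmeth) per pooled CpG site.
#' Sites with fewer than `min_calls` total calls are flagged excluded and get
#' `M = NA`; sparse sites give unstable percentages (a 1-call site can only be
#' 0 or 100), so a minimum of five calls is required by default.
#'
#' @param sites pooled sites from [merge_symmetric_cg()].
#' @param min_calls minimum total calls for a site to be included.
#' @return the input with added columns `n_calls`, `M`, `included`.
#' @export
site_methylation <- function(sites, min_calls = 5) {
  if (!is.numeric(min_calls) || length(min_calls) != 1 || min_calls < 1)
    stop("min_calls must be a single integer >= 1")
  n_calls <- sites$n_meth + sites$n_unmeth
  included <- n_calls >= min_calls
  M <- ifelse(included, 100 * sites$n_meth / n_calls, NA_real_)
  cbind(sites, data.frame(n_calls = n_calls, M = M, included = included))
}

#' Global call-weighted methylation by context and compartment
#'
#' Totals methylated over all calls, split by context (CG vs non-CG, the
#' latter pooling CHG and CHH) and compartment (nuclear vs mitochondrial, per
#' the table's mitochondrial scaffold set). This is call-weighted arithmetic
#' (total methylated calls over total calls), not a mean of per-site
#' percentages, matching how aligner mapping reports summarise global levels.
#'
#' @param table a [site_call_table()].
#' @return data.frame with columns `compartment`, `context`,
#'   `total_meth_calls`, `total_calls`, `percent` (NA where a stratum has no
#'   calls).
#' @export
global_methylation <- function(table) {
  mito <- mito_ids(table)
  compartment <- ifelse(table$chrom %in% mito, "mitochondrial", "nuclear")
  context <- ifelse(table$context == "CG", "CG", "non-CG")
  strata <- expand.grid(compartment = c("nuclear", "mitochondrial"),
                        context = c("CG", "non-CG"),
                        stringsAsFactors = FALSE)
  strata <- strata[order(strata$compartment, decreasing = TRUE), ]
  rownames(strata) <- NULL
  key <- paste(compartment, context)
  meth <- tapply(table$n_meth, key, sum)
  tot <- tapply(table$n_meth + table$n_unmeth, key, sum)
  skey <- paste(strata$compartment, strata$context)
  strata$total_meth_calls <- ifelse(is.na(meth[skey]), 0, meth[skey])
  strata$total_calls <- ifelse(is.na(tot[skey]), 0, tot[skey])
  strata$percent <- ifelse(strata$total_calls > 0,
                           100 * strata$total_meth_calls / strata$total_calls,
                           NA_real_)
  strata
}

#' Bisulfite conversion efficiency from non-CG methylation
#'
#' In genomes with negligible true non-CG methylation, apparent methylation in
#' CHG/CHH context reflects unconverted cytosines, so observed non-CG
#' methylation bounds the non-conversion rate from above. The value returned,
#' 100 minus the call-weighted nuclear non-CG methylation percentage, is
#' therefore a lower bound on conversion efficiency.
#'
#' @param table a [site_call_table()] with non-CG records.
#' @return efficiency in percent.
#' @export
conversion_efficiency <- function(table) {
  g <- global_methylation(table)
  row <- g[g$compartment == "nuclear" & g$context == "non-CG", ]
  if (row$total_calls == 0)
    stop("no nuclear non-CG calls: conversion efficiency undefined")
  100 - row$percent
}

#' Distribution of per-site methylation over decade bins
#'
#' Bins per-site M values into ten left-closed bins [0,10), ..., [80,90),
#' [90,100], and reports the fraction of sites per bin plus two headline
#' fractions: highly methylated sites (M >= 80, the top two bins) and
#' unmethylated sites (the lowest bin).
#'
#' @param M_values numeric vector of per-site percentages (NAs dropped).
#' @return list with `bins` (data.frame: lower, upper, fraction, n),
#'   `frac_high` (M >= 80), `frac_low` (M < 10) and `n_sites`.
#' @export
site_category_distribution <- function(M_values) {
  M <- M_values[!is.na(M_values)]
  if (!length(M)) stop("no defined M values to bin")
  if (any(M < 0 | M > 100)) stop("M values must lie in [0, 100]")
  idx <- pmin(floor(M / 10) + 1L, 10L)  # 100 falls in the top bin
  counts <- tabulate(idx, nbins = 10L)
  bins <- data.frame(lower = seq(0, 90, 10), upper = seq(10, 100, 10),
                     n = counts, fraction = counts / length(M))
  list(bins = bins,
       frac_high = sum(counts[9:10]) / length(M),
       frac_low = counts[1L] / length(M),
       n_sites = length(M))
}

#' Two-sample location test on methylation percentages
#'
#' Two-sided two-sample t-test comparing group methylation levels (e.g. female
#' vs male global CG percentages). Defaults to the unpooled-variance (Welch)
#' variant; the pooled-variance variant is available. Two identical constant
#' groups are reported as p = 1 by convention (no evidence of a difference; the
#' t statistic is undefined there).
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param var_equal use the pooled-variance variant.
#' @return list with `statistic`, `p_value`, `variant`, `df`.
#' @export
two_sample_location_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  variant <- if (var_equal) "pooled" else "unpooled"
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      group_a[1L] == group_b[1L]) {
    message("identical constant groups: p = 1 by convention")
    return(list(statistic = 0, p_value = 1, variant = variant,
                df = NA_real_))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       variant = variant, df = unname(tt$parameter))
}
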