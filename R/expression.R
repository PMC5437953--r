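## RNA-seq exon quantitation, contamination/length correction, quintiles.

exonic_length_bp <- function(genes) {
  vapply(genes$exons, function(e) sum(e$end - e$start + 1), numeric(1))
}

#' Count exonic reads per gene
#'
#' A read counts toward a gene if it overlaps any exon of that gene; reads
#' overlapping exons of several genes count toward each (the multi-gene read
#' total is reported in a message). Reads below the mapping-quality threshold
#' (default 60, keeping only uniquely aligned reads) and unmapped records
#' (missing coordinates) are skipped.
#'
#' @param read_positions data.frame with `chrom`, `start`, `end` and
#'   optionally `mapq` (records without a mapq column are treated as passing).
#' @param genes gene models ([read_gene_annotation()]).
#' @param mapq_min minimum mapping quality.
#' @return named integer vector of raw counts, one per gene (zeros included).
#' @export
count_exonic_reads <- function(read_positions, genes, mapq_min = 60) {
  r <- read_positions
  unmapped <- is.na(r$chrom) | is.na(r$start) | is.na(r$end)
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped record(s) skipped")
    r <- r[!unmapped, , drop = FALSE]
  }
  if (!is.null(r$mapq)) r <- r[r$mapq >= mapq_min, , drop = FALSE]
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (!nrow(r) || !nrow(genes)) return(counts)
  ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    data.frame(gene = i, chrom = genes$chrom[i],
               start = genes$exons[[i]]$start, end = genes$exons[[i]]$end)))
  rq <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
  sq <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rq, sq, ignore.strand = TRUE))
  pair <- unique(data.frame(read = S4Vectors::queryHits(hits),
                            gene = ex$gene[S4Vectors::subjectHits(hits)]))
  if (nrow(pair)) {
    multi <- sum(table(pair$read) > 1)
    if (multi) message(multi, " read(s) overlapping exons of multiple genes ",
                       "counted toward each")
    tab <- table(pair$gene)
    counts[as.integer(names(tab))] <- as.integer(tab)
    names(counts) <- genes$gene_id
  }
  counts
}

#' Correct raw counts for DNA contamination
#'
#' Genomic DNA carried into an RNA-seq library contributes reads uniformly
#' across the genome. The background read density (reads/bp) is estimated
#' from intergenic territory (the manifest minus the union of gene spans,
#' counting reads that overlap no gene span), and the expected background,
#' density times exonic length, is subtracted from each gene's raw count,
#' floored at zero. With no intergenic territory the correction is skipped
#' with a warning; with zero intergenic reads the counts are unchanged.
#'
#' @param raw_counts named numeric vector from [count_exonic_reads()] (or a
#'   precomputed counts table).
#' @param genes gene models.
#' @param read_positions the read table used for the counts.
#' @param manifest scaffold lengths.
#' @param mapq_min minimum mapping quality, applied as in counting.
#' @return list with `corrected` (named vector), `background_density`
#'   (reads/bp) and `intergenic_bp`.
#' @export
contamination_correct <- function(raw_counts, genes, read_positions, manifest,
                                  mapq_min = 60) {
  manifest <- as_manifest(manifest)
  r <- read_positions
  if (!is.null(r$mapq)) r <- r[r$mapq >= mapq_min, , drop = FALSE]
  gene_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start, genes$end)))))
  intergenic_bp <- sum(manifest) - gene_bp
  if (intergenic_bp <= 0) {
    warning("no intergenic territory: contamination correction skipped")
    return(list(corrected = raw_counts, background_density = NA_real_,
                intergenic_bp = 0))
  }
  if (nrow(r)) {
    rq <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
    gq <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    genic <- GenomicRanges::countOverlaps(rq, gq, ignore.strand = TRUE) > 0
    n_intergenic <- sum(!genic)
  } else n_intergenic <- 0
  density <- n_intergenic / intergenic_bp
  expected <- density * exonic_length_bp(genes)
  corrected <- pmax(raw_counts - expected[match(names(raw_counts),
                                                genes$gene_id)], 0)
  list(corrected = corrected, background_density = density,
       intergenic_bp = intergenic_bp)
}

#' Correct counts by transcript length
#'
#' Divides each (contamination-corrected) count by the gene's exonic length in
#' kb, yielding reads per kb of transcript.
#'
#' @param corrected_counts named numeric vector.
#' @param genes gene models.
#' @return named numeric vector of per-kb expression values.
#' @export
length_correct <- function(corrected_counts, genes) {
  len_kb <- exonic_length_bp(genes) / 1000
  idx <- match(names(corrected_counts), genes$gene_id)
  if (anyNA(idx)) stop("counts carry gene ids absent from the gene models")
  if (any(len_kb[idx] <= 0)) stop("zero-length transcript")
  corrected_counts / len_kb[idx]
}

#' Assign expression quintiles
#'
#' Ranks genes by expression value (ties broken by gene id for determinism)
#' and splits them into five near-equal groups, label 5 = highest expression.
#' When the gene count is not a multiple of five, the extra genes are
#' allocated one each to the lowest quintiles, so group sizes differ by at
#' most one and the lowest quintile takes the first remainder slot.
#'
#' @param expression_values named numeric vector (>= 5 genes).
#' @return named integer vector of quintile labels 1-5, aligned with the
#'   input order.
#' @export
assign_quintiles <- function(expression_values) {
  n <- length(expression_values)
  if (n < 5) stop("at least 5 genes are required for quintiles")
  ids <- names(expression_values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  o <- order(expression_values, ids)  # ascending; stable by (value, id)
  base <- n %/% 5L
  extra <- n %% 5L
  sizes <- rep(base, 5L) + as.integer(seq_len(5L) <= extra)
  lab_sorted <- rep.int(1:5, sizes)
  labels <- integer(n)
  labels[o] <- lab_sorted
  setNames(labels, ids)
}

#' Stratify a per-gene methylation statistic by expression quintile
#'
#' Summarises a per-gene methylation value (TSS-window or gene-body percent)
#' within each expression quintile. Genes lacking a methylation value (below
#' the call threshold) are excluded from the summary of their quintile only;
#' quintiles left empty after exclusions are flagged.
#'
#' @param per_gene_methylation named numeric vector (NA = no value).
#' @param quintiles named integer vector from [assign_quintiles()].
#' @return list with `summary` (quintile, n_genes, n_with_value, median,
#'   mean), `values` (per-quintile list of the retained values) and
#'   `empty_quintiles`.
#' @export
stratify_methylation <- function(per_gene_methylation, quintiles) {
  ids <- intersect(names(quintiles), names(per_gene_methylation))
  if (!length(ids)) stop("no shared gene ids between methylation and quintiles")
  q <- quintiles[ids]
  m <- per_gene_methylation[ids]
  summ <- data.frame(quintile = 1:5, n_genes = 0L, n_with_value = 0L,
                     median = NA_real_, mean = NA_real_)
  values <- vector("list", 5L)
  names(values) <- as.character(1:5)
  for (k in 1:5) {
    v <- m[q == k]
    summ$n_genes[k] <- length(v)
    v <- v[!is.na(v)]
    summ$n_with_value[k] <- length(v)
    values[[k]] <- unname(v)
    if (length(v)) {
      summ$median[k] <- median(v)
      summ$mean[k] <- mean(v)
    }
  }
  list(summary = summ, values = values,
       empty_quintiles = summ$quintile[summ$n_with_value == 0])
}
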