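# Builders and independent brute-force oracles shared across test files.

call_df <- function(chrom, pos, strand, context, n_meth, n_unmeth) {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             n_meth = n_meth, n_unmeth = n_unmeth, stringsAsFactors = FALSE)
}

# n_pairs symmetric CpGs on one scaffold, deterministic counts
paired_cg_table <- function(n_pairs, chrom = "s1", spacing = 10L) {
  anchor <- seq(1L, by = spacing, length.out = n_pairs)
  calls <- rbind(
    call_df(chrom, anchor, "+", "CG", (seq_len(n_pairs) %% 7L),
            (seq_len(n_pairs) %% 5L) + 1L),
    call_df(chrom, anchor + 1L, "-", "CG", (seq_len(n_pairs) %% 3L),
            (seq_len(n_pairs) %% 4L) + 1L))
  site_call_table(calls,
                  manifest = setNames(max(anchor) + 10, chrom))
}

toy_genes <- function(gene_id, chrom, strand, start, end, exons = NULL,
                      biotype = "protein_coding") {
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = start, end = end, biotype = biotype,
                  stringsAsFactors = FALSE)
  g$exons <- if (is.null(exons))
    lapply(seq_len(nrow(g)), function(i)
      data.frame(start = g$start[i], end = g$end[i]))
  else exons
  g
}

# brute-force call-weighted percent of one interval by per-site scan
brute_interval_percent <- function(sites, chrom, start, end) {
  inside <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
  m <- sum(sites$n_meth[inside])
  tot <- m + sum(sites$n_unmeth[inside])
  list(n_calls = tot, percent = if (tot > 0) 100 * m / tot else NA_real_)
}

# brute-force exonic read counting by a double loop
brute_exonic_counts <- function(reads, genes, mapq_min = 60) {
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  for (r in seq_len(nrow(reads))) {
    if (!is.null(reads$mapq) && reads$mapq[r] < mapq_min) next
    for (g in seq_len(nrow(genes))) {
      if (reads$chrom[r] != genes$chrom[g]) next
      ex <- genes$exons[[g]]
      if (any(reads$start[r] <= ex$end & reads$end[r] >= ex$start))
        counts[g] <- counts[g] + 1L
    }
  }
  counts
}

# one full default vertebrate-mode dataset, built once per test run
vertebrate_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(
        simulate_methylome_dataset(synth_config("vertebrate", seed = 42)))
    cache
  }
})

mosaic_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(
        simulate_methylome_dataset(synth_config("mosaic", seed = 43)))
    cache
  }
})

# pipeline thresholds matched to the synthetic scaffold scale (250 kb
# scaffolds would all fall to the default 277 kb assembly filter)
synth_thresholds <- list(scaffold_min = 50000)

run_synth_pipeline <- function(ds, dataset = "synthetic") {
  suppressMessages(run_pipeline(ds$calls, ds$genome$genes,
                                ds$genome$repeats, ds$expression$counts,
                                thresholds = synth_thresholds,
                                dataset = dataset))
}
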