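## Seeded synthetic methylome generator: genomes, annotations, true
## methylomes (vertebrate and mosaic architectures), bisulfite call data,
## read records and expression counts.

#' Configuration for the synthetic methylome generator
#'
#' Builds a validated configuration for [simulate_methylome_dataset()] and
#' its stages. The two modes emulate the two methylome architectures the
#' package contrasts: `vertebrate` is pervasively hypermethylated (per-site
#' levels around `background_meth_mean`, hypermethylated transposable
#' elements, TSS hypomethylation deepening with expression tier);
#' `mosaic` is mostly unmethylated with methylated domains covering
#' `mosaic_domain_fraction` of the genome, biased toward gene bodies, and no
#' TSS-expression relationship. Per-site levels are drawn from Beta
#' distributions parameterised by mean and concentration (a bounded unimodal
#' family). Apparent non-CG methylation arises purely from
#' `conversion_failure_rate`.
#'
#' @param mode `"vertebrate"` or `"mosaic"`.
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_scaffolds,scaffold_length_bp genome layout (default 2 x 250 kb).
#' @param cg_per_kb expected CpG density per kb.
#' @param n_genes number of genes, placed without overlap.
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_min,gene_length_max
#'   log-normal gene-length model (bp), clamped.
#' @param n_te named vector of element counts per class.
#' @param te_length_range named list of (min, max) element lengths per class.
#' @param background_meth_mean,background_meth_conc vertebrate background
#'   Beta parameters (mean in [0,1], concentration > 0).
#' @param tss_meth_weight_by_tier per expression tier 1-5, probability that a
#'   TSS is methylated (drawn from the high component).
#' @param tss_high_mean,tss_low_mean,tss_conc TSS mixture components.
#' @param te_meth_mean,te_meth_conc TE-site Beta parameters (vertebrate).
#' @param mosaic_domain_fraction,mosaic_domain_mean,mosaic_background_mean,mosaic_genic_bias,mosaic_conc
#'   mosaic-mode architecture: domain coverage, in/out Beta means, the
#'   probability a domain is seeded on a gene body, and the Beta
#'   concentration.
#' @param conversion_failure_rate probability an unmethylated C escapes
#'   bisulfite conversion and reads as methylated.
#' @param mean_depth mean per-site call depth (both strands pooled).
#' @param noncg_per_kb density of emitted non-CG cytosines per kb.
#' @param n_reads,read_mean_cg read-record pool size and mean CG calls per
#'   read (reads cover consecutive CpG sites).
#' @param tier_means per-tier mean expression in reads per exonic kb.
#' @param nb_size negative-binomial size (overdispersion) of counts.
#' @param contamination_density uniform DNA-contamination read density,
#'   reads per kb of genome.
#' @param low_mapq_frac fraction of transcription reads emitted with
#'   sub-threshold mapping quality.
#' @return a `synth_config` list.
#' @export
synth_config <- function(mode = c("vertebrate", "mosaic"), seed,
                         n_scaffolds = 2, scaffold_length_bp = 250000,
                         cg_per_kb = 20, n_genes = 100,
                         gene_length_meanlog = log(3000),
                         gene_length_sdlog = 0.3,
                         gene_length_min = 1800, gene_length_max = 8000,
                         n_te = c(LINE = 60, SINE = 60),
                         te_length_range = list(LINE = c(500, 3000),
                                                SINE = c(150, 500)),
                         background_meth_mean = 0.74,
                         background_meth_conc = 2,
                         tss_meth_weight_by_tier = c(0.70, 0.45, 0.20,
                                                     0.06, 0.02),
                         tss_high_mean = 0.85, tss_low_mean = 0.03,
                         tss_conc = 8,
                         te_meth_mean = 0.85, te_meth_conc = 8,
                         mosaic_domain_fraction = 0.25,
                         mosaic_domain_mean = 0.80,
                         mosaic_background_mean = 0.02,
                         mosaic_genic_bias = 0.75,
                         mosaic_conc = 8,
                         conversion_failure_rate = 0.01,
                         mean_depth = 20, noncg_per_kb = 50,
                         n_reads = 50000, read_mean_cg = 2,
                         tier_means = c(1, 4, 16, 64, 256),
                         nb_size = 4, contamination_density = 0.2,
                         low_mapq_frac = 0.05) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(cfg$tss_meth_weight_by_tier, cfg$conversion_failure_rate,
             cfg$low_mapq_frac, cfg$mosaic_domain_fraction,
             cfg$mosaic_genic_bias, cfg$background_meth_mean,
             cfg$tss_high_mean, cfg$tss_low_mean, cfg$te_meth_mean,
             cfg$mosaic_domain_mean, cfg$mosaic_background_mean)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities and Beta means must lie in [0, 1]")
  if (length(cfg$tss_meth_weight_by_tier) != 5 || length(cfg$tier_means) != 5)
    stop("tier-indexed parameters must have length 5")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  structure(cfg, class = "synth_config")
}

rbeta_mc <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 1e-4), 1 - 1e-4)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate a synthetic genome with annotations
#'
#' Lays out scaffolds, places CpG sites at the configured density (anchors on
#' odd positions, so sites never abut), non-overlapping genes with exon
#' structure and random strands, and transposable elements confined to
#' non-exonic (intergenic or intronic) territory.
#'
#' @param config a [synth_config()].
#' @return list with `manifest`, `cg_sites` (chrom, pos anchors), `genes`
#'   (gene-model frame), `repeats`, and the echoed `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  manifest <- setNames(rep(config$scaffold_length_bp, config$n_scaffolds),
                       sprintf("scaf%02d", seq_len(config$n_scaffolds)))

  ## CpG anchors on odd positions: each candidate kept independently, giving
  ## a binomial count around cg_per_kb per kb
  cg <- do.call(rbind, lapply(names(manifest), function(chr) {
    cand <- seq.int(1L, manifest[[chr]] - 1L, by = 2L)
    keep <- runif(length(cand)) < config$cg_per_kb / 500
    data.frame(chrom = chr, pos = cand[keep])
  }))

  ## genes: round-robin over scaffolds, sequential placement with random gaps
  glen <- round(rlnorm(config$n_genes, config$gene_length_meanlog,
                       config$gene_length_sdlog))
  glen <- pmin(pmax(glen, config$gene_length_min), config$gene_length_max)
  scaf_of <- rep(names(manifest), length.out = config$n_genes)
  gene_rows <- list()
  for (chr in names(manifest)) {
    idx <- which(scaf_of == chr)
    if (!length(idx)) next
    lens <- glen[idx]
    slack <- manifest[[chr]] - sum(lens)
    if (slack < length(idx) + 1)
      stop("infeasible packing: ", sum(lens), " bp of genes on a ",
           manifest[[chr]], " bp scaffold")
    w <- runif(length(idx) + 1)
    gaps <- floor(w / sum(w) * slack)
    inc <- if (length(idx) > 1) lens[-length(lens)] + gaps[2:length(idx)]
           else numeric(0)
    starts <- 1 + gaps[1L] + cumsum(c(0, inc))
    gene_rows[[chr]] <- data.frame(
      gene_id = sprintf("g%04d", idx), chrom = chr,
      strand = sample(c("+", "-"), length(idx), replace = TRUE),
      start = starts, end = starts + lens - 1,
      biotype = "protein_coding", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]; e <- genes$end[i]
    n_ex <- sample(3:6, 1)
    inner <- seq.int(s + 100L, e - 100L, by = 10L)
    if (length(inner) < 2 * (n_ex - 1)) n_ex <- 1L
    if (n_ex == 1L) return(data.frame(start = s, end = e))
    b <- sort(sample(inner, 2 * (n_ex - 1)))
    starts <- c(s, b[seq(2, length(b), by = 2)])
    ends <- c(b[seq(1, length(b), by = 2)] - 1L, e)
    data.frame(start = starts, end = ends)
  })

  repeats <- place_repeats(manifest, genes, config)
  list(manifest = manifest, cg_sites = cg, genes = genes, repeats = repeats,
       config = config)
}

place_repeats <- function(manifest, genes, config) {
  exons <- data.frame(
    chrom = rep(genes$chrom, vapply(genes$exons, nrow, integer(1))),
    start = unlist(lapply(genes$exons, `[[`, "start")),
    end = unlist(lapply(genes$exons, `[[`, "end")))
  accepted <- exons[0, ]
  accepted$te_class <- character()
  accepted$strand <- character()
  for (cl in names(config$n_te)) {
    rng <- config$te_length_range[[cl]]
    need <- config$n_te[[cl]]
    got <- 0L
    rounds <- 0L
    while (got < need) {
      rounds <- rounds + 1L
      if (rounds > 50L)
        stop("infeasible packing: could not place ", need, " ", cl,
             " elements outside exons")
      k <- 4L * (need - got)
      chr <- sample(names(manifest), k, replace = TRUE, prob = manifest)
      len <- sample(rng[1L]:rng[2L], k, replace = TRUE)
      st <- floor(runif(k) * (manifest[chr] - len)) + 1L
      cand <- data.frame(chrom = chr, start = st, end = st + len - 1L,
                         te_class = cl,
                         strand = sample(c("+", "-"), k, replace = TRUE),
                         stringsAsFactors = FALSE)
      blocked <- rbind(exons, accepted[c("chrom", "start", "end")])
      ## drop candidates hitting exons or already-placed elements, then
      ## greedily keep mutually non-overlapping ones in coordinate order
      ov <- suppressWarnings(GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start, cand$end)),
        GenomicRanges::GRanges(blocked$chrom,
                               IRanges::IRanges(blocked$start, blocked$end))))
      cand <- cand[setdiff(seq_len(k), S4Vectors::queryHits(ov)), ,
                   drop = FALSE]
      cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
      keep <- logical(nrow(cand))
      last_end <- -1L
      last_chr <- ""
      for (i in seq_len(nrow(cand))) {
        if (cand$chrom[i] != last_chr || cand$start[i] > last_end) {
          keep[i] <- TRUE
          last_chr <- cand$chrom[i]
          last_end <- cand$end[i]
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > need - got)
        cand <- cand[seq_len(need - got), , drop = FALSE]
      accepted <- rbind(accepted,
                        cand[c("chrom", "start", "end", "te_class",
                               "strand")])
      got <- got + nrow(cand)
    }
  }
  out <- accepted[c("chrom", "start", "end", "strand", "te_class")]
  rownames(out) <- NULL
  out
}

#' Draw a true methylome over a synthetic genome
#'
#' Assigns every CpG site a true methylation probability p and every gene an
#' expression tier (1-5, balanced) with a true expression value. In
#' vertebrate mode, background sites draw around `background_meth_mean`, TE
#' sites around `te_meth_mean`, and TSS-window sites from a tier-dependent
#' two-component mixture (tier 1 bimodal, tier 5 almost always
#' hypomethylated); TSS assignment takes precedence over TE, which takes
#' precedence over background. In mosaic mode, methylated domains are seeded
#' (preferentially on gene bodies) until they cover the configured genome
#' fraction; sites draw around the domain mean inside and the background
#' mean outside, with no TSS treatment.
#'
#' @param genome output of [make_genome()].
#' @param config the same [synth_config()].
#' @return list with `sites` (chrom, pos, p), `genes` (genome gene frame plus
#'   `tier` and `true_expr`), `mode`.
#' @export
make_methylome <- function(genome, config) {
  set.seed(config$seed + 1L)
  sites <- genome$cg_sites
  genes <- genome$genes
  n <- nrow(sites)

  tier <- sample(rep(1:5, length.out = nrow(genes)))
  genes$tier <- tier
  genes$true_expr <- config$tier_means[tier] * rlnorm(nrow(genes), 0, 0.4)

  if (config$mode == "vertebrate") {
    p <- rbeta_mc(n, config$background_meth_mean, config$background_meth_conc)
    in_te <- overlap_pairs(sites$chrom, sites$pos, genome$repeats$chrom,
                           genome$repeats$start, genome$repeats$end)
    p[unique(in_te$site)] <- rbeta_mc(length(unique(in_te$site)),
                                      config$te_meth_mean,
                                      config$te_meth_conc)
    tssw <- tss_windows(genes, width = 200, manifest = genome$manifest)
    in_tss <- overlap_pairs(sites$chrom, sites$pos,
                            tssw$chrom, tssw$start, tssw$end)
    if (nrow(in_tss)) {
      ## mixture membership is drawn per TSS, not per site: a methylated
      ## promoter is methylated as a unit, giving the bimodal per-gene
      ## distribution seen at low expression tiers
      tss_hi <- runif(nrow(tssw)) <
        config$tss_meth_weight_by_tier[tier]
      hi <- tss_hi[in_tss$interval]
      draw <- ifelse(hi,
                     rbeta_mc(nrow(in_tss), config$tss_high_mean,
                              config$tss_conc),
                     rbeta_mc(nrow(in_tss), config$tss_low_mean,
                              config$tss_conc))
      ## a site in several TSS windows keeps the last draw (rare overlap)
      p[in_tss$site] <- draw
    }
  } else {
    target <- config$mosaic_domain_fraction * sum(genome$manifest)
    domains <- GenomicRanges::GRanges()
    covered <- 0
    while (covered < target) {
      if (runif(1) < config$mosaic_genic_bias && nrow(genes)) {
        g <- genes[sample.int(nrow(genes), 1), ]
        cand <- GenomicRanges::GRanges(g$chrom,
                                       IRanges::IRanges(g$start, g$end))
      } else {
        chr <- sample(names(genome$manifest), 1, prob = genome$manifest)
        len <- min(round(500 + stats::rexp(1, 1 / 2500)),
                   genome$manifest[[chr]])
        st <- sample.int(genome$manifest[[chr]] - len + 1, 1)
        cand <- GenomicRanges::GRanges(chr,
                                       IRanges::IRanges(st, st + len - 1))
      }
      domains <- GenomicRanges::reduce(suppressWarnings(c(domains, cand)))
      covered <- sum(GenomicRanges::width(domains))
    }
    dom <- as.data.frame(domains)
    in_dom <- overlap_pairs(sites$chrom, sites$pos,
                            as.character(dom$seqnames), dom$start, dom$end)
    p <- rbeta_mc(n, config$mosaic_background_mean, config$mosaic_conc)
    p[unique(in_dom$site)] <- rbeta_mc(length(unique(in_dom$site)),
                                       config$mosaic_domain_mean,
                                       config$mosaic_conc)
  }
  sites$p <- p
  list(sites = sites, genes = genes, mode = config$mode)
}

#' Simulate bisulfite calls and read records from a true methylome
#'
#' Each CpG site receives Poisson call depth on each strand (mean
#' `mean_depth`/2 per strand) and each call reads methylated with probability
#' p + (1-p) * `conversion_failure_rate`. Non-CG cytosines are emitted with
#' true p = 0 at `noncg_per_kb`, so their observed methylation approximates
#' the conversion-failure rate. Read records cover runs of consecutive CpG
#' sites (geometric-like length around `read_mean_cg` calls), giving the
#' within-read call grouping the bootstrap resamples.
#'
#' @param methylome output of [make_methylome()].
#' @param genome output of [make_genome()].
#' @param config the same [synth_config()].
#' @return list with `calls` (a [site_call_table()]) and `reads` (read_id,
#'   n_meth, n_unmeth).
#' @export
simulate_calls <- function(methylome, genome, config) {
  set.seed(config$seed + 2L)
  s <- methylome$sites
  n <- nrow(s)
  p_eff <- s$p + (1 - s$p) * config$conversion_failure_rate
  d_plus <- rpois(n, config$mean_depth / 2)
  d_minus <- rpois(n, config$mean_depth / 2)
  m_plus <- rbinom(n, d_plus, p_eff)
  m_minus <- rbinom(n, d_minus, p_eff)
  cg_calls <- data.frame(
    chrom = rep(s$chrom, 2L),
    pos = c(s$pos, s$pos + 1L),
    strand = rep(c("+", "-"), each = n),
    context = "CG",
    n_meth = c(m_plus, m_minus),
    n_unmeth = c(d_plus - m_plus, d_minus - m_minus))

  noncg <- do.call(rbind, lapply(names(genome$manifest), function(chr) {
    len <- genome$manifest[[chr]]
    k <- round(len * config$noncg_per_kb / 1000)
    taken <- s$pos[s$chrom == chr] + 1L   # even partner positions in use
    cand <- setdiff(seq.int(2L, len, by = 2L), taken)
    pos <- sort(sample(cand, min(k, length(cand))))
    data.frame(chrom = chr, pos = pos, strand = "+",
               context = sample(c("CHG", "CHH"), length(pos), replace = TRUE,
                                prob = c(1, 2)))
  }))
  d_nc <- rpois(nrow(noncg), config$mean_depth)
  m_nc <- rbinom(nrow(noncg), d_nc, config$conversion_failure_rate)
  noncg$n_meth <- m_nc
  noncg$n_unmeth <- d_nc - m_nc

  calls <- site_call_table(rbind(cg_calls, noncg), manifest = genome$manifest)

  ## read records over runs of consecutive CpG sites
  o <- order(s$chrom, s$pos)
  chrom_o <- s$chrom[o]
  p_o <- p_eff[o]
  chrom_end <- cumsum(as.integer(table(chrom_o)[unique(chrom_o)]))
  names(chrom_end) <- unique(chrom_o)
  start_idx <- sample.int(n, config$n_reads, replace = TRUE)
  len_r <- 1L + rpois(config$n_reads, max(config$read_mean_cg - 1, 0))
  end_idx <- pmin(start_idx + len_r - 1L, chrom_end[chrom_o[start_idx]])
  sizes <- end_idx - start_idx + 1L
  site_idx <- sequence(sizes) - 1L + rep(start_idx, sizes)
  meth <- rbinom(length(site_idx), 1L, p_o[site_idx])
  read_id <- rep(seq_len(config$n_reads), sizes)
  nm <- tapply(meth, factor(read_id, levels = seq_len(config$n_reads)), sum)
  reads <- data.frame(read_id = sprintf("r%06d", seq_len(config$n_reads)),
                      n_meth = as.integer(nm),
                      n_unmeth = as.integer(sizes - nm))
  list(calls = calls, reads = reads)
}

#' Simulate RNA-seq reads and per-gene counts
#'
#' Per-gene transcription read counts are negative-binomial with mean equal
#' to the gene's true expression (reads per exonic kb) times its exonic
#' length; reads are placed inside exons. Uniform DNA contamination is added
#' at `contamination_density` reads per kb of genome. A fraction of
#' transcription reads is emitted below the mapping-quality threshold to
#' exercise the uniquely-aligned filter.
#'
#' @inheritParams simulate_calls
#' @return list with `reads` (chrom, start, end, mapq, source), `counts`
#'   (gene_id, count: passing reads overlapping each gene's exons) and
#'   `truth` (gene_id, tier, true_expr, n_transcribed: planted passing
#'   transcription reads per gene).
#' @export
simulate_expression <- function(methylome, genome, config) {
  set.seed(config$seed + 3L)
  genes <- methylome$genes
  ex_kb <- exonic_length_bp(genes) / 1000
  mu <- genes$true_expr * ex_kb
  n_tx <- rnbinom(nrow(genes), mu = mu, size = config$nb_size)
  read_len <- 100L
  tx_rows <- lapply(seq_len(nrow(genes)), function(i) {
    k <- n_tx[i]
    if (!k) return(NULL)
    exd <- genes$exons[[i]]
    w <- exd$end - exd$start + 1
    j <- sample.int(nrow(exd), k, replace = TRUE, prob = w)
    st <- exd$start[j] + floor(runif(k) * pmax(w[j] - read_len + 1, 1))
    en <- pmin(st + read_len - 1L, exd$end[j])
    data.frame(chrom = genes$chrom[i], start = st, end = en, gene = i)
  })
  tx <- do.call(rbind, tx_rows)
  if (is.null(tx)) tx <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), gene = integer())
  mapq_tx <- ifelse(runif(nrow(tx)) < config$low_mapq_frac, 30L, 60L)

  n_contam <- rpois(1, config$contamination_density * sum(genome$manifest) /
                      1000)
  chr_c <- sample(names(genome$manifest), n_contam, replace = TRUE,
                  prob = genome$manifest)
  st_c <- floor(runif(n_contam) * (genome$manifest[chr_c] - read_len)) + 1L
  contam <- data.frame(chrom = chr_c, start = st_c,
                       end = st_c + read_len - 1L)

  reads <- rbind(
    data.frame(chrom = tx$chrom, start = tx$start, end = tx$end,
               mapq = mapq_tx, source = rep("transcription", nrow(tx))),
    data.frame(chrom = contam$chrom, start = contam$start, end = contam$end,
               mapq = rep(60L, n_contam),
               source = rep("contamination", n_contam)))
  rownames(reads) <- NULL

  counts <- count_exonic_reads(reads, genes, mapq_min = 60)
  truth <- data.frame(gene_id = genes$gene_id, tier = genes$tier,
                      true_expr = genes$true_expr,
                      n_transcribed = as.integer(
                        tabulate(tx$gene[mapq_tx >= 60], nrow(genes))))
  list(reads = reads,
       counts = data.frame(gene_id = genes$gene_id,
                           count = as.integer(counts)),
       truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_genome()], [make_methylome()], [simulate_calls()] and
#' [simulate_expression()] under one configuration, optionally writing every
#' artifact in the package's standard dialects (cytosine report, coverage
#' file, GFF3, rmsk table, manifest TSV, read-record TSV, counts TSV, truth
#' TSVs and a JSON config echo).
#'
#' @param config a [synth_config()].
#' @param out_dir if non-NULL, directory to write the files into.
#' @return list with `genome`, `methylome`, `calls`, `reads`, `expression`,
#'   `config` (and `files` when written).
#' @export
simulate_methylome_dataset <- function(config, out_dir = NULL) {
  genome <- make_genome(config)
  methylome <- make_methylome(genome, config)
  sim <- simulate_calls(methylome, genome, config)
  expr <- simulate_expression(methylome, genome, config)
  out <- list(genome = genome, methylome = methylome, calls = sim$calls,
              reads = sim$reads, expression = expr, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(out_dir, x)
    write_cytosine_report(sim$calls, f("calls.cx.tsv"))
    cg <- sim$calls[sim$calls$context == "CG" & sim$calls$strand == "+", ]
    write_bismark_coverage(cg, f("calls.cov.tsv"))
    write_gene_annotation(genome$genes, f("genes.gff3"))
    write_repeat_annotation(genome$repeats, f("repeats.rmsk.tsv"))
    write_genome_manifest(genome$manifest, f("genome.manifest.tsv"))
    data.table::fwrite(sim$reads, f("reads.tsv"), sep = "\t")
    data.table::fwrite(expr$counts, f("counts.tsv"), sep = "\t")
    data.table::fwrite(expr$reads, f("rna_reads.tsv"), sep = "\t")
    data.table::fwrite(methylome$sites, f("truth_sites.tsv"), sep = "\t")
    data.table::fwrite(expr$truth, f("truth_genes.tsv"), sep = "\t")
    jsonlite::write_json(unclass(config), f("config.json"),
                         auto_unbox = TRUE, digits = NA)
    out$files <- list.files(out_dir, full.names = TRUE)
  }
  out
}
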