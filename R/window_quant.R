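## Interval-level quantitation: running windows, TSS windows, gene bodies.

## index pairs (site row, interval row); strand-blind point-in-interval
overlap_pairs <- function(site_chrom, site_pos, iv_chrom, iv_start, iv_end) {
  q <- GenomicRanges::GRanges(site_chrom,
                              IRanges::IRanges(site_pos, width = 1L))
  s <- GenomicRanges::GRanges(iv_chrom, IRanges::IRanges(iv_start, iv_end))
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  })
  data.frame(site = S4Vectors::queryHits(hits),
             interval = S4Vectors::subjectHits(hits))
}

#' Tile running windows over a genome manifest
#'
#' Windows of `size` bp are laid from position 1 of each scaffold at `step`
#' intervals (default step = size, i.e. non-overlapping tiling that covers the
#' genome exactly once). The terminal partial window is retained and flagged,
#' so every base of every scaffold is covered.
#'
#' @param manifest named numeric vector of scaffold lengths (or two-column
#'   data.frame).
#' @param size window width in bp.
#' @param step distance between window starts in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `partial`.
#' @export
running_windows <- function(manifest, size = 2000, step = size) {
  manifest <- as_manifest(manifest)
  if (size < 1 || step < 1) stop("size and step must be >= 1")
  pieces <- lapply(names(manifest), function(chr) {
    len <- manifest[[chr]]
    starts <- seq.int(1L, len, by = step)
    ends <- pmin(starts + size - 1, len)
    data.frame(chrom = chr, start = starts, end = ends,
               partial = ends - starts + 1 < size)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Call-weighted methylation per interval
#'
#' For each interval, pools the calls of every CpG site whose anchor (the +
#' strand C of the dinucleotide) lies inside it, and reports the call-weighted
#' percentage. Anchoring membership on the single + strand coordinate means a
#' dinucleotide straddling a window edge is counted exactly once. Intervals
#' with fewer than `min_calls` calls are flagged excluded (`percent = NA`).
#'
#' @param sites pooled CpG sites ([merge_symmetric_cg()]).
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); extra columns are carried through.
#' @param min_calls minimum calls for an interval to be included.
#' @return `intervals` with added `n_meth`, `n_calls`, `percent`, `included`.
#' @export
quantify_windows <- function(sites, intervals, min_calls = 1) {
  if (!is.numeric(min_calls) || min_calls < 1)
    stop("min_calls must be >= 1")
  n <- nrow(intervals)
  n_meth <- numeric(n)
  n_calls <- numeric(n)
  if (nrow(sites) && n) {
    ov <- overlap_pairs(sites$chrom, sites$pos,
                        intervals$chrom, intervals$start, intervals$end)
    if (nrow(ov)) {
      nm <- tapply(sites$n_meth[ov$site], ov$interval, sum)
      nc <- tapply((sites$n_meth + sites$n_unmeth)[ov$site], ov$interval, sum)
      idx <- as.integer(names(nm))
      n_meth[idx] <- nm
      n_calls[idx] <- nc
    }
  }
  out <- intervals
  out$n_meth <- n_meth
  out$n_calls <- n_calls
  out$included <- n_calls >= min_calls
  out$percent <- ifelse(out$included, 100 * n_meth / n_calls, NA_real_)
  out
}

#' Windows centred on transcription start sites
#'
#' Places a window of `width` bp (default 200) centred on the first nucleotide
#' of each annotated mRNA: on the + strand the window runs from width/2 bp
#' before the first nucleotide through width/2 - 1 bp after it (the one extra
#' base implied by centring an even width on a single nucleotide is placed
#' downstream); the placement is mirrored on the - strand. Windows running off
#' a scaffold edge are clipped and flagged truncated.
#'
#' @param genes gene models ([read_gene_annotation()]).
#' @param width window width in bp; must be even and >= 2.
#' @param manifest optional scaffold lengths, used to clip at scaffold ends.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `truncated`.
#' @export
tss_windows <- function(genes, width = 200, manifest = NULL) {
  if (width < 2 || width %% 2 != 0)
    stop("width must be an even integer >= 2")
  half <- width %/% 2
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - half, tss - half + 1)
  end <- ifelse(plus, tss + half - 1, tss + half)
  lo <- pmax(start, 1)
  hi <- end
  if (!is.null(manifest)) {
    manifest <- as_manifest(manifest)
    hi <- pmin(end, manifest[genes$chrom])
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = lo, end = hi, strand = genes$strand,
             truncated = lo != start | hi != end,
             stringsAsFactors = FALSE)
}

#' Methylation of TSS windows
#'
#' Call-weighted methylation of the 200 bp window centred on each gene's first
#' nucleotide; windows with fewer than `min_calls` calls are excluded.
#'
#' @inheritParams quantify_windows
#' @inheritParams tss_windows
#' @param min_calls minimum calls in a window for inclusion.
#' @return per-gene data.frame with window coordinates, `n_calls`, `percent`,
#'   `included`.
#' @export
tss_methylation <- function(sites, genes, min_calls = 5, width = 200,
                            manifest = NULL) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene models")
  win <- tss_windows(genes, width = width, manifest = manifest)
  quantify_windows(sites, win, min_calls = min_calls)
}

#' Gene-body methylation from 2 kb running windows
#'
#' The transcribed unit, excluding its 5'-most `exclude_5prime` bp (where
#' promoter hypomethylation would otherwise dilute the body signal), is tiled
#' strand-aware with windows of `window` bp from the 5' end toward the 3' end
#' (terminal partial window retained). Each window is quantified call-weighted
#' and kept only if it carries at least `min_calls_per_window` calls; the gene
#' value is the unweighted mean of the passing windows' percentages. Genes
#' shorter than `exclude_5prime` + 1 bp, or with no passing window, are
#' excluded with a reason.
#'
#' @inheritParams quantify_windows
#' @param genes gene models.
#' @param window window width in bp.
#' @param exclude_5prime bp trimmed from the 5' end of each gene.
#' @param min_calls_per_window minimum calls for a window to enter the mean.
#' @return data.frame with `gene_id`, `percent` (NA when excluded),
#'   `n_windows`, `n_windows_passing`, `excluded_reason`.
#' @export
gene_body_methylation <- function(sites, genes, window = 2000,
                                  exclude_5prime = 1000,
                                  min_calls_per_window = 50) {
  wins <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start + 1
    if (len <= exclude_5prime) next
    if (g$strand == "+") {
      starts <- seq.int(g$start + exclude_5prime, g$end, by = window)
      ends <- pmin(starts + window - 1, g$end)
    } else {
      ends <- seq.int(g$end - exclude_5prime, g$start, by = -window)
      starts <- pmax(ends - window + 1, g$start)
    }
    wins[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
  }
  too_short <- vapply(wins, is.null, logical(1))
  all_wins <- if (all(too_short)) NULL else do.call(rbind, wins[!too_short])
  out <- data.frame(gene_id = genes$gene_id, percent = NA_real_,
                    n_windows = 0L, n_windows_passing = 0L,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  out$excluded_reason[too_short] <- "shorter_than_5prime_exclusion"
  if (!is.null(all_wins)) {
    q <- quantify_windows(sites, all_wins, min_calls = min_calls_per_window)
    means <- tapply(q$percent[q$included], q$gene_id[q$included], mean)
    n_w <- table(q$gene_id)
    n_p <- tapply(q$included, q$gene_id, sum)
    idx <- match(names(n_w), out$gene_id)
    out$n_windows[idx] <- as.integer(n_w)
    out$n_windows_passing[match(names(n_p), out$gene_id)] <- as.integer(n_p)
    out$percent[match(names(means), out$gene_id)] <- as.numeric(means)
    no_pass <- !too_short & is.na(out$percent)
    out$excluded_reason[no_pass] <- "no_window_passing_call_threshold"
  }
  out
}
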