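#' @import methods
#' @importFrom stats median quantile rbeta rbinom rlnorm rnbinom rpois runif
#'   setNames complete.cases cor t.test coef lm
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

TE_CLASSES <- c("LINE", "SINE", "LTR", "DNA")
CONTEXTS <- c("CG", "CHG", "CHH")

## ---- site call tables -------------------------------------------------------

#' Construct a per-cytosine call table
#'
#' A site call table holds one record per (scaffold, position, strand) with
#' methylated and unmethylated call counts and sequence context, plus a genome
#' manifest (scaffold lengths) and an optional set of scaffolds designated
#' mitochondrial. It is the substrate for all downstream quantitation.
#'
#' @param calls data.frame with columns `chrom`, `pos` (1-based position of the
#'   cytosine on its own strand), `strand` (`+`/`-`), `context`
#'   (`CG`/`CHG`/`CHH`), `n_meth`, `n_unmeth`.
#' @param manifest named numeric vector of scaffold lengths in bp, or a
#'   two-column data.frame (name, length). If `NULL`, lengths are inferred as
#'   the maximum observed position + 1 per scaffold.
#' @param mito_ids character vector of scaffold names designated mitochondrial.
#' @return A `site_call_table`: a data.frame sorted by (chrom, pos, strand)
#'   with `manifest` and `mito_ids` attributes.
#' @export
site_call_table <- function(calls, manifest = NULL, mito_ids = character()) {
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table is missing columns: ", paste(miss, collapse = ", "))
  calls <- as.data.frame(calls)[need]
  calls$chrom <- as.character(calls$chrom)
  calls$strand <- as.character(calls$strand)
  calls$context <- as.character(calls$context)
  validate_site_calls(calls)
  manifest <- if (is.null(manifest)) infer_manifest(calls) else as_manifest(manifest)
  absent <- setdiff(unique(calls$chrom), names(manifest))
  if (length(absent))
    stop("scaffolds absent from manifest: ", paste(absent, collapse = ", "))
  o <- order(calls$chrom, calls$pos, calls$strand)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls,
            manifest = manifest,
            mito_ids = as.character(mito_ids),
            class = c("site_call_table", "data.frame"))
}

validate_site_calls <- function(calls) {
  bad <- which(!(calls$strand %in% c("+", "-")))
  if (length(bad))
    stop("invalid strand at record(s) ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!(calls$context %in% CONTEXTS))
  if (length(bad))
    stop("invalid context at record(s) ", paste(head(bad, 5), collapse = ", "))
  bad <- which(is.na(calls$n_meth) | is.na(calls$n_unmeth) |
                 calls$n_meth < 0 | calls$n_unmeth < 0)
  if (length(bad))
    stop("negative or missing call counts at record(s) ",
         paste(head(bad, 5), collapse = ", "))
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, strand) records, e.g. ",
         key[which(duplicated(key))[1L]])
  invisible(calls)
}

as_manifest <- function(x) {
  if (is.data.frame(x)) {
    m <- setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
  } else {
    m <- setNames(as.numeric(x), names(x))
  }
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("manifest must carry scaffold names")
  if (any(is.na(m) | m < 1)) stop("manifest lengths must be positive")
  m
}

infer_manifest <- function(calls) {
  if (!nrow(calls)) return(setNames(numeric(0), character(0)))
  tapply(calls$pos + 1, calls$chrom, max)[unique(calls$chrom)]
}

#' @rdname site_call_table
#' @param x a `site_call_table`
#' @export
genome_manifest <- function(x) attr(x, "manifest", exact = TRUE)

#' @rdname site_call_table
#' @export
mito_ids <- function(x) attr(x, "mito_ids", exact = TRUE)

#' @export
print.site_call_table <- function(x, ...) {
  cat(sprintf("site_call_table: %d records on %d scaffold(s); contexts: %s\n",
              nrow(x), length(genome_manifest(x)),
              paste(sort(unique(x$context)), collapse = ", ")))
  NextMethod()
}

## ---- cytosine report dialect ------------------------------------------------

#' Read a per-cytosine report
#'
#' Parses the tab-delimited per-cytosine (CX) dialect: chrom, pos, strand,
#' count methylated, count unmethylated, context, trinucleotide. Gzip input is
#' handled transparently. An empty file yields an empty table.
#'
#' @param path path to the report (optionally `.gz`).
#' @inheritParams site_call_table
#' @return A [site_call_table()].
#' @export
read_cytosine_report <- function(path, manifest = NULL, mito_ids = character()) {
  dt <- if (file.exists(path) && file.size(path) == 0) data.table::data.table()
        else data.table::fread(path, header = FALSE, sep = "\t",
                               colClasses = list(character = c(1, 3, 6, 7)),
                               fill = TRUE, showProgress = FALSE)
  if (!nrow(dt)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        n_meth = integer(), n_unmeth = integer())
    return(site_call_table(empty, manifest = manifest, mito_ids = mito_ids))
  }
  if (ncol(dt) < 6)
    stop("malformed cytosine report: fewer than 6 columns in ", path)
  calls <- data.frame(chrom = dt[[1L]],
                      pos = suppressWarnings(as.integer(dt[[2L]])),
                      strand = dt[[3L]],
                      context = dt[[6L]],
                      n_meth = suppressWarnings(as.integer(dt[[4L]])),
                      n_unmeth = suppressWarnings(as.integer(dt[[5L]])))
  bad <- which(is.na(calls$pos) | is.na(calls$n_meth) | is.na(calls$n_unmeth))
  if (length(bad))
    stop("malformed cytosine report line(s): ",
         paste(head(bad, 5), collapse = ", "), " in ", path)
  neg <- which(calls$n_meth < 0 | calls$n_unmeth < 0)
  if (length(neg))
    stop("negative counts at line(s): ", paste(head(neg, 5), collapse = ", "))
  site_call_table(calls, manifest = manifest, mito_ids = mito_ids)
}

#' Write a per-cytosine report
#'
#' Emits the same tab-delimited dialect [read_cytosine_report()] consumes, so
#' write-then-read round-trips reproduce all call counts exactly. The
#' trinucleotide column, which carries no quantitative information here, is
#' filled with the context string.
#'
#' @param table a [site_call_table()].
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
write_cytosine_report <- function(table, path) {
  out <- data.table::data.table(table$chrom, table$pos, table$strand,
                                table$n_meth, table$n_unmeth, table$context,
                                table$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

## ---- coverage dialect -------------------------------------------------------

#' Read a coverage-dialect call file
#'
#' Parses the six-column coverage dialect (chrom, start, end, methylation
#' percentage, count methylated, count unmethylated). That dialect encodes
#' neither context nor strand, so records are created as CG-context calls on
#' the + strand of the reported cytosine by declared convention (overridable
#' via `context`/`strand`). The percentage column is ignored and recomputed
#' from the counts; an inconsistency beyond rounding raises a warning and the
#' counts win.
#'
#' @inheritParams read_cytosine_report
#' @param context,strand convention applied to every record.
#' @return A [site_call_table()].
#' @export
read_bismark_coverage <- function(path, manifest = NULL,
                                  mito_ids = character(),
                                  context = "CG", strand = "+") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (!nrow(dt)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        n_meth = integer(), n_unmeth = integer())
    return(site_call_table(empty, manifest = manifest, mito_ids = mito_ids))
  }
  if (ncol(dt) < 6) stop("malformed coverage file: fewer than 6 columns")
  n_meth <- as.integer(dt[[5L]])
  n_unmeth <- as.integer(dt[[6L]])
  tot <- n_meth + n_unmeth
  recomputed <- ifelse(tot > 0, 100 * n_meth / tot, NA_real_)
  stated <- as.numeric(dt[[4L]])
  off <- which(tot > 0 & abs(stated - recomputed) > 0.1)
  if (length(off))
    warning(length(off), " record(s) with a percentage inconsistent with the ",
            "counts beyond rounding; counts used")
  calls <- data.frame(chrom = dt[[1L]], pos = as.integer(dt[[2L]]),
                      strand = strand, context = context,
                      n_meth = n_meth, n_unmeth = n_unmeth)
  site_call_table(calls, manifest = manifest, mito_ids = mito_ids)
}

#' Write a coverage-dialect call file
#'
#' @inheritParams write_cytosine_report
#' @export
write_bismark_coverage <- function(table, path) {
  tot <- table$n_meth + table$n_unmeth
  pct <- ifelse(tot > 0, 100 * table$n_meth / tot, 0)
  out <- data.table::data.table(table$chrom, table$pos, table$pos, pct,
                                table$n_meth, table$n_unmeth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a two-column genome manifest (scaffold name, length in bp)
#'
#' @param path tab-separated file with columns name and length, no header.
#' @return named numeric vector of scaffold lengths.
#' @export
read_genome_manifest <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  as_manifest(data.frame(dt[[1L]], as.numeric(dt[[2L]])))
}

#' @rdname read_genome_manifest
#' @param manifest named numeric vector of scaffold lengths.
#' @export
write_genome_manifest <- function(manifest, path) {
  data.table::fwrite(data.table::data.table(names(manifest),
                                            as.integer(manifest)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- gene annotation --------------------------------------------------------

#' Read gene models from GFF3 or GTF
#'
#' Builds one gene model per mRNA/transcript feature, with its exon intervals,
#' strand and biotype. The transcript's first nucleotide (the `start` field on
#' the + strand, `end` on the - strand) defines the transcription start site
#' downstream. Exons without a resolvable parent transcript are skipped with a
#' message; transcripts lacking a strand are rejected with a warning.
#'
#' @param path a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @param biotype_filter if non-NULL, keep only transcripts with this biotype
#'   (e.g. `"protein_coding"`).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `biotype` and a list-column `exons` of two-column (start, end)
#'   data.frames, sorted and non-overlapping.
#' @export
read_gene_annotation <- function(path, biotype_filter = NULL) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if (fmt == "gtf") {
    is_tx <- type == "transcript"
    tx_id <- as.character(mc$transcript_id)
    bio <- if (!is.null(mc$gene_biotype)) as.character(mc$gene_biotype)
           else if (!is.null(mc$transcript_biotype)) as.character(mc$transcript_biotype)
           else rep(NA_character_, length(gr))
    exon_parent <- ifelse(type == "exon", tx_id, NA_character_)
  } else {
    is_tx <- type %in% c("mRNA", "transcript")
    tx_id <- as.character(mc$ID)
    bio <- if (!is.null(mc$biotype)) as.character(mc$biotype)
           else if (!is.null(mc$gene_biotype)) as.character(mc$gene_biotype)
           else rep(NA_character_, length(gr))
    par <- mc$Parent
    first_parent <- vapply(as.list(par), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    exon_parent <- ifelse(type == "exon", first_parent, NA_character_)
  }
  tx <- which(is_tx)
  if (!length(tx))
    return(empty_gene_frame())
  strand <- as.character(GenomicRanges::strand(gr))
  no_strand <- tx[strand[tx] == "*"]
  if (length(no_strand)) {
    warning(length(no_strand), " transcript(s) without strand rejected")
    tx <- setdiff(tx, no_strand)
  }
  ex <- which(type == "exon")
  orphan <- ex[is.na(exon_parent[ex]) | !(exon_parent[ex] %in% tx_id[tx])]
  if (length(orphan))
    message(length(orphan), " exon(s) without a parent transcript skipped")
  ex <- setdiff(ex, orphan)
  ex_by_tx <- split(ex, exon_parent[ex])
  genes <- data.frame(gene_id = tx_id[tx],
                      chrom = as.character(GenomicRanges::seqnames(gr))[tx],
                      strand = strand[tx],
                      start = GenomicRanges::start(gr)[tx],
                      end = GenomicRanges::end(gr)[tx],
                      biotype = bio[tx],
                      stringsAsFactors = FALSE)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- ex_by_tx[[genes$gene_id[i]]]
    if (is.null(idx) || !length(idx))
      return(data.frame(start = genes$start[i], end = genes$end[i]))
    ir <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(gr)[idx],
                                           GenomicRanges::end(gr)[idx]))
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  if (!is.null(biotype_filter))
    genes <- genes[!is.na(genes$biotype) & genes$biotype == biotype_filter, ,
                   drop = FALSE]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate transcript identifiers in ", path)
  rownames(genes) <- NULL
  genes
}

empty_gene_frame <- function() {
  g <- data.frame(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  biotype = character(), stringsAsFactors = FALSE)
  g$exons <- list()
  g
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features in the layout [read_gene_annotation()]
#' parses, including the biotype attribute.
#'
#' @param genes gene model data.frame as returned by [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- paste0("gene:", g$gene_id)
    attr_g <- sprintf("ID=%s;biotype=%s", gid, g$biotype)
    attr_m <- sprintf("ID=%s;Parent=%s;biotype=%s", g$gene_id, gid, g$biotype)
    lines <- c(lines,
      paste(g$chrom, "methylomap", "gene", g$start, g$end, ".", g$strand, ".",
            attr_g, sep = "\t"),
      paste(g$chrom, "methylomap", "mRNA", g$start, g$end, ".", g$strand, ".",
            attr_m, sep = "\t"))
    exd <- g$exons[[1L]]
    for (j in seq_len(nrow(exd)))
      lines <- c(lines,
        paste(g$chrom, "methylomap", "exon", exd$start[j], exd$end[j], ".",
              g$strand, ".",
              sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, j, g$gene_id),
              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- repeat annotation ------------------------------------------------------

collapse_te_class <- function(x) {
  cls <- toupper(sub("/.*$", "", x))
  out <- ifelse(cls %in% TE_CLASSES, cls, "other")
  out[is.na(x) | !nzchar(x)] <- "other"
  out
}

#' Read repeat annotation
#'
#' Supports the UCSC rmsk tab-separated table (0-based starts; repClass in
#' column 12) and the RepeatMasker `.out` format (whitespace-separated with a
#' three-line header; class/family in column 11, `C` strand meaning -). The
#' class/family string is collapsed to the controlled set LINE/SINE/LTR/DNA,
#' with anything else (or unparseable) mapped to `other`.
#'
#' @param path annotation file.
#' @param dialect `"rmsk_table"` or `"repeatmasker_out"`.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `te_class`.
#' @export
read_repeat_annotation <- function(path,
                                   dialect = c("rmsk_table",
                                               "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  if (dialect == "rmsk_table") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            showProgress = FALSE)
    if (nrow(dt) && ncol(dt) < 12)
      stop("rmsk table needs at least 12 columns")
    if (!nrow(dt)) return(empty_repeat_frame())
    rep_frame(chrom = as.character(dt[[6L]]),
              start = as.integer(dt[[7L]]) + 1L,  # UCSC starts are 0-based
              end = as.integer(dt[[8L]]),
              strand = as.character(dt[[10L]]),
              te_class = collapse_te_class(as.character(dt[[12L]])))
  } else {
    raw <- readLines(path)
    body <- raw[-seq_len(min(3L, length(raw)))]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) return(empty_repeat_frame())
    fields <- strsplit(trimws(body), "\\s+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 11))
      stop("unparseable RepeatMasker .out line(s): ",
           paste(head(which(nf < 11), 5), collapse = ", "))
    pick <- function(k) vapply(fields, `[[`, character(1), k)
    strand <- pick(9L)
    rep_frame(chrom = pick(5L),
              start = as.integer(pick(6L)),
              end = as.integer(pick(7L)),
              strand = ifelse(strand == "C", "-", strand),
              te_class = collapse_te_class(pick(11L)))
  }
}

rep_frame <- function(chrom, start, end, strand, te_class) {
  if (any(end < start)) stop("repeat element with end < start")
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    te_class = te_class, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_repeat_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), te_class = character(),
             stringsAsFactors = FALSE)
}

#' Write repeat annotation as an rmsk-style tab table
#'
#' @param repeats data.frame as returned by [read_repeat_annotation()].
#' @param path output path.
#' @export
write_repeat_annotation <- function(repeats, path) {
  n <- nrow(repeats)
  out <- data.table::data.table(
    0L, 0L, 0L, 0L, 0L,
    repeats$chrom, repeats$start - 1L, repeats$end, 0L,
    repeats$strand, paste0(repeats$te_class, "-element"), repeats$te_class,
    repeats$te_class)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- scaffold filter --------------------------------------------------------

#' Drop records on short scaffolds
#'
#' Retains records only on scaffolds whose length is strictly greater than
#' `min_length_bp` (default 277 kb, guarding against assembly artefacts and
#' poorly annotated short scaffolds). Scaffolds flagged mitochondrial are
#' retained regardless of length, since the mitochondrial genome is analysed
#' as its own compartment.
#'
#' @param table a [site_call_table()].
#' @param min_length_bp length threshold in bp; strict inequality.
#' @return filtered `site_call_table` with an unchanged manifest.
#' @export
filter_scaffolds <- function(table, min_length_bp = 277000) {
  manifest <- genome_manifest(table)
  absent <- setdiff(unique(table$chrom), names(manifest))
  if (length(absent))
    stop("scaffolds absent from manifest: ", paste(absent, collapse = ", "))
  mito <- mito_ids(table)
  keep_chrom <- names(manifest)[manifest > min_length_bp]
  keep_chrom <- union(keep_chrom, mito)
  keep <- table$chrom %in% keep_chrom
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, manifest = manifest, mito_ids = mito,
            class = c("site_call_table", "data.frame"))
}
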