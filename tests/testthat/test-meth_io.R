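test_that("cytosine report lines map to call records verbatim", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t100\t+\t7\t3\tCG\tCGT", f)
  tab <- read_cytosine_report(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(as.data.frame(tab),
               call_df("s1", 100L, "+", "CG", 7L, 3L), ignore_attr = TRUE)
})

test_that("an empty cytosine report yields an empty table without error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  tab <- read_cytosine_report(f)
  expect_s3_class(tab, "site_call_table")
  expect_equal(nrow(tab), 0L)
})

test_that("negative counts and malformed lines are rejected with a location", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\t100\t+\t7\t3\tCG\tCGT",
               "s1\t104\t+\t-1\t3\tCG\tCGT"), f)
  expect_error(read_cytosine_report(f), "2")
  writeLines(c("s1\t100\t+\t7\t3\tCG\tCGT",
               "s1\tnot_a_number\t+\t7\t3\tCG\tCGT"), f)
  expect_error(read_cytosine_report(f), "malformed")
})

test_that("cytosine-report write then read round-trips a 1000-record table", {
  set.seed(11)
  n <- 1000L
  calls <- call_df(sample(c("s1", "s2"), n, TRUE),
                   sample.int(50000L, n), "+",
                   sample(c("CG", "CHG", "CHH"), n, TRUE),
                   rbinom(n, 30, 0.6), rbinom(n, 30, 0.4))
  calls <- calls[!duplicated(calls[c("chrom", "pos", "strand")]), ]
  man <- c(s1 = 60000, s2 = 60000)
  tab <- site_call_table(calls, manifest = man)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(tab, f)
  back <- read_cytosine_report(f, manifest = man)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(genome_manifest(back), genome_manifest(tab))
})

test_that("coverage dialect applies the CG/+ convention and recomputes percent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t100\t100\t70\t7\t3", f)
  tab <- read_bismark_coverage(f)
  expect_equal(as.data.frame(tab), call_df("s1", 100L, "+", "CG", 7L, 3L),
               ignore_attr = TRUE)

  writeLines("s1\t100\t100\t0\t0\t0", f)
  expect_equal(nrow(read_bismark_coverage(f)), 1L)  # zero-call record kept

  writeLines("s1\t100\t100\t69.5\t7\t3", f)
  expect_warning(tab2 <- read_bismark_coverage(f), "counts")
  expect_equal(100 * tab2$n_meth / (tab2$n_meth + tab2$n_unmeth), 70)
})

test_that("coverage write then read round-trips counts exactly", {
  tab <- paired_cg_table(200)
  plus <- tab[tab$strand == "+", ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bismark_coverage(plus, f)
  back <- read_bismark_coverage(f, manifest = genome_manifest(tab))
  expect_equal(back$n_meth, plus$n_meth)
  expect_equal(back$n_unmeth, plus$n_unmeth)
  expect_equal(back$pos, plus$pos)
})

test_that("GFF3 gene models round-trip with strand-aware first nucleotide", {
  genes <- toy_genes(c("tA", "tB"), "s1", c("+", "-"),
                     c(1000L, 20000L), c(5000L, 24000L),
                     exons = list(data.frame(start = c(1000L, 3000L),
                                             end = c(1999L, 5000L)),
                                  data.frame(start = c(20000L, 23000L),
                                             end = c(20999L, 24000L))))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(genes, f)
  back <- read_gene_annotation(f)
  back <- back[order(back$gene_id), ]
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$exons[[1]], genes$exons[[1]])
  # first nucleotide of the - strand transcript is its end coordinate
  expect_equal(tss_windows(back[back$strand == "-", ])$end, 24000 + 100)
})

test_that("biotype filtering keeps exactly the protein-coding models", {
  set.seed(5)
  bio <- sample(rep(c("protein_coding", "lincRNA"), c(14, 6)))
  genes <- toy_genes(sprintf("t%02d", 1:20), "s1", "+",
                     seq(1000L, by = 2000L, length.out = 20),
                     seq(2500L, by = 2000L, length.out = 20), biotype = bio)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(genes, f)
  expect_equal(nrow(read_gene_annotation(f)), 20L)
  expect_equal(nrow(read_gene_annotation(f, "protein_coding")), 14L)
})

test_that("GTF transcripts are parsed with exons and biotype", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("s1\tsrc\ttranscript\t100\t900\t.\t+\t.",
          "gene_id \"gX\"; transcript_id \"tX\"; gene_biotype \"protein_coding\";",
          sep = "\t"),
    paste("s1\tsrc\texon\t100\t300\t.\t+\t.",
          "gene_id \"gX\"; transcript_id \"tX\";", sep = "\t"),
    paste("s1\tsrc\texon\t500\t900\t.\t+\t.",
          "gene_id \"gX\"; transcript_id \"tX\";", sep = "\t")), f)
  g <- read_gene_annotation(f)
  expect_equal(g$gene_id, "tX")
  expect_equal(g$biotype, "protein_coding")
  expect_equal(g$exons[[1]], data.frame(start = c(100L, 500L),
                                        end = c(300L, 900L)))
})

test_that("repeat classes collapse to the controlled set in both dialects", {
  rep_in <- data.frame(chrom = c(rep("s1", 5), rep("s2", 3)),
                       start = seq(100L, by = 1000L, length.out = 8),
                       end = seq(600L, by = 1000L, length.out = 8),
                       strand = "+",
                       te_class = c(rep("LINE", 5), rep("SINE", 3)),
                       stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_repeat_annotation(rep_in, f)
  back <- read_repeat_annotation(f, "rmsk_table")
  expect_equal(nrow(back), 8L)        # 5 LINE + 3 SINE merged set
  expect_equal(back[names(rep_in)], rep_in)
  expect_equal(back, read_repeat_annotation(f, "rmsk_table"))  # idempotent

  out <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header", "header", "",
    " 463 1.3 0.6 1.7 s1 100 600 (0) + L1-el LINE/L1 1 500 (0) 1",
    " 463 1.3 0.6 1.7 s1 800 900 (0) C MIR SINE/MIR 1 100 (0) 2",
    " 100 1.3 0.6 1.7 s1 950 990 (0) + x Simple_repeat 1 40 (0) 3"), out)
  rm_out <- read_repeat_annotation(out, "repeatmasker_out")
  expect_equal(rm_out$te_class, c("LINE", "SINE", "other"))
  expect_equal(rm_out$strand, c("+", "-", "+"))
})

test_that("scaffold filter is strict, keeps mitochondria and conserves records", {
  calls <- rbind(call_df("big", c(10L, 20L), "+", "CG", 3L, 1L),
                 call_df("edge", 10L, "+", "CG", 5L, 5L),
                 call_df("small", 10L, "+", "CG", 2L, 2L),
                 call_df("chrM", 10L, "+", "CG", 0L, 9L))
  man <- c(big = 277001, edge = 277000, small = 1000, chrM = 16000)
  tab <- site_call_table(calls, manifest = man, mito_ids = "chrM")
  kept <- filter_scaffolds(tab, 277000)
  expect_setequal(unique(kept$chrom), c("big", "chrM"))
  # retained records are unchanged and their calls conserved
  expect_equal(as.data.frame(kept)[kept$chrom == "big", ],
               as.data.frame(tab)[tab$chrom == "big", ],
               ignore_attr = TRUE)
  expect_equal(sum(kept$n_meth + kept$n_unmeth),
               sum((tab$n_meth + tab$n_unmeth)[tab$chrom %in%
                                                 c("big", "chrM")]))
  # all scaffolds above threshold: identity
  tab2 <- site_call_table(calls[calls$chrom == "big", ],
                          manifest = c(big = 277001))
  expect_equal(as.data.frame(filter_scaffolds(tab2, 277000)),
               as.data.frame(tab2))
  # scaffold missing from the manifest is an error naming it
  tab3 <- tab
  attr(tab3, "manifest") <- man[c("big", "edge", "small")]
  expect_error(filter_scaffolds(tab3), "chrM")
})
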