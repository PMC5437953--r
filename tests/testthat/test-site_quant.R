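test_that("symmetric CG records pool onto the + strand anchor", {
  tab <- site_call_table(rbind(
    call_df("s1", 100L, "+", "CG", 3L, 1L),
    call_df("s1", 101L, "-", "CG", 2L, 2L),
    call_df("s1", 201L, "-", "CG", 2L, 2L)),   # unpaired - strand record
    manifest = c(s1 = 1000))
  cpg <- merge_symmetric_cg(tab)
  expect_equal(cpg$pos, c(100L, 200L))
  expect_equal(cpg$n_meth, c(5L, 2L))
  expect_equal(cpg$n_unmeth, c(3L, 2L))
  expect_equal(site_methylation(cpg, 1)$M[1], 62.5)
})

test_that("duplicate same-strand records at one position are an error", {
  calls <- rbind(call_df("s1", c(100L, 100L), "+", "CG", 1L, 1L))
  expect_error(site_call_table(calls, manifest = c(s1 = 500)), "duplicate")
})

test_that("pooling 10,000 paired records halves the rows and conserves calls", {
  tab <- paired_cg_table(5000)
  cpg <- merge_symmetric_cg(tab)
  expect_equal(nrow(cpg), 5000L)
  expect_equal(sum(cpg$n_meth), sum(tab$n_meth))
  expect_equal(sum(cpg$n_meth + cpg$n_unmeth),
               sum(tab$n_meth + tab$n_unmeth))
})

test_that("per-site M honours the five-call inclusion threshold", {
  sites <- data.frame(chrom = "s1", pos = c(10L, 20L),
                      n_meth = c(7L, 2L), n_unmeth = c(3L, 2L))
  m <- site_methylation(sites)
  expect_equal(m$M, c(70, NA_real_))
  expect_equal(m$included, c(TRUE, FALSE))
  expect_error(site_methylation(sites, min_calls = 0), "min_calls")

  # bookkeeping: 100 sites of which 40 fall below the threshold
  set.seed(2)
  depth <- c(rep(2L, 40), rep(8L, 60))[sample.int(100)]
  sites2 <- data.frame(chrom = "s1", pos = seq(1, by = 10, length.out = 100),
                       n_meth = rbinom(100, depth, 0.5))
  sites2$n_unmeth <- depth - sites2$n_meth
  expect_equal(sum(!is.na(site_methylation(sites2)$M)), 60L)
})

test_that("global methylation is call-weighted per context and compartment", {
  tab <- site_call_table(rbind(
    call_df("s1", seq(1, by = 10, length.out = 10), "+", "CG", 70L, 30L),
    call_df("s1", seq(5, by = 10, length.out = 10), "+", "CHH", 1L, 99L),
    call_df("chrM", 7L, "+", "CG", 1L, 49L)),
    manifest = c(s1 = 500, chrM = 16000), mito_ids = "chrM")
  g <- global_methylation(tab)
  expect_equal(g$percent[g$compartment == "nuclear" & g$context == "CG"], 70)
  expect_equal(g$percent[g$compartment == "nuclear" & g$context == "non-CG"],
               1)
  expect_equal(g$percent[g$compartment == "mitochondrial" &
                           g$context == "CG"], 2)
  expect_true(is.na(g$percent[g$compartment == "mitochondrial" &
                                g$context == "non-CG"]))
  # calls partition exactly across the four strata
  expect_equal(sum(g$total_calls), sum(tab$n_meth + tab$n_unmeth))
})

test_that("global percent is invariant to record order and chunking", {
  tab <- paired_cg_table(300)
  g0 <- global_methylation(tab)
  set.seed(9)
  shuffled <- site_call_table(as.data.frame(tab)[sample.int(nrow(tab)), ],
                              manifest = genome_manifest(tab))
  expect_equal(global_methylation(shuffled), g0)
  # split into chunks, recombine sums
  idx <- rep(1:3, length.out = nrow(tab))
  parts <- lapply(1:3, function(k)
    global_methylation(site_call_table(as.data.frame(tab)[idx == k, ],
                                       manifest = genome_manifest(tab))))
  tot_meth <- Reduce(`+`, lapply(parts, `[[`, "total_meth_calls"))
  tot <- Reduce(`+`, lapply(parts, `[[`, "total_calls"))
  expect_equal(100 * tot_meth[1] / tot[1],
               g0$percent[g0$compartment == "nuclear" & g0$context == "CG"])
})

test_that("conversion efficiency is the complement of non-CG methylation", {
  tab <- site_call_table(rbind(
    call_df("s1", 1L, "+", "CG", 5L, 5L),
    call_df("s1", 11L, "+", "CHH", 11L, 989L)),  # non-CG level 1.1%
    manifest = c(s1 = 2000))
  expect_equal(conversion_efficiency(tab), 98.9)

  tab0 <- site_call_table(rbind(
    call_df("s1", 1L, "+", "CG", 5L, 5L),
    call_df("s1", 11L, "+", "CHH", 0L, 100L)), manifest = c(s1 = 2000))
  expect_equal(conversion_efficiency(tab0), 100)

  cg_only <- site_call_table(call_df("s1", 1L, "+", "CG", 5L, 5L),
                             manifest = c(s1 = 2000))
  expect_error(conversion_efficiency(cg_only), "non-CG")
})

test_that("site distribution uses decade bins with a closed top bin", {
  d <- site_category_distribution(c(0, 85, 90))
  expect_equal(d$frac_low, 1 / 3)
  expect_equal(d$frac_high, 2 / 3)
  expect_equal(sum(d$bins$fraction), 1)

  top <- site_category_distribution(rep(100, 5))
  expect_equal(top$bins$fraction[10], 1)

  set.seed(4)
  r <- site_category_distribution(runif(500, 0, 100))
  expect_equal(sum(r$bins$fraction), 1)
  expect_error(site_category_distribution(NA_real_), "no defined")
})

test_that("location test handles degenerate groups and matches a permutation oracle", {
  expect_message(res <- two_sample_location_test(rep(5, 3), rep(5, 4)),
                 "convention")
  expect_equal(res$p_value, 1)
  expect_equal(two_sample_location_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  a <- c(64.1, 66.9, 65.2, 68.0, 66.4)
  b <- c(68.2, 69.5, 67.9, 70.3, 68.6)
  obs <- abs(two_sample_location_test(a, b, var_equal = TRUE)$statistic)
  pool <- c(a, b)
  splits <- utils::combn(10, 5)
  t_of <- function(i) {
    x <- pool[i]; y <- pool[-i]
    sp <- sqrt((4 * stats::var(x) + 4 * stats::var(y)) / 8)
    abs((mean(x) - mean(y)) / (sp * sqrt(2 / 5)))
  }
  perm_p <- mean(apply(splits, 2, t_of) >= obs - 1e-12)
  expect_lt(abs(perm_p -
                  two_sample_location_test(a, b, var_equal = TRUE)$p_value),
            0.1)
})
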