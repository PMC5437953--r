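const_sites <- function(M = 80, n = 3000, spacing = 10L, chrom = "s1") {
  s <- data.frame(chrom = chrom, pos = seq(1L, by = spacing, length.out = n),
                  n_meth = round(M / 10), n_unmeth = 10 - round(M / 10))
  site_methylation(s, min_calls = 5)
}

test_that("a constant methylome gives a flat profile at exactly that level", {
  sites <- const_sites(80)
  feat <- data.frame(chrom = "s1", start = 12001L, end = 16000L,
                     strand = "+")
  tr <- feature_trend(sites, feat, flank = 5000, body_bins = 20,
                      smooth_k = 100)
  expect_true(all(tr$body$mean[tr$body$n > 0] == 80))
  expect_true(all(tr$upstream$mean == 80))
  expect_true(all(tr$downstream$mean == 80))
})

test_that("minus-strand profiles mirror the plus-strand profile", {
  grad <- function(chrom, reverse = FALSE) {
    n <- 500L
    m <- round(seq(0, 10, length.out = n))
    if (reverse) m <- rev(m)
    site_methylation(
      data.frame(chrom = chrom, pos = seq(1L, by = 20L, length.out = n),
                 n_meth = m, n_unmeth = 10L - m), 5)
  }
  sites <- rbind(grad("sA"), grad("sB", reverse = TRUE))
  span <- c(start = 2001L, end = 8000L)
  plus <- feature_trend(sites, data.frame(chrom = "sA", start = span[1],
                                          end = span[2], strand = "+"),
                        flank = 1000, body_bins = 10, smooth_k = 1)
  minus <- feature_trend(sites, data.frame(chrom = "sB", start = span[1],
                                           end = span[2], strand = "-"),
                         flank = 1000, body_bins = 10, smooth_k = 1)
  expect_equal(minus$body$mean, plus$body$mean, tolerance = 1e-9)
  expect_equal(minus$upstream$mean, plus$upstream$mean, tolerance = 1e-9)
})

test_that("flank smoothing keeps series length and k = 1 is the identity", {
  set.seed(8)
  sites <- const_sites(80)
  jitter_m <- rbinom(nrow(sites), 10, 0.5)
  sites$n_meth <- jitter_m
  sites$n_unmeth <- 10L - jitter_m
  sites <- site_methylation(sites[c("chrom", "pos", "n_meth", "n_unmeth")], 5)
  feat <- data.frame(chrom = "s1", start = 10001L, end = 14000L,
                     strand = "+")
  raw <- feature_trend(sites, feat, flank = 3000, body_bins = 10,
                       smooth_k = 1)
  sm <- feature_trend(sites, feat, flank = 3000, body_bins = 10,
                      smooth_k = 100)
  expect_equal(nrow(sm$upstream), nrow(raw$upstream))
  expect_equal(sm$upstream$offset, raw$upstream$offset)
  expect_false(isTRUE(all.equal(sm$upstream$mean, raw$upstream$mean)))
  # the running mean reproduces a direct windowed average at an interior point
  i <- 150                      # interior point: full 100-point window
  lo <- i - 49; hi <- i + 50
  expect_equal(sm$upstream$mean[i], mean(raw$upstream$mean[lo:hi]))
})

test_that("profiles are invariant to feature input order", {
  sites <- const_sites(60)
  feats <- data.frame(chrom = "s1",
                      start = c(2001L, 12001L, 22001L),
                      end = c(6000L, 16000L, 26000L),
                      strand = c("+", "-", "+"))
  a <- feature_trend(sites, feats, flank = 1000, body_bins = 10)
  b <- feature_trend(sites, feats[c(3, 1, 2), ], flank = 1000,
                     body_bins = 10)
  expect_equal(a$body, b$body)
  expect_equal(a$upstream, b$upstream)
})

test_that("TE trends: single class equals merged; TE body exceeds flanks", {
  # 85%-methylated elements in a 70% background
  set.seed(12)
  n <- 4000L
  pos <- seq(1L, by = 10L, length.out = n)
  reps <- data.frame(chrom = "s1",
                     start = seq(5001L, by = 8000L, length.out = 4),
                     end = seq(7000L, by = 8000L, length.out = 4),
                     strand = "+", te_class = "LINE",
                     stringsAsFactors = FALSE)
  in_te <- rowSums(sapply(seq_len(4), function(i)
    pos >= reps$start[i] & pos <= reps$end[i])) > 0
  m <- rbinom(n, 40, ifelse(in_te, 0.85, 0.70))
  sites <- site_methylation(
    data.frame(chrom = "s1", pos = pos, n_meth = m, n_unmeth = 40L - m), 5)
  tt <- te_trend(sites, reps, flank = 2000, body_bins = 20, smooth_k = 50)
  expect_equal(tt$LINE$body, tt$merged$body)
  expect_gt(mean(tt$merged$body$mean, na.rm = TRUE),
            mean(c(tt$merged$upstream$mean, tt$merged$downstream$mean)))
})

test_that("LINE and SINE profiles agree when simulated identically", {
  set.seed(13)
  n <- 3000L
  pos <- seq(1L, by = 10L, length.out = n)
  m <- rbinom(n, 30, 0.75)
  sites <- site_methylation(
    data.frame(chrom = "s1", pos = pos, n_meth = m, n_unmeth = 30L - m), 5)
  reps <- data.frame(chrom = "s1",
                     start = seq(1001L, by = 3000L, length.out = 8),
                     end = seq(2500L, by = 3000L, length.out = 8),
                     strand = "+",
                     te_class = rep(c("LINE", "SINE"), 4),
                     stringsAsFactors = FALSE)
  tt <- te_trend(sites, reps, flank = 500, body_bins = 10, smooth_k = 10)
  expect_lt(abs(mean(tt$LINE$body$mean, na.rm = TRUE) -
                  mean(tt$SINE$body$mean, na.rm = TRUE)), 3)
})

test_that("per-element distributions exclude sparse elements and bin by decade", {
  sites <- data.frame(chrom = "s1", pos = c(100L, 200L, 1100L, 2100L),
                      n_meth = c(17L, 2L, 19L, 2L),
                      n_unmeth = c(3L, 0L, 1L, 2L))
  reps <- data.frame(chrom = "s1",
                     start = c(50L, 1050L, 2050L), end = c(250L, 1250L, 2250L),
                     strand = "+", te_class = "SINE",
                     stringsAsFactors = FALSE)
  d <- te_distribution(sites, reps, min_calls = 5)
  # third element has 4 calls: excluded
  expect_equal(sum(d$elements$included), 2L)
  # remaining elements at 86.4% and 95%: all mass in the top two bins
  expect_equal(sum(d$histogram$fraction[d$histogram$lower >= 80]), 1)
})
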