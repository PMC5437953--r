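## Size-standardised methylation trend profiles over genes/TEs with flanks.

## centred running mean with window truncation at the series ends; k = 1 is
## the identity. For even k the extra neighbour is taken downstream.
running_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  left <- (k - 1) %/% 2
  right <- k - 1 - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Methylation trend across size-standardised features with flanks
#'
#' Each feature (gene or transposable element) is standardised to unit length
#' and divided into `body_bins` equal bins; every included CpG site inside a
#' feature contributes its per-site M to the bin covering its relative
#' position (strand-oriented, so bin 1 is always the 5' end). Sites in the
#' `flank` bp upstream and downstream are keyed by their bp offset from the
#' feature edge, oriented by strand; the per-offset mean series is smoothed
#' with a centred running mean over `smooth_k` neighbouring offset points
#' (window truncated at the series ends, so the series keeps its length and a
#' constant series is unchanged). Sites are weighted equally across features
#' by default; `weight_features` averages within each feature first.
#'
#' @param sites output of [site_methylation()] (per-site M with inclusion
#'   flags); excluded sites are ignored.
#' @param features data.frame with `chrom`, `start`, `end`, `strand`.
#' @param flank flank width in bp.
#' @param body_bins number of bins across the standardised feature.
#' @param smooth_k running-mean width for the flank series, in offset points.
#' @param weight_features average per feature before pooling (default: every
#'   site weighs equally).
#' @return a `trend_profile`: list with `body` (bin, mean, n),
#'   `upstream`/`downstream` (offset, mean, n; means smoothed; offsets count
#'   away from the feature edge), `n_features`, `params`.
#' @export
feature_trend <- function(sites, features, flank = 10000, body_bins = 100,
                          smooth_k = 100, weight_features = FALSE) {
  if (!"M" %in% names(sites))
    stop("sites must carry per-site M (run site_methylation first)")
  use <- sites[!is.na(sites$M), , drop = FALSE]
  n_feat <- nrow(features)
  empty <- data.frame(offset = integer(), mean = numeric(), n = integer())
  if (!n_feat || !nrow(use)) {
    return(structure(list(body = data.frame(bin = seq_len(body_bins),
                                            mean = NA_real_, n = 0L),
                          upstream = empty, downstream = empty,
                          n_features = n_feat,
                          params = list(flank = flank, body_bins = body_bins,
                                        smooth_k = smooth_k)),
                     class = "trend_profile"))
  }
  plus <- features$strand == "+"
  len <- features$end - features$start + 1

  ## body: map each in-feature site to a strand-oriented relative coordinate
  ov <- overlap_pairs(use$chrom, use$pos,
                      features$chrom, features$start, features$end)
  body <- data.frame(bin = seq_len(body_bins), mean = NA_real_, n = 0L)
  if (nrow(ov)) {
    f <- ov$interval
    rel <- ifelse(plus[f],
                  (use$pos[ov$site] - features$start[f]) / len[f],
                  (features$end[f] - use$pos[ov$site]) / len[f])
    bin <- pmin(floor(rel * body_bins) + 1L, body_bins)
    m <- use$M[ov$site]
    if (weight_features) {
      per <- tapply(m, list(f, bin), mean)
      mb <- apply(per, 2, mean, na.rm = TRUE)
      nb <- apply(per, 2, function(z) sum(!is.na(z)))
      idx <- as.integer(colnames(per))
    } else {
      mb <- tapply(m, bin, mean)
      nb <- tapply(m, bin, length)
      idx <- as.integer(names(mb))
    }
    body$mean[idx] <- as.numeric(mb)
    body$n[idx] <- as.integer(nb)
  }

  flank_series <- function(side) {
    if (side == "up") {
      st <- ifelse(plus, features$start - flank, features$end + 1)
      en <- ifelse(plus, features$start - 1, features$end + flank)
    } else {
      st <- ifelse(plus, features$end + 1, features$start - flank)
      en <- ifelse(plus, features$end + flank, features$start - 1)
    }
    st <- pmax(st, 1)
    ok <- en >= st
    if (!any(ok)) return(empty)
    ovf <- overlap_pairs(use$chrom, use$pos,
                         features$chrom[ok], st[ok], en[ok])
    if (!nrow(ovf)) return(empty)
    f <- which(ok)[ovf$interval]
    ## offset counts away from the feature edge (1 = adjacent base)
    off <- if (side == "up") {
      ifelse(plus[f], features$start[f] - use$pos[ovf$site],
             use$pos[ovf$site] - features$end[f])
    } else {
      ifelse(plus[f], use$pos[ovf$site] - features$end[f],
             features$start[f] - use$pos[ovf$site])
    }
    m <- use$M[ovf$site]
    mu <- tapply(m, off, mean)
    nn <- tapply(m, off, length)
    off_sorted <- sort(as.integer(names(mu)))
    key <- as.character(off_sorted)
    data.frame(offset = off_sorted,
               mean = running_mean(as.numeric(mu[key]), smooth_k),
               n = as.integer(nn[key]))
  }

  structure(list(body = body,
                 upstream = flank_series("up"),
                 downstream = flank_series("down"),
                 n_features = n_feat,
                 params = list(flank = flank, body_bins = body_bins,
                               smooth_k = smooth_k)),
            class = "trend_profile")
}

#' @export
print.trend_profile <- function(x, ...) {
  cat(sprintf(paste0("trend_profile: %d feature(s), %d body bins ",
                     "(%d defined), flanks %d bp (up: %d points, ",
                     "down: %d points)\n"),
              x$n_features, nrow(x$body), sum(!is.na(x$body$mean)),
              x$params$flank, nrow(x$upstream), nrow(x$downstream)))
  invisible(x)
}

#' Trend profiles per transposable-element class
#'
#' Applies [feature_trend()] separately to each requested TE class present in
#' the repeat set, and additionally to the merged set of those classes. Empty
#' classes are skipped with a message.
#'
#' @inheritParams feature_trend
#' @param repeats repeat elements ([read_repeat_annotation()]).
#' @param te_classes classes to profile (default: all present).
#' @return named list of `trend_profile`s, one per class plus `"merged"`.
#' @export
te_trend <- function(sites, repeats, te_classes = NULL, flank = 10000,
                     body_bins = 100, smooth_k = 100) {
  if (is.null(te_classes)) te_classes <- sort(unique(repeats$te_class))
  out <- list()
  kept <- character()
  for (cl in te_classes) {
    sub <- repeats[repeats$te_class == cl, , drop = FALSE]
    if (!nrow(sub)) {
      message("TE class ", cl, " empty: skipped")
      next
    }
    out[[cl]] <- feature_trend(sites, sub, flank = flank,
                               body_bins = body_bins, smooth_k = smooth_k)
    kept <- c(kept, cl)
  }
  merged <- repeats[repeats$te_class %in% kept, , drop = FALSE]
  out[["merged"]] <- feature_trend(sites, merged, flank = flank,
                                   body_bins = body_bins, smooth_k = smooth_k)
  out
}

#' Per-element mean methylation distributions by TE class
#'
#' Quantifies each repeat element call-weighted (elements with fewer than
#' `min_calls` calls are excluded) and bins the per-element percentages into
#' `n_bins` equal bins per class.
#'
#' @inheritParams te_trend
#' @param sites pooled CpG sites ([merge_symmetric_cg()]).
#' @param min_calls minimum calls for an element to be included.
#' @param n_bins number of equal bins over [0, 100].
#' @return list with `elements` (per-element quantitation with class) and
#'   `histogram` (class, lower, upper, n, fraction); classes empty after
#'   filtering are flagged in `empty_classes`.
#' @export
te_distribution <- function(sites, repeats, min_calls = 5, n_bins = 10) {
  q <- quantify_windows(sites, repeats, min_calls = min_calls)
  classes <- sort(unique(repeats$te_class))
  width <- 100 / n_bins
  hist_list <- list()
  empty_classes <- character()
  for (cl in classes) {
    v <- q$percent[q$te_class == cl & q$included]
    if (!length(v)) {
      empty_classes <- c(empty_classes, cl)
      next
    }
    idx <- pmin(floor(v / width) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    hist_list[[cl]] <- data.frame(te_class = cl,
                                  lower = width * (seq_len(n_bins) - 1),
                                  upper = width * seq_len(n_bins),
                                  n = counts,
                                  fraction = counts / length(v))
  }
  list(elements = q,
       histogram = if (length(hist_list)) do.call(rbind, hist_list)
                   else data.frame(),
       empty_classes = empty_classes)
}
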