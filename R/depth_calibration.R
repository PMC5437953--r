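## Bootstrap calibration of global-methylation margin of error vs depth.

#' Resample reads until a target number of CG calls is reached
#'
#' Reads are the resampling unit: they are drawn with replacement from the
#' pool until the cumulative CG call count reaches `target_calls`, and the
#' final read is kept whole, so the sample may overshoot the target by at most
#' one read's calls (`mode = "truncate"` instead clips the final read's calls
#' to hit the target exactly, breaking within-read grouping for that read).
#'
#' @param reads data.frame with columns `n_meth`, `n_unmeth` (one row per
#'   read); reads with zero calls are allowed in the pool.
#' @param target_calls target cumulative CG call count (>= 1).
#' @param mode overshoot convention.
#' @return list with `n_meth`, `n_calls`, `n_reads`, `overshoot`.
#' @export
subsample_to_depth <- function(reads, target_calls,
                               mode = c("whole_read", "truncate")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_calls) || target_calls < 1)
    stop("target_calls must be >= 1")
  calls <- reads$n_meth + reads$n_unmeth
  if (!nrow(reads) || !any(calls > 0))
    stop("read pool has no read with a CG call")
  mean_calls <- mean(calls)
  got_meth <- 0
  got_calls <- 0
  n_reads <- 0L
  last <- c(0, 0)
  while (got_calls < target_calls) {
    need <- target_calls - got_calls
    batch <- max(32L, ceiling(1.3 * need / mean_calls))
    idx <- sample.int(nrow(reads), batch, replace = TRUE)
    cum <- cumsum(calls[idx])
    stop_at <- which(got_calls + cum >= target_calls)
    take <- if (length(stop_at)) stop_at[1L] else batch
    sel <- idx[seq_len(take)]
    got_meth <- got_meth + sum(reads$n_meth[sel])
    got_calls <- got_calls + sum(calls[sel])
    n_reads <- n_reads + take
    last <- c(reads$n_meth[sel[take]], calls[sel[take]])
  }
  overshoot <- got_calls - target_calls
  if (mode == "truncate" && overshoot > 0) {
    ## clip the final read: drop `overshoot` of its calls, methylated calls
    ## reduced proportionally (deterministic rounding)
    drop_meth <- round(last[1L] * overshoot / last[2L])
    got_meth <- got_meth - drop_meth
    got_calls <- target_calls
    overshoot <- 0
  }
  list(n_meth = got_meth, n_calls = got_calls, n_reads = n_reads,
       overshoot = overshoot)
}

#' Bootstrap margin of error of global methylation across depths
#'
#' For each target depth (CG call count), global CG methylation is recomputed
#' over `iterations` read-resamples, and the margin of error is the half-width
#' of the central interval between the (100-ci)/2 and (100+ci)/2 percentiles
#' (0.5 and 99.5 for the default 99% interval). An asymptotic curve is fitted
#' to the (depth, half-width) points with [fit_asymptotic()].
#'
#' @inheritParams subsample_to_depth
#' @param depths target call counts; default 15 log-spaced targets from 100
#'   to 30,000.
#' @param iterations bootstrap iterations per depth.
#' @param ci central interval coverage in percent.
#' @param seed integer seed; the run is fully reproducible.
#' @param model_form asymptotic model passed to [fit_asymptotic()].
#' @return a `bootstrap_curve`: list with `curve` (depth, half_width, mean,
#'   lower, upper), `a`, `model_form`, `iterations`, `ci`, `seed`.
#' @export
bootstrap_margin <- function(reads, depths = depth_grid(), iterations = 1000,
                             ci = 99, seed = 1,
                             model_form = c("a_over_sqrt_x", "a_over_x")) {
  model_form <- match.arg(model_form)
  if (iterations < 2) stop("iterations must be >= 2")
  depths <- sort(as.numeric(depths))
  if (any(depths < 1)) stop("depths must be >= 1")
  lo_q <- (100 - ci) / 200
  hi_q <- 1 - lo_q
  set.seed(seed)
  rows <- lapply(depths, function(d) {
    pct <- vapply(seq_len(iterations), function(i) {
      s <- subsample_to_depth(reads, d)
      100 * s$n_meth / s$n_calls
    }, numeric(1))
    qs <- quantile(pct, c(lo_q, hi_q), names = FALSE)
    data.frame(depth = d, half_width = (qs[2L] - qs[1L]) / 2,
               mean = mean(pct), lower = qs[1L], upper = qs[2L])
  })
  curve <- do.call(rbind, rows)
  a <- if (nrow(curve) >= 2) {
    if (all(curve$half_width == 0)) 0
    else fit_asymptotic(curve, model_form)$a
  } else NA_real_
  structure(list(curve = curve, a = a, model_form = model_form,
                 iterations = iterations, ci = ci, seed = seed),
            class = "bootstrap_curve")
}

#' @rdname bootstrap_margin
#' @param from,to,n grid limits and size.
#' @export
depth_grid <- function(from = 100, to = 30000, n = 15) {
  round(exp(seq(log(from), log(to), length.out = n)))
}

#' @export
print.bootstrap_curve <- function(x, ...) {
  cat(sprintf(paste0("bootstrap_curve: %d depths (%g-%g calls), %d ",
                     "iterations, %g%% interval; fitted a = %.4g (%s)\n"),
              nrow(x$curve), min(x$curve$depth), max(x$curve$depth),
              x$iterations, x$ci, x$a, x$model_form))
  invisible(x)
}

#' Fit an asymptotic margin-of-error model
#'
#' Least-squares fit of y = a/x or y = a/sqrt(x) to (depth, half-width)
#' points. Both forms are single-parameter, so the fit has the closed form
#' a = sum(y g) / sum(g^2) with g = 1/x or 1/sqrt(x).
#'
#' @param curve a `bootstrap_curve` or a data.frame with `depth` and
#'   `half_width`.
#' @param model_form which asymptotic form to fit.
#' @return list with `a`, `model_form`, `residuals`, `rss`.
#' @export
fit_asymptotic <- function(curve, model_form = c("a_over_sqrt_x",
                                                 "a_over_x")) {
  model_form <- match.arg(model_form)
  if (inherits(curve, "bootstrap_curve")) curve <- curve$curve
  x <- curve$depth
  y <- curve$half_width
  if (length(x) < 2) stop("need at least 2 (depth, half_width) points")
  g <- if (model_form == "a_over_x") 1 / x else 1 / sqrt(x)
  if (all(y == 0)) {
    warning("all half-widths are zero: a = 0")
    return(list(a = 0, model_form = model_form, residuals = y, rss = 0))
  }
  a <- sum(y * g) / sum(g * g)
  res <- y - a * g
  list(a = a, model_form = model_form, residuals = res, rss = sum(res^2))
}

#' Predict the margin of error at a sequencing depth
#'
#' Evaluates the fitted asymptotic model at a CG call count, giving the
#' expected half-width of the confidence interval of global methylation in
#' percentage points.
#'
#' @param a fitted asymptotic constant (>= 0).
#' @param model_form the form `a` was fitted under.
#' @param depth CG call count (>= 1).
#' @return margin of error in methylation percentage points.
#' @export
predict_margin <- function(a, model_form = c("a_over_sqrt_x", "a_over_x"),
                           depth) {
  model_form <- match.arg(model_form)
  if (a < 0) stop("a must be >= 0")
  if (any(depth < 1)) stop("depth must be >= 1")
  if (model_form == "a_over_x") a / depth else a / sqrt(depth)
}
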