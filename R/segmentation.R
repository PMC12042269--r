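#' Resample a trajectory onto a uniform time grid
#'
#' Interpolation of an irregularly sampled series onto `n_grid` equally
#' spaced points spanning the same interval; the endpoints are preserved
#' exactly.  Trajectory monitoring works on such downsampled windows for
#' speed.  `method = "constant"` treats the input as a right-continuous
#' step function, which is exact for KMC observables (the energy is
#' constant between transition events); `"linear"` is conventional
#' polyline interpolation.
#'
#' @param times strictly increasing sample times (s), length >= 2.
#' @param values sample values (k_BT).
#' @param n_grid grid length (default 1000).
#' @param method `"linear"` (default) or `"constant"` (step function).
#' @return an object of class `uniform_series`: list with `t`, `y`,
#'   `n_grid`.
#' @export
resample_uniform <- function(times, values, n_grid = 1000,
                             method = c("linear", "constant")) {
  method <- match.arg(method)
  if (length(times) < 2) stop("insufficient data: need at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(times)) stop("times/values length mismatch")
  g <- approx(times, values, n = n_grid, method = method, f = 0)
  structure(list(t = g$x, y = g$y, n_grid = n_grid),
            class = "uniform_series")
}

# per-(i,j) OLS linear-fit residual cost via prefix sums; returns closures
.ols_prefix <- function(x, y) {
  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x * x))
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  # segment [i..j] (1-based, inclusive), i may be a vector
  function(i, j) {
    m <- j - i + 1
    Sx <- cx[j + 1] - cx[i]; Sxx <- cxx[j + 1] - cxx[i]
    Sy <- cy[j + 1] - cy[i]; Syy <- cyy[j + 1] - cyy[i]
    Sxy <- cxy[j + 1] - cxy[i]
    vx <- Sxx - Sx * Sx / m
    vy <- Syy - Sy * Sy / m
    cxy_ <- Sxy - Sx * Sy / m
    slope <- ifelse(vx > 0, cxy_ / vx, 0)
    rss <- pmax(vy - slope * cxy_, 0)
    list(m = m, slope = slope, rss = rss,
         intercept = Sy / m - slope * Sx / m)
  }
}

#' Segment a uniform series into piecewise-linear trends
#'
#' Partitions the grid into contiguous segments, each carrying an
#' ordinary-least-squares linear trend, by exact dynamic-programming
#' optimal partitioning: changepoints minimise the summed per-segment
#' Gaussian cost `m * log(RSS/m)` plus a BIC-type penalty per changepoint
#' (default `3 log n`, for slope, intercept and variance), subject to a
#' minimum segment length.  This is the measurement layer of the stochastic
#' landscape method: it assumes a noisy signal whose linear trend is stable
#' within a segment and shifts abruptly at changepoints.  The engine sits
#' behind this interface, so a Bayesian changepoint engine can be
#' substituted without touching callers.
#'
#' @param series a [resample_uniform()] `uniform_series` (or list with
#'   numeric `t`, `y` on a uniform grid).
#' @param min_seg minimum segment length in grid points (default 10).
#' @param penalty per-changepoint penalty; default `3 * log(n)`.
#' @return a data.frame of class `slm_segments`, one row per segment, with
#'   columns `t_start`, `t_end`, `trend` (k_BT/s), `mean`, `std` (k_BT),
#'   `dwell` (s); segments are contiguous (`t_end[k] == t_start[k+1]`) and
#'   their dwell times sum to the window length.  Attribute `"breaks"`
#'   holds the first grid index of each segment.
#' @examples
#' s <- resample_uniform(c(0, 5, 10), c(0, -5, -5), n_grid = 200)
#' segment_series(s, min_seg = 10)
#' @export
segment_series <- function(series, min_seg = 10, penalty = NULL) {
  t <- series$t; y <- series$y
  n <- length(y)
  if (n < 2 * min_seg) stop("series too short: need >= 2 * min_seg points")
  if (is.null(penalty)) penalty <- 3 * log(n)
  x <- t - t[1]  # shifted abscissa for numerical stability; slopes unchanged

  starts <- n + 1L  # sentinel; replaced below
  if (stats::var(y) == 0) {
    starts <- 1L
  } else {
    seg <- .ols_prefix(x, y)
    floor_c <- 1e-10 * stats::var(y)
    # F[j+1]: optimal cost of y[1..j]; F[1] = 0 for the empty prefix
    F <- rep(Inf, n + 1); F[1] <- 0
    from <- integer(n + 1)
    for (j in min_seg:n) {
      i <- seq_len(j - min_seg + 1L)            # candidate segment starts
      i <- i[is.finite(F[i])]
      if (!length(i)) next
      s <- seg(i, j)
      cost <- F[i] + s$m * log(pmax(s$rss, s$m * floor_c) / s$m) + penalty
      best <- which.min(cost)
      F[j + 1] <- cost[best]
      from[j + 1] <- i[best]
    }
    if (!is.finite(F[n + 1])) {
      warning("segmentation failed; falling back to a single segment")
      starts <- 1L
    } else {
      starts <- integer(0); j <- n
      while (j >= 1) { i <- from[j + 1]; starts <- c(i, starts); j <- i - 1 }
    }
  }

  seg2 <- .ols_prefix(x, y)
  ends <- c(starts[-1] - 1L, n)
  k <- length(starts)
  fit <- seg2(starts, ends)
  # snap numerically negligible slopes to exact zero: a trend whose total
  # change over the whole window is far below the signal range is noise
  thr <- 1e-8 * diff(range(y)) / max(x[n] - x[1], .Machine$double.xmin)
  fit$slope[abs(fit$slope) < thr] <- 0
  t_start <- t[starts]
  t_end <- c(t[starts[-1]], t[n])   # contiguous; dwells sum to the window
  out <- data.frame(
    t_start = t_start, t_end = t_end, trend = fit$slope,
    mean = vapply(seq_len(k), function(q) mean(y[starts[q]:ends[q]]), 0),
    std = vapply(seq_len(k), function(q)
      if (ends[q] > starts[q]) sd(y[starts[q]:ends[q]]) else 0, 0),
    dwell = t_end - t_start)
  attr(out, "breaks") <- starts
  class(out) <- c("slm_segments", "data.frame")
  out
}

#' Trend of the most recent segment of a partial trajectory
#'
#' Implements the near-real-time monitoring step: the partial energy
#' trajectory spanning from the last detected changepoint (or the start of
#' the run) up to `t_now` is downsampled onto a uniform grid, segmented,
#' and the final segment's trend `t*` is returned together with any newly
#' confirmed changepoints (all internal segment boundaries) for trajectory
#' bookkeeping.  If the window holds fewer than `min_samples` raw samples
#' (or has zero span) a no-decision sentinel is returned, which callers
#' treat as "not trapped".
#'
#' @param times,values raw trajectory samples (full history is fine; the
#'   window is selected internally).
#' @param last_changepoint_time left edge of the analysis window (s).
#' @param t_now right edge of the analysis window (s), > left edge.
#' @param n_grid,min_seg,penalty segmentation controls, see
#'   [segment_series()].
#' @param min_samples minimum raw samples required for a decision.
#' @param method interpolation method, see [resample_uniform()].
#' @return list with `decided` (logical), `trend` (`t*`, NA when
#'   undecided), `segment` (last segment row or `NULL`), `changepoints`
#'   (absolute times of newly confirmed internal boundaries), and
#'   `segments` (the full window segmentation).
#' @export
latest_trend <- function(times, values, last_changepoint_time, t_now,
                         n_grid = 1000, min_seg = 10, penalty = NULL,
                         min_samples = 10, method = "linear") {
  stopifnot(t_now > last_changepoint_time)
  keep <- times >= last_changepoint_time & times <= t_now
  t <- times[keep]; y <- values[keep]
  dedup <- c(TRUE, diff(t) > 0)
  t <- t[dedup]; y <- y[dedup]
  if (length(t) < max(2, min_samples) || t[length(t)] <= t[1])
    return(list(decided = FALSE, trend = NA_real_, segment = NULL,
                changepoints = numeric(0), segments = NULL))
  segs <- segment_series(resample_uniform(t, y, n_grid, method = method),
                         min_seg = min_seg, penalty = penalty)
  k <- nrow(segs)
  list(decided = TRUE, trend = segs$trend[k], segment = segs[k, ],
       changepoints = if (k > 1) segs$t_start[-1] else numeric(0),
       segments = segs)
}
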