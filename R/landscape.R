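#' Calibrate the monitoring window W2
#'
#' The monitoring (segmentation-activation) window is tied to the assembly
#' time scale of the interaction strength under study:
#' `W2 = 0.01 * median(T_FAS)`, making monitoring near-real-time relative
#' to the time to first assembly.  Unassembled realizations contribute
#' their total simulated time.  For an even-length input the median is the
#' mean of the central pair (R's default).
#'
#' @param equilibrium_tfas_values numeric vector of first-assembly times
#'   (s); unassembled runs enter as `T_tot`.
#' @return the window `W2` in seconds.
#' @examples
#' calibrate_w2(c(50, 100, 150))  # 1.0
#' @export
calibrate_w2 <- function(equilibrium_tfas_values) {
  if (!length(equilibrium_tfas_values)) stop("empty T_FAS collection")
  0.01 * median(equilibrium_tfas_values)
}

#' Learn the kinetic-trap trend region
#'
#' The trap region `T* = [-tau, +tau]` is the symmetric interval around
#' zero trend that captures between 20 and 21% of the training segments:
#' near-zero trends with long dwelling times are the signature of a
#' kinetic trap.  `tau` is found by iterative expansion around zero with a
#' binary search on the inclusion fraction, then snapped to the smallest
#' admissible order statistic of `|trend|`.  When ties (atoms) make the
#' 20–21% band unattainable, the `tau` minimising `|fraction - 0.205|` is
#' returned with `attained = FALSE`.
#'
#' @param segment_ensemble a data.frame of pooled segments (needs a
#'   `trend` column), or a numeric vector of trends.  At least 50 segments
#'   are recommended for a stable region.
#' @param lower,upper inclusion-fraction band (defaults 0.20, 0.21).
#' @return an object of class `trap_region`: list with `tau`,
#'   `achieved_fraction`, `attained`, `n_segments`.
#' @export
find_trap_region <- function(segment_ensemble, lower = 0.20, upper = 0.21) {
  trends <- if (is.data.frame(segment_ensemble)) segment_ensemble$trend
            else as.numeric(segment_ensemble)
  if (!length(trends)) stop("empty segment ensemble")
  if (!all(is.finite(trends))) stop("non-finite trends in ensemble")
  if (length(trends) < 50)
    warning("fewer than 50 segments; trap region may be unstable")
  at <- sort(abs(trends)); n <- length(at)
  frac <- function(tau) mean(at <= tau)

  # iterative expansion + binary search on the half-width
  lo <- 0; hi <- max(at)
  tau <- hi
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (f < lower) lo <- mid
    else if (f > upper) hi <- mid
    else { tau <- mid; break }
    if (hi - lo <= .Machine$double.eps * max(1, hi)) { tau <- hi; break }
  }
  # snap to the smallest admissible tau: the k-th order statistic
  k <- ceiling(lower * n)
  tau_k <- at[max(k, 1L)]
  f_k <- frac(tau_k)
  if (f_k >= lower && f_k <= upper) {
    tau <- tau_k; f <- f_k; attained <- TRUE
  } else {
    f <- frac(tau)
    attained <- f >= lower && f <= upper
    if (!attained) {
      # atoms: the k-th order statistic covers >= 20% but overshoots 21%;
      # keep it (dropping below 20% could exclude the zero-trend atom,
      # i.e. the traps themselves)
      tau <- tau_k; f <- f_k
    }
  }
  structure(list(tau = tau, achieved_fraction = f, attained = attained,
                 n_segments = n),
            class = "trap_region")
}

#' @export
print.trap_region <- function(x, ...) {
  cat(sprintf("trap region T* = [-%.4g, +%.4g] k_BT/s (%.1f%% of %d segments%s)\n",
              x$tau, x$tau, 100 * x$achieved_fraction, x$n_segments,
              if (x$attained) "" else "; 20-21% band unattainable"))
  invisible(x)
}

#' Build the dwelling-time-vs-trend stochastic landscape
#'
#' Bins the pooled segments by trend (21 equal-width bins over the
#' observed range by default), computes the mean dwelling time per bin,
#' and interpolates linearly between bin centres.  The landscape is
#' diagnostic: the controller itself only needs the trap region, but the
#' landscape visualises why near-zero trends are traps (their dwelling
#' times are the longest).
#'
#' @param segment_ensemble data.frame of pooled segments with `trend` and
#'   `dwell` columns.
#' @param n_bins number of trend bins (default 21).
#' @return an object of class `stochastic_landscape`: list with `bins`
#'   (data.frame of centre/mean/count), `query` (function trend ->
#'   expected dwell), and the raw `scatter`.
#' @export
build_landscape <- function(segment_ensemble, n_bins = 21) {
  stopifnot(is.data.frame(segment_ensemble),
            all(c("trend", "dwell") %in% names(segment_ensemble)))
  tr <- segment_ensemble$trend; dw <- segment_ensemble$dwell
  if (!length(tr)) stop("empty segment ensemble")
  rng <- range(tr)
  if (diff(rng) == 0) {  # degenerate: constant map
    q <- function(trend) rep(mean(dw), length(trend))
    bins <- data.frame(center = rng[1], mean_dwell = mean(dw),
                       count = length(dw))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- findInterval(tr, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    mean_dwell <- tapply(dw, factor(idx, levels = seq_len(n_bins)), mean)
    count <- tapply(rep(1, length(dw)), factor(idx, levels = seq_len(n_bins)),
                    sum)
    keep <- !is.na(mean_dwell)
    bins <- data.frame(center = centers[keep],
                       mean_dwell = as.numeric(mean_dwell[keep]),
                       count = as.numeric(count[keep]))
    if (nrow(bins) == 1) {
      q <- function(trend) rep(bins$mean_dwell, length(trend))
    } else {
      q <- function(trend)
        approx(bins$center, bins$mean_dwell, xout = trend, rule = 2)$y
    }
  }
  structure(list(bins = bins, query = q,
                 scatter = segment_ensemble[, c("trend", "dwell")]),
            class = "stochastic_landscape")
}

#' @export
print.stochastic_landscape <- function(x, ...) {
  cat(sprintf("stochastic landscape: %d segments in %d trend bins\n",
              nrow(x$scatter), nrow(x$bins)))
  invisible(x)
}

#' @export
plot.stochastic_landscape <- function(x, trap = NULL, ...) {
  plot(x$scatter$trend, x$scatter$dwell, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("grey30", 0.5),
       xlab = "trend (k_BT/s)", ylab = "dwelling time (s)", ...)
  lines(x$bins$center, x$bins$mean_dwell, col = "red", lwd = 2)
  if (!is.null(trap))
    abline(v = c(-trap$tau, trap$tau), lty = 2, col = "blue")
  invisible(x)
}

#' Replay near-real-time segmentation over a finished trajectory
#'
#' Reproduces the online monitoring protocol on a stored trajectory: every
#' `w2` seconds the partial window from the last confirmed changepoint is
#' segmented with [latest_trend()]; non-final segments become confirmed and
#' are appended to the output.  The tail is flushed at the end of the run.
#' With `mode = "offline"` the whole energy series is segmented once
#' instead (cheaper; nearly identical pooled statistics).
#'
#' @param traj a [run_trajectory()] `kmc_trajectory`.
#' @param w2 monitoring interval (s).
#' @param mode `"online"` (faithful replay) or `"offline"` (single pass).
#' @param n_grid,min_seg,penalty,min_samples segmentation controls.
#' @param method energy-series interpolation, see [resample_uniform()];
#'   default `"constant"` (exact for KMC records).
#' @return data.frame of segments (`t_start`, `t_end`, `trend`, `mean`,
#'   `std`, `dwell`).
#' @export
collect_segments <- function(traj, w2, mode = c("online", "offline"),
                             n_grid = 1000, min_seg = 10, penalty = NULL,
                             min_samples = 10, method = "constant") {
  mode <- match.arg(mode)
  ser <- .records_series(traj$records)
  if (mode == "offline") {
    if (length(ser$t) < max(2, min_samples)) return(.empty_segments())
    return(segment_series(resample_uniform(ser$t, ser$y, n_grid,
                                           method = method),
                          min_seg = min_seg, penalty = penalty))
  }
  t_end <- ser$t[length(ser$t)]
  confirmed <- list()
  last_cp <- ser$t[1]
  epochs <- seq(ser$t[1] + w2, t_end, by = w2)
  for (ep in c(epochs, t_end)) {
    if (ep <= last_cp) next
    tt <- ser$t; ee <- ser$y
    if (tt[length(tt)] < ep) { tt <- c(tt, ep); ee <- c(ee, ee[length(ee)]) }
    lt <- latest_trend(tt, ee, last_cp, ep, n_grid = n_grid,
                       min_seg = min_seg, penalty = penalty,
                       min_samples = min_samples, method = method)
    if (!lt$decided) next
    k <- nrow(lt$segments)
    if (ep >= t_end) {           # final flush: keep everything
      confirmed[[length(confirmed) + 1L]] <- lt$segments
      last_cp <- t_end
      break
    } else if (k > 1) {          # confirm all but the live final segment
      confirmed[[length(confirmed) + 1L]] <- lt$segments[-k, ]
      last_cp <- lt$segments$t_start[k]
    }
  }
  if (!length(confirmed)) return(.empty_segments())
  out <- do.call(rbind, confirmed)
  rownames(out) <- NULL
  out
}

.empty_segments <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), trend = numeric(0),
             mean = numeric(0), std = numeric(0), dwell = numeric(0))
}

#' Learning phase: fit the stochastic landscape and trap region
#'
#' Fits the full learning phase of the closed-loop protocol from an
#' ensemble of equilibrium trajectories at fixed interaction parameters:
#' calibrates the monitoring window `W2` from the ensemble's
#' first-assembly times, collects trend segments from every trajectory
#' ([collect_segments()]), pools them, learns the trap region
#' ([find_trap_region()]) and builds the dwelling-time landscape
#' ([build_landscape()]).  The result is everything the activation phase
#' needs.
#'
#' @param trajectories list of `kmc_trajectory` objects simulated under
#'   equilibrium (no drive) at one `J_s`.
#' @param w2 optional override of the monitoring window (s); default
#'   calibrated from the ensemble.
#' @param mode segment collection mode, see [collect_segments()].
#' @param n_grid,min_seg,penalty,min_samples segmentation controls.
#' @param method energy-series interpolation (default `"constant"`).
#' @param n_bins landscape bins.
#' @return an object of class `slm`: list with `w2`, `trap`
#'   (`trap_region`), `landscape`, `segments` (pooled data.frame with a
#'   `realization` tag), and `meta`.
#' @examples
#' \donttest{
#' tg <- make_targets(9, 2); p <- interaction_params(J_s = -3)
#' trajs <- lapply(1:4, function(s)
#'   run_trajectory(random_initial_state(9, tg, seed = s), p, tg,
#'                  T_cap = 2e4, seed = 100 + s, stride = 20))
#' fit <- slm_learn(trajs, mode = "offline", n_grid = 200)
#' fit
#' }
#' @export
slm_learn <- function(trajectories, w2 = NULL, mode = c("online", "offline"),
                      n_grid = 1000, min_seg = 10, penalty = NULL,
                      min_samples = 10, n_bins = 21, method = "constant") {
  mode <- match.arg(mode)
  stopifnot(length(trajectories) >= 1,
            all(vapply(trajectories, inherits, TRUE, "kmc_trajectory")))
  tfas <- vapply(trajectories, function(tr)
    if (tr$assembled) tr$t_fas else tr$t_tot, numeric(1))
  if (is.null(w2)) w2 <- calibrate_w2(tfas)
  segs <- lapply(seq_along(trajectories), function(i) {
    s <- collect_segments(trajectories[[i]], w2, mode = mode,
                          n_grid = n_grid, min_seg = min_seg,
                          penalty = penalty, min_samples = min_samples,
                          method = method)
    if (nrow(s)) s$realization <- i
    s
  })
  pooled <- do.call(rbind, segs[vapply(segs, nrow, 1L) > 0])
  if (is.null(pooled) || !nrow(pooled))
    stop("no segments collected; trajectories too short for the window")
  rownames(pooled) <- NULL
  trap <- find_trap_region(pooled)
  landscape <- build_landscape(pooled, n_bins = n_bins)
  params <- trajectories[[1]]$meta$params
  structure(list(w2 = w2, trap = trap, landscape = landscape,
                 segments = pooled,
                 meta = list(J_s = params$J_s, J_w = params$J_w,
                             n_traj = length(trajectories),
                             median_tfas = median(tfas), mode = mode,
                             n_grid = n_grid, min_seg = min_seg)),
            class = "slm")
}

#' @export
print.slm <- function(x, ...) {
  cat("stochastic landscape fit (learning phase)\n")
  cat(sprintf("  J_s = %g k_BT, %d trajectories, %d pooled segments\n",
              x$meta$J_s, x$meta$n_traj, nrow(x$segments)))
  cat(sprintf("  W2 = %.4g s (0.01 x median T_FAS = %.4g s)\n",
              x$w2, x$meta$median_tfas))
  cat(sprintf("  T* = [-%.4g, +%.4g] k_BT/s (%.1f%% of segments)\n",
              x$trap$tau, x$trap$tau, 100 * x$trap$achieved_fraction))
  invisible(x)
}

#' @export
summary.slm <- function(object, ...) {
  print(object)
  cat("\nsegment trend quartiles (k_BT/s):\n")
  print(quantile(object$segments$trend))
  cat("\ndwell in trap vs outside (s):\n")
  inside <- abs(object$segments$trend) <= object$trap$tau
  cat(sprintf("  inside T*: mean %.4g   outside: mean %.4g\n",
              mean(object$segments$dwell[inside]),
              mean(object$segments$dwell[!inside])))
  invisible(object)
}

#' @export
plot.slm <- function(x, ...) {
  plot(x$landscape, trap = x$trap, ...)
  invisible(x)
}

#' Persist / restore learned control artifacts as JSON
#'
#' Stores the quantities the activation phase needs (`J_s`, `W2`, `tau`,
#' achieved fraction, ensemble metadata) as plain JSON.
#'
#' @param x an `slm` fit.
#' @param path file path.
#' @name slm-learned-json
#' @export
write_slm_json <- function(x, path) {
  stopifnot(inherits(x, "slm"))
  obj <- list(J_s = x$meta$J_s, J_w = x$meta$J_w, w2 = x$w2,
              tau = x$trap$tau,
              achieved_fraction = x$trap$achieved_fraction,
              attained = x$trap$attained,
              n_traj = x$meta$n_traj, n_segments = nrow(x$segments),
              median_tfas = x$meta$median_tfas)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slm-learned-json
#' @export
read_slm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trap <- structure(list(tau = obj$tau,
                         achieved_fraction = obj$achieved_fraction,
                         attained = obj$attained,
                         n_segments = obj$n_segments),
                    class = "trap_region")
  structure(list(w2 = obj$w2, trap = trap, landscape = NULL,
                 segments = NULL,
                 meta = list(J_s = obj$J_s, J_w = obj$J_w,
                             n_traj = obj$n_traj,
                             median_tfas = obj$median_tfas)),
            class = "slm")
}
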