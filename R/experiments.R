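#' First-assembly statistics of an ensemble
#'
#' Collects the per-realization time to first assembly `T_FAS` (the first
#' time the minimum distance to any stored target hits zero; unassembled
#' realizations enter as their total simulated time `T_tot`), the
#' max-normalized `T_hat = T_FAS / max(T_FAS)` (unassembled runs group at
#' 1), the assembly yield `SA[%] = 100 * #assembled / #realizations`, and
#' the assembled-only mean `T_bar`.
#'
#' @param trajectories list of `kmc_trajectory` objects, or a data.frame
#'   with columns `t_fas`, `assembled`, `t_tot`.
#' @return an object of class `assembly_ensemble`: list with `n`, `sa_pct`,
#'   `median_tfas`, `tbar` (NA when nothing assembled), and a `table`
#'   data.frame (`t_fas`, `assembled`, `t_hat`).
#' @export
first_assembly_stats <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    df <- trajectories
    stopifnot(all(c("t_fas", "assembled", "t_tot") %in% names(df)))
    t_fas <- ifelse(df$assembled, df$t_fas, df$t_tot)
    assembled <- df$assembled
  } else {
    stopifnot(length(trajectories) >= 1)
    t_fas <- vapply(trajectories, function(tr)
      if (tr$assembled) tr$t_fas else tr$t_tot, numeric(1))
    assembled <- vapply(trajectories, function(tr) tr$assembled, logical(1))
  }
  t_hat <- if (max(t_fas) > 0) t_fas / max(t_fas) else rep(0, length(t_fas))
  structure(list(
    n = length(t_fas),
    sa_pct = 100 * mean(assembled),
    median_tfas = median(t_fas),
    tbar = if (any(assembled)) mean(t_fas[assembled]) else NA_real_,
    table = data.frame(t_fas = t_fas, assembled = assembled, t_hat = t_hat)),
    class = "assembly_ensemble")
}

#' @export
print.assembly_ensemble <- function(x, ...) {
  cat(sprintf(paste0("assembly ensemble: n = %d, SA = %.1f%%, ",
                     "median T_FAS = %.4g s, T_bar = %.4g s\n"),
              x$n, x$sa_pct, x$median_tfas, x$tbar))
  invisible(x)
}

# deterministic disjoint per-run seeds derived from one base seed
.derive_seeds <- function(base_seed, n) {
  .with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Equilibrium scan over interaction strengths
#'
#' Runs `reps` seeded equilibrium realizations per `J_s` value and
#' summarises each ensemble with [first_assembly_stats()].  Per-run seeds
#' are derived deterministically (and disjointly) from `seed` and logged
#' in the result manifest.
#'
#' @param js_values numeric vector of strong-interaction energies (k_BT).
#' @param reps realizations per value.
#' @param targets `target_set`; `L` board side; `J_w`, `r_0` interaction
#'   constants.
#' @param L board side length.
#' @param J_w,r_0 weak energy and base rate.
#' @param T_cap step cap per run.
#' @param t_limit optional simulated-time cap per run (s), default `Inf`.
#' @param seed base seed for the seed manifest.
#' @param stride record stride.
#' @param keep_trajectories keep the full trajectory objects (needed for a
#'   subsequent learning phase; memory permitting).
#' @param stop_on_assembly default `FALSE` (full trajectories).
#' @param rate_law `"symmetric"` or `"metropolis"`.
#' @return an object of class `equilibrium_scan`: list with `results` (a
#'   data.frame: `J_s`, `rep`, `seed`, `t_fas`, `assembled`, `t_tot`),
#'   `stats` (per-`J_s` list of `assembly_ensemble`), and optionally
#'   `trajectories`.
#' @export
equilibrium_scan <- function(js_values, reps, targets, L, J_w = -1,
                             r_0 = 2.5e6, T_cap, t_limit = Inf, seed = 1,
                             stride = 1L,
                             keep_trajectories = FALSE,
                             stop_on_assembly = FALSE,
                             rate_law = c("symmetric", "metropolis")) {
  rate_law <- match.arg(rate_law)
  stopifnot(length(js_values) >= 1)
  seeds <- matrix(.derive_seeds(seed, 2L * reps * length(js_values)),
                  ncol = 2)  # columns: init seed, run seed
  rows <- list(); stats <- list(); trajs <- list()
  k <- 0L
  for (js in js_values) {
    p <- interaction_params(J_s = js, J_w = J_w, r_0 = r_0)
    ens <- vector("list", reps)
    for (r in seq_len(reps)) {
      k <- k + 1L
      st <- random_initial_state(L, targets, seed = seeds[k, 1])
      tr <- run_trajectory(st, p, targets, T_cap, t_limit = t_limit,
                           seed = seeds[k, 2], stride = stride,
                           stop_on_assembly = stop_on_assembly,
                           rate_law = rate_law)
      ens[[r]] <- tr
      rows[[k]] <- data.frame(J_s = js, rep = r, seed = seeds[k, 2],
                              t_fas = if (tr$assembled) tr$t_fas else tr$t_tot,
                              assembled = tr$assembled, t_tot = tr$t_tot)
    }
    stats[[as.character(js)]] <- first_assembly_stats(ens)
    if (keep_trajectories) trajs[[as.character(js)]] <- ens
  }
  structure(list(results = do.call(rbind, rows), stats = stats,
                 trajectories = if (keep_trajectories) trajs else NULL,
                 meta = list(js_values = js_values, reps = reps, L = L,
                             T_cap = T_cap, base_seed = seed)),
            class = "equilibrium_scan")
}

#' @export
print.equilibrium_scan <- function(x, ...) {
  cat("equilibrium scan:\n")
  for (js in names(x$stats)) {
    s <- x$stats[[js]]
    cat(sprintf("  J_s = %s: SA = %.1f%%, median T_FAS = %.4g s\n",
                js, s$sa_pct, s$median_tfas))
  }
  invisible(x)
}

#' Classify the self-assembly region of an interaction strength
#'
#' The equilibrium `T_FAS(J_s)` curve splits into three physical regions:
#' `I` — unstable nucleation seeds (weak binding, `J_s > -2.25`), `II` —
#' efficient equilibrium self-assembly (`-3.15 <= J_s <= -2.25`), and
#' `III` — kinetic stagnation, where traps are abundant (strong binding,
#' `J_s < -3.15`).
#'
#' @param J_s strong interaction energy (k_BT); vectorised.
#' @return character vector of region labels `"I"`, `"II"`, `"III"`.
#' @examples
#' classify_region(c(-3.5, -2.5, -2.2))  # "III" "II" "I"
#' @export
classify_region <- function(J_s) {
  ifelse(J_s < -3.15, "III", ifelse(J_s <= -2.25, "II", "I"))
}

#' Controlled-drive scan over amplitudes
#'
#' For one `J_s`, runs `reps` closed-loop controlled realizations per
#' drive amplitude and summarises yield and first-assembly time per
#' amplitude.  The amplitude grid always includes the `rho = 1`
#' equilibrium reference, against which the rescaled mean first-assembly
#' time `T_tilde(rho) = T_bar(rho) / T_bar(1)` is computed (`NA`, with a
#' flag, when nothing assembles at `rho = 1`).
#'
#' @param learned an `slm` fit for this `J_s` (supplies `W2` and the trap
#'   region).
#' @param rho_values drive amplitudes; 1 is added if missing.
#' @param reps realizations per amplitude.
#' @param targets,L,J_s,J_w,r_0,T_cap system configuration.
#' @param t_limit optional simulated-time cap per run (s), default `Inf`.
#' @param seed base seed.
#' @param stride record stride.
#' @param w1,relaxation_gap,n_grid,min_seg,penalty,min_samples,mask_shocks
#'   forwarded to [control_config()].
#' @param rate_law `"symmetric"` or `"metropolis"`.
#' @return an object of class `control_scan`: list with `summary`
#'   (data.frame: `rho`, `sa_pct`, `tbar`, `t_tilde`, `n_shocks`),
#'   `results` (per-run rows), `stats` (per-rho `assembly_ensemble`).
#' @export
control_scan <- function(learned, rho_values, reps, targets, L, J_s,
                         J_w = -1, r_0 = 2.5e6, T_cap, t_limit = Inf,
                         seed = 1, stride = 1L, w1 = NULL,
                         relaxation_gap = NULL,
                         n_grid = 1000, min_seg = 10, penalty = NULL,
                         min_samples = 10, mask_shocks = FALSE,
                         rate_law = c("symmetric", "metropolis")) {
  rate_law <- match.arg(rate_law)
  stopifnot(inherits(learned, "slm"))
  rho_values <- sort(unique(c(1, rho_values)))
  p <- interaction_params(J_s = J_s, J_w = J_w, r_0 = r_0)
  seeds <- matrix(.derive_seeds(seed, 2L * reps), ncol = 2)  # shared across rho
  rows <- list(); stats <- list(); nshocks <- numeric(length(rho_values))
  for (i in seq_along(rho_values)) {
    rho <- rho_values[i]
    cfg <- control_config(rho = rho, trap = learned, w1 = w1,
                          relaxation_gap = relaxation_gap, n_grid = n_grid,
                          min_seg = min_seg, penalty = penalty,
                          min_samples = min_samples,
                          mask_shocks = mask_shocks)
    ens <- vector("list", reps)
    for (r in seq_len(reps)) {
      st <- random_initial_state(L, targets, seed = seeds[r, 1])
      tr <- run_controlled(st, p, targets, cfg, T_cap, t_limit = t_limit,
                           seed = seeds[r, 2], stride = stride,
                           rate_law = rate_law)
      ens[[r]] <- tr
      rows[[length(rows) + 1L]] <-
        data.frame(rho = rho, rep = r, seed = seeds[r, 2],
                   t_fas = if (tr$assembled) tr$t_fas else tr$t_tot,
                   assembled = tr$assembled, t_tot = tr$t_tot,
                   n_shocks = nrow(tr$shocks))
    }
    stats[[as.character(rho)]] <- first_assembly_stats(ens)
    nshocks[i] <- mean(vapply(ens, function(tr) nrow(tr$shocks), numeric(1)))
  }
  sa <- vapply(stats, function(s) s$sa_pct, numeric(1))
  tbar <- vapply(stats, function(s) s$tbar, numeric(1))
  tbar1 <- tbar[as.character(1)]
  t_tilde <- if (is.na(tbar1)) rep(NA_real_, length(tbar)) else tbar / tbar1
  structure(list(
    summary = data.frame(rho = rho_values, sa_pct = sa, tbar = tbar,
                         t_tilde = t_tilde, n_shocks = nshocks),
    results = do.call(rbind, rows), stats = stats,
    t_tilde_defined = !is.na(tbar1),
    meta = list(J_s = J_s, reps = reps, T_cap = T_cap, base_seed = seed)),
    class = "control_scan")
}

#' @export
print.control_scan <- function(x, ...) {
  cat(sprintf("controlled scan at J_s = %g (%d reps per rho):\n",
              x$meta$J_s, x$meta$reps))
  print(x$summary, row.names = FALSE)
  if (!x$t_tilde_defined)
    cat("  (T_tilde undefined: no assemblies at rho = 1)\n")
  invisible(x)
}

#' Before/during/after shock distance analysis
#'
#' Quantifies what a shock does to the system's distance from the targets.
#' For each drive activation the time-weighted mean minimum distance is
#' computed over three spans: the segment immediately preceding the
#' activation (clipped at the shock onset), the activation interval
#' itself, and the segment preceding the subsequent activation or final
#' assembly.  For assembled runs only pre-first-assembly activations are
#' analysed; unassembled runs contribute all activations.  Activations
#' with no succeeding span get `d_after = NA`.
#'
#' @param trajectories a `controlled_trajectory` or list of them.
#' @param segmentations optional pre-computed segment tables (one per
#'   trajectory); by default each trajectory's energy record is segmented
#'   offline with [segment_series()].
#' @param n_grid,min_seg,penalty segmentation controls for the default
#'   segmentation.
#' @return data.frame of class `shock_distance_records` with one row per
#'   activation: `realization`, `t_on`, `t_off`, `d_before`, `d_during`,
#'   `d_after`.  Use [bin_shock_distances()] for the binned boxplot
#'   statistics.
#' @export
distance_shock_analysis <- function(trajectories, segmentations = NULL,
                                    n_grid = 1000, min_seg = 10,
                                    penalty = NULL) {
  if (inherits(trajectories, "kmc_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(all(vapply(trajectories, inherits, TRUE,
                       "controlled_trajectory")))
  out <- list()
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (!nrow(tr$shocks)) next
    r <- tr$records
    dcols <- grep("^d[0-9]+$", names(r), value = TRUE)
    dmin <- do.call(pmin, r[dcols])
    tt <- r$t
    segs <- if (!is.null(segmentations)) segmentations[[i]] else {
      ser <- .records_series(r)
      if (length(ser$t) < 2) next
      segment_series(resample_uniform(ser$t, ser$y, n_grid),
                     min_seg = min_seg, penalty = penalty)
    }
    t_limit <- if (tr$assembled) tr$t_fas else tr$t_tot
    sh <- tr$shocks[tr$shocks$t_on < t_limit, , drop = FALSE]
    if (!nrow(sh)) next
    for (j in seq_len(nrow(sh))) {
      t_on <- sh$t_on[j]; t_off <- min(sh$t_off[j], t_limit)
      # segment in progress at activation, clipped at the shock onset
      kb <- which(segs$t_start < t_on & segs$t_end >= t_on)
      d_before <- if (length(kb))
        .timed_mean(tt, dmin, max(segs$t_start[kb[1]], 0), t_on)
      else NA_real_
      d_during <- .timed_mean(tt, dmin, t_on, t_off)
      t_next <- if (j < nrow(sh)) sh$t_on[j + 1] else t_limit
      ka <- which(segs$t_start < t_next & segs$t_end >= t_next)
      if (!length(ka) && t_next >= max(segs$t_end))
        ka <- nrow(segs)  # tail segment before assembly/end of run
      d_after <- if (length(ka) && t_next > t_off) {
        a0 <- max(segs$t_start[ka[1]], t_off)
        if (t_next > a0) .timed_mean(tt, dmin, a0, t_next) else NA_real_
      } else NA_real_
      out[[length(out) + 1L]] <-
        data.frame(realization = i, t_on = t_on, t_off = t_off,
                   d_before = d_before, d_during = d_during,
                   d_after = d_after)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(realization = integer(0), t_on = numeric(0),
               t_off = numeric(0), d_before = numeric(0),
               d_during = numeric(0), d_after = numeric(0))
  class(res) <- c("shock_distance_records", "data.frame")
  res
}

# time-weighted mean of a piecewise-constant record over [a, b)
.timed_mean <- function(t, v, a, b) {
  if (!(b > a)) return(NA_real_)
  brk <- c(a, t[t > a & t < b], b)
  idx <- findInterval(brk[-length(brk)], t)
  idx[idx < 1] <- 1
  w <- diff(brk)
  sum(v[idx] * w) / sum(w)
}

#' Bin shock-distance records for boxplot statistics
#'
#' Groups activation records by `d_before` into five bins of width 20
#' centred at 10, 30, 50, 70, 90 and computes, per bin and for both
#' `d_during` and `d_after`, the quartiles, 1.5 IQR whiskers and outliers
#' (values beyond the whiskers).
#'
#' @param records a [distance_shock_analysis()] result.
#' @param centers bin centres (default `c(10, 30, 50, 70, 90)`).
#' @param half_width bin half-width (default 10).
#' @return list with `bins` (data.frame: per bin and variable, `n`,
#'   quartiles, whiskers) and `outliers` (list of outlying values).
#' @export
bin_shock_distances <- function(records, centers = c(10, 30, 50, 70, 90),
                                half_width = 10) {
  stopifnot(is.data.frame(records))
  rows <- list(); outliers <- list()
  for (v in c("d_during", "d_after")) {
    for (ct in centers) {
      sel <- !is.na(records$d_before) & !is.na(records[[v]]) &
        abs(records$d_before - ct) <= half_width
      vals <- records[[v]][sel]
      if (!length(vals)) next
      bs <- boxplot.stats(vals, coef = 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, center = ct, n = length(vals),
        lower_whisker = bs$stats[1], q1 = bs$stats[2], median = bs$stats[3],
        q3 = bs$stats[4], upper_whisker = bs$stats[5],
        n_outliers = length(bs$out))
      outliers[[paste(v, ct, sep = "_")]] <- bs$out
    }
  }
  list(bins = if (length(rows)) do.call(rbind, rows) else data.frame(),
       outliers = outliers)
}

#' Registered miniature benchmark systems
#'
#' Deterministic small systems used throughout the test-suite and the
#' method's own validation:
#' \describe{
#'   \item{`"toy2"`}{2 particles on a 3x3 board, one stored domino target,
#'     default energies — small enough to enumerate all 72 configurations
#'     and compare long-run occupancy against the exact Boltzmann
#'     distribution.}
#'   \item{`"trap4"`}{4 particles on a 4x4 board, one stored 2x2 block
#'     target with deep binding (`J_s = -12`) — engineered to linger in
#'     misassembled straight chains (three correct bonds that cannot fold
#'     into the square without breaking one), i.e. long-lived kinetic
#'     traps.  Because rejection-free KMC spends *time*, not steps, inside
#'     a fully bonded trap, the fixture carries a calibrated simulated-time
#'     budget `t_limit` (1e-4 s) under which well below half of
#'     equilibrium runs assemble.}
#' }
#'
#' @param spec scenario name: `"toy2"` or `"trap4"`.
#' @param seed seed for the random initial configuration.
#' @return list with `state`, `targets`, `params`, `L`, a suggested
#'   `T_cap`, and (for `"trap4"`) the calibrated `t_limit`.
#' @export
fixture_small_system <- function(spec = c("toy2", "trap4"), seed = 1) {
  spec <- match.arg(spec)
  if (spec == "toy2") {
    targets <- make_targets(2, 1, shape_spec = cbind(c(0L, 0L), c(0L, 1L)))
    params <- interaction_params()  # J_s = -2.5, J_w = -1
    L <- 3L; T_cap <- 1e6; t_limit <- Inf
  } else {
    targets <- make_targets(4, 1)
    params <- interaction_params(J_s = -12, J_w = -1)
    L <- 4L; T_cap <- 1e5; t_limit <- 1e-4
  }
  list(state = random_initial_state(L, targets, seed = seed),
       targets = targets, params = params, L = L, T_cap = T_cap,
       t_limit = t_limit)
}
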