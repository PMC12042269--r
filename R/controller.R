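#' Closed-loop drive configuration
#'
#' Bundles the drive amplitude and the protocol time scales.  Defaults:
#' the shock duration is `W1 = 0.5 * W2` (inside the protocol's stated
#' bound `W1 < 0.01 * median(T_FAS)`, since `W2` equals that bound) and
#' the post-shock relaxation gap equals `W2`, giving the system time to
#' settle into a new metastable state before the next shock.
#'
#' @param rho drive amplitude (>= 1; 1 = no drive).
#' @param w2 monitoring interval (s); epochs are integer multiples of it.
#' @param trap a `trap_region`, or an `slm` fit (supplies `w2` and the
#'   trap region in one go).
#' @param w1 shock duration (s); default `w2 / 2`; must satisfy
#'   `0 < w1 <= w2`.
#' @param relaxation_gap post-shock monitoring suspension (s); default
#'   `w2`.
#' @param n_grid,min_seg,penalty,min_samples segmentation controls for the
#'   online monitoring (see [latest_trend()]).
#' @param interp interpolation of the monitored energy series:
#'   `"constant"` (default; exact for the piecewise-constant KMC energy,
#'   and lets the monitor extend the window to the evaluation epoch even
#'   when no transition happened recently — essential inside deep traps)
#'   or `"linear"`.
#' @param mask_shocks drop in-shock samples from analysis windows
#'   (default `FALSE`: shock samples stay in the window).
#' @return an object of class `control_config`.
#' @export
control_config <- function(rho, w2 = NULL, trap = NULL, w1 = NULL,
                           relaxation_gap = NULL, n_grid = 1000,
                           min_seg = 10, penalty = NULL, min_samples = 10,
                           mask_shocks = FALSE,
                           interp = c("constant", "linear")) {
  interp <- match.arg(interp)
  if (inherits(trap, "slm")) {
    if (is.null(w2)) w2 <- trap$w2
    trap <- trap$trap
  }
  if (is.null(w2)) stop("w2 is required (give it directly or via an slm fit)")
  if (is.null(w1)) w1 <- w2 / 2
  if (is.null(relaxation_gap)) relaxation_gap <- w2
  stopifnot(is.numeric(rho), length(rho) == 1)
  if (rho < 1) stop("drive amplitude rho must be >= 1")
  if (!(w1 > 0 && w1 <= w2)) stop("need 0 < w1 <= w2")
  if (relaxation_gap < 0) stop("relaxation_gap must be >= 0")
  if (!is.null(trap) && !inherits(trap, "trap_region"))
    stop("trap must be a trap_region (or an slm fit)")
  structure(list(rho = rho, w1 = w1, w2 = w2,
                 relaxation_gap = relaxation_gap, trap = trap,
                 n_grid = n_grid, min_seg = min_seg, penalty = penalty,
                 min_samples = min_samples, mask_shocks = mask_shocks,
                 interp = interp),
            class = "control_config")
}

#' @export
print.control_config <- function(x, ...) {
  cat(sprintf("control config: rho = %g, W1 = %.4g s, W2 = %.4g s, gap = %.4g s\n",
              x$rho, x$w1, x$w2, x$relaxation_gap))
  if (!is.null(x$trap)) print(x$trap)
  invisible(x)
}

#' Shock scheduling decision at one evaluation point
#'
#' Pure decision rule of the activation phase: a shock starts iff the
#' latest trend `t*` falls inside the trap region, no shock is currently
#' active, and the relaxation gap of the previous shock has passed; an
#' active shock ends exactly `W1` after it started; otherwise nothing
#' happens.  Undecided trends (`NA`) are treated as "not trapped".
#'
#' @param t_now current evaluation time (an epoch, or a scheduled shock
#'   end).
#' @param latest_t_star trend of the most recent segment (k_BT/s), or NA.
#' @param config a [control_config()] with a trap region.
#' @param schedule_state list with `shock_active` (logical), `shock_end`
#'   (s), `gap_until` (s).
#' @return one of `"none"`, `"start_shock"`, `"end_shock"`.
#' @export
control_step <- function(t_now, latest_t_star, config, schedule_state) {
  if (isTRUE(schedule_state$shock_active)) {
    if (t_now >= schedule_state$shock_end) return("end_shock")
    return("none")
  }
  if (is.na(latest_t_star)) return("none")
  if (t_now < schedule_state$gap_until) return("none")
  if (abs(latest_t_star) <= config$trap$tau) return("start_shock")
  "none"
}

#' Run one closed-loop controlled trajectory
#'
#' Interleaves KMC stepping with trend monitoring: every `W2` seconds of
#' simulated time the partial energy trajectory (from the last confirmed
#' changepoint) is segmented and the latest trend `t*` evaluated; if `t*`
#' falls inside the learned trap region (and no shock or relaxation gap is
#' pending), all interaction energies are divided by `rho` for `W1`
#' seconds, after which the equilibrium energies are restored.  Recorded
#' energies during a shock are computed with the shocked parameters.  The
#' run stops at the first complete assembly or at `T_cap` steps.
#'
#' With `rho = 1` the controlled run is trajectory-identical to an
#' equilibrium [run_trajectory()] under the same seed (the monitoring
#' consumes no random numbers).
#'
#' @param initial_state [lattice_state()].
#' @param params equilibrium [interaction_params()].
#' @param targets `target_set`.
#' @param config [control_config()] carrying `rho`, `W1`, `W2` and the
#'   learned trap region.
#' @param T_cap maximum KMC steps.
#' @param t_limit optional cap on simulated time (s), default `Inf`.
#' @param seed optional integer seed, local to this run.
#' @param stride record every `stride`-th step.
#' @param stop_on_assembly stop at first assembly (default `TRUE` for
#'   controlled yield scans).
#' @param rate_law `"symmetric"` or `"metropolis"`.
#' @return an object of class `controlled_trajectory` (also
#'   `kmc_trajectory`), with an extra `shocks` data.frame (`t_on`,
#'   `t_off`, `trigger_trend`) and a 0/1 `shock` column in `records`.
#' @export
run_controlled <- function(initial_state, params, targets, config, T_cap,
                           t_limit = Inf, seed = NULL, stride = 1L,
                           stop_on_assembly = TRUE,
                           rate_law = c("symmetric", "metropolis")) {
  rate_law <- match.arg(rate_law)
  stopifnot(inherits(config, "control_config"))
  if (is.null(config$trap))
    stop("no learned trap region in config: run the learning phase ",
         "(slm_learn) first")
  run <- function() .run_controlled_impl(initial_state, params, targets,
                                         config, T_cap, t_limit, stride,
                                         stop_on_assembly, rate_law)
  if (is.null(seed)) run() else .with_seed(seed, run())
}

.run_controlled_impl <- function(initial_state, params, targets, config,
                                 T_cap, t_limit, stride, stop_on_assembly,
                                 rate_law) {
  shocked <- shock_params(params, config$rho)
  w1 <- config$w1; w2 <- config$w2; gap <- config$relaxation_gap

  state <- initial_state
  t <- 0; steps <- 0
  rec_list <- list(); shock_flags <- list()
  shocks <- data.frame(t_on = numeric(0), t_off = numeric(0),
                       trigger_trend = numeric(0))
  sched <- list(shock_active = FALSE, shock_end = NA_real_, gap_until = 0)
  last_cp <- 0
  assembled <- FALSE; t_fas <- NA_real_
  first_chunk <- TRUE
  pending <- list(move = -1L, residual = 0)

  while (steps < T_cap && t < t_limit && !(assembled && stop_on_assembly)) {
    t_stop <- if (sched$shock_active) sched$shock_end
              else w2 * (floor(t / w2 + 1e-9) + 1)
    t_stop <- min(t_stop, t_limit)
    p_now <- if (sched$shock_active) shocked else params
    out <- .engine_chunk(state, p_now, targets, max_steps = T_cap - steps,
                         t_stop = t_stop, t_init = t, step_offset = steps,
                         stride = stride, stop_on_assembly = stop_on_assembly,
                         record_initial = first_chunk, rate_law = rate_law,
                         pending_move = pending$move,
                         pending_residual = pending$residual)
    first_chunk <- FALSE
    pending <- list(move = out$pending_move, residual = out$pending_residual)
    state <- out$state
    nrec <- nrow(out$records)
    if (nrec) {
      rec_list[[length(rec_list) + 1L]] <- out$records
      shock_flags[[length(shock_flags) + 1L]] <-
        rep(as.integer(sched$shock_active), nrec)
    }
    t <- out$t; steps <- steps + out$steps
    if (out$assembled && !assembled) { assembled <- TRUE; t_fas <- out$t_fas }
    if (out$reason == 3 || (out$reason == 1 && steps >= T_cap)) break
    if (t >= t_limit) break

    if (sched$shock_active && t >= sched$shock_end) {
      # end of shock: restore equilibrium energies, start relaxation gap
      sched$shock_active <- FALSE
      sched$gap_until <- sched$shock_end + gap
      sched$shock_end <- NA_real_
      # an interrupted dwell is invalid across a parameter switch: the
      # rates change, so the residual is redrawn (memoryless, exact);
      # with rho = 1 nothing changes and the dwell is kept bit-exactly
      if (config$rho > 1) pending <- list(move = -1L, residual = 0)
      next
    }

    # epoch evaluation
    recs <- do.call(rbind, rec_list)
    tt <- recs[, "t"]; ee <- recs[, "E"]
    if (config$mask_shocks && nrow(shocks)) {
      inshock <- rep(FALSE, length(tt))
      for (r in seq_len(nrow(shocks)))
        inshock <- inshock | (tt >= shocks$t_on[r] & tt < shocks$t_off[r])
      tt <- tt[!inshock]; ee <- ee[!inshock]
    }
    t_star <- NA_real_
    if (t > last_cp) {
      if (tail(tt, 1) < t) {  # energy is known up to t: append virtual sample
        tt <- c(tt, t); ee <- c(ee, tail(ee, 1))
      }
      lt <- latest_trend(tt, ee, last_cp, t, n_grid = config$n_grid,
                         min_seg = config$min_seg, penalty = config$penalty,
                         min_samples = config$min_samples,
                         method = config$interp)
      if (lt$decided) {
        t_star <- lt$trend
        if (length(lt$changepoints))
          last_cp <- lt$segment$t_start
      }
    }
    act <- control_step(t, t_star, config, sched)
    if (identical(act, "start_shock")) {
      sched$shock_active <- TRUE
      sched$shock_end <- t + w1
      if (config$rho > 1) pending <- list(move = -1L, residual = 0)
      shocks <- rbind(shocks, data.frame(t_on = t, t_off = t + w1,
                                         trigger_trend = t_star))
    }
  }

  if (nrow(shocks)) shocks$t_off <- pmin(shocks$t_off, t)  # T_cap truncation
  recs <- as.data.frame(do.call(rbind, rec_list))
  recs$shock <- unlist(shock_flags)
  structure(list(records = recs, final_state = state, t_tot = t,
                 steps = steps, assembled = assembled, t_fas = t_fas,
                 shocks = shocks,
                 meta = list(params = params, targets_m = targets$m,
                             n = targets$n, L = initial_state$L,
                             T_cap = T_cap, t_limit = t_limit,
                             stride = stride,
                             rate_law = rate_law, rho = config$rho,
                             w1 = w1, w2 = w2, gap = gap,
                             tau = config$trap$tau,
                             stop_on_assembly = stop_on_assembly)),
            class = c("controlled_trajectory", "kmc_trajectory"))
}

#' @export
print.controlled_trajectory <- function(x, ...) {
  cat(sprintf(paste0("controlled KMC trajectory (rho = %g): %d steps, ",
                     "T_tot = %.4g s, %d shock(s), %s\n"),
              x$meta$rho, as.integer(x$steps), x$t_tot, nrow(x$shocks),
              if (x$assembled) sprintf("assembled at t = %.4g s", x$t_fas)
              else "not assembled"))
  invisible(x)
}
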