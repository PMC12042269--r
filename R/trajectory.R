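# thin wrappers around the compiled n-fold-way engine

.targets_flat <- function(targets) {
  as.integer(unlist(targets$adjacency))
}

.rate_law_code <- function(rate_law) {
  match(match.arg(rate_law, c("symmetric", "metropolis")),
        c("symmetric", "metropolis")) - 1L
}

# one engine chunk; returns raw engine output plus the updated lattice_state
.engine_chunk <- function(state, params, targets, max_steps, t_stop = Inf,
                          t_init = 0, step_offset = 0, stride = 1L,
                          stop_on_assembly = FALSE, record_initial = TRUE,
                          record_state_code = FALSE,
                          rate_law = "symmetric",
                          pending_move = -1L, pending_residual = 0) {
  out <- .kmc_run_cpp(state$positions[, 1], state$positions[, 2],
                      state$states, state$L, .targets_flat(targets),
                      targets$m, params$J_s, params$J_w, params$r_0,
                      .rate_law_code(rate_law), t_init, step_offset,
                      t_stop, max_steps, as.integer(stride),
                      stop_on_assembly, record_initial, record_state_code,
                      as.integer(pending_move), pending_residual)
  out$state <- lattice_state(cbind(out$row, out$col), out$state, state$L,
                             targets$m)
  out
}

#' Run one KMC trajectory
#'
#' Simulates up to `T_cap` n-fold-way steps from an initial configuration,
#' recording time-stamped total energy and per-target distances (every
#' `stride`-th step; the initial and final states are always recorded).
#' Simulated time advances by exponential waiting times `-log(u')/Q`, so
#' `T_cap` caps KMC *steps*, not seconds.  The run is bit-reproducible
#' given `seed` (or the ambient RNG state when `seed` is `NULL`); the
#' engine re-validates its incremental energy and distance bookkeeping
#' against full recomputation every 1e5 steps and aborts on drift.
#'
#' @param initial_state [lattice_state()] (e.g. [random_initial_state()]).
#' @param params [interaction_params()].
#' @param targets [make_targets()] `target_set`.
#' @param T_cap maximum number of KMC steps (>= 1).
#' @param t_limit optional cap on simulated time (s); the run stops once
#'   the cumulative time passes it (default `Inf`: step-capped only).
#'   Useful for trap fixtures, where rejection-free KMC spends time, not
#'   steps, inside a trap.
#' @param seed optional integer seed, local to this run.
#' @param stride record every `stride`-th step.
#' @param stop_on_assembly stop at the first time `min_m d_m = 0`
#'   (default `FALSE`: equilibrium scans record full trajectories).
#' @param rate_law `"symmetric"` (default) or `"metropolis"`.
#' @param record_state_code also record an integer encoding of the particle
#'   positions (tiny systems only; used by enumeration oracles).
#' @return an object of class `kmc_trajectory`: list with `records` (a
#'   data.frame with columns `step`, `t`, `E`, `kind`, `d1..dM`, `shock`),
#'   `final_state`, `t_tot`, `steps`, `assembled`, `t_fas`, and `meta`.
#' @examples
#' tg <- make_targets(4, 1)
#' p <- interaction_params()
#' st <- random_initial_state(4, tg, seed = 1)
#' tr <- run_trajectory(st, p, tg, T_cap = 1000, seed = 2)
#' tr
#' @export
run_trajectory <- function(initial_state, params, targets, T_cap,
                           t_limit = Inf, seed = NULL, stride = 1L,
                           stop_on_assembly = FALSE,
                           rate_law = c("symmetric", "metropolis"),
                           record_state_code = FALSE) {
  rate_law <- match.arg(rate_law)
  stopifnot(T_cap >= 1)
  run <- function() {
    .engine_chunk(initial_state, params, targets, max_steps = T_cap,
                  t_stop = t_limit,
                  stride = stride, stop_on_assembly = stop_on_assembly,
                  record_state_code = record_state_code, rate_law = rate_law)
  }
  out <- if (is.null(seed)) run() else .with_seed(seed, run())
  rec <- as.data.frame(out$records)
  rec$shock <- 0L
  structure(list(records = rec, final_state = out$state, t_tot = out$t,
                 steps = out$steps, assembled = out$assembled,
                 t_fas = out$t_fas,
                 meta = list(params = params, targets_m = targets$m,
                             n = targets$n, L = initial_state$L,
                             T_cap = T_cap, t_limit = t_limit,
                             seed = seed, stride = stride,
                             rate_law = rate_law,
                             stop_on_assembly = stop_on_assembly)),
            class = "kmc_trajectory")
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat(sprintf(paste0("KMC trajectory: %d steps, T_tot = %.4g s, ",
                     "E_final = %.3f k_BT, %s\n"),
              as.integer(x$steps), x$t_tot, tail(x$records$E, 1),
              if (x$assembled) sprintf("assembled at t = %.4g s", x$t_fas)
              else "not assembled"))
  invisible(x)
}

#' @export
plot.kmc_trajectory <- function(x, which = c("energy", "distance"), ...) {
  which <- match.arg(which)
  r <- x$records
  if (which == "energy") {
    plot(r$t, r$E, type = "l", xlab = "time (s)", ylab = "E (k_BT)", ...)
    if (any(r$shock > 0)) {
      on_idx <- which(diff(c(0L, r$shock)) == 1L)
      off_idx <- which(diff(c(r$shock, 0L)) == -1L)
      for (i in seq_along(on_idx))
        rect(r$t[on_idx[i]], min(r$E), r$t[off_idx[i]], max(r$E),
             col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  } else {
    dcols <- grep("^d[0-9]+$", names(r), value = TRUE)
    dmin <- do.call(pmin, r[dcols])
    plot(r$t, dmin, type = "l", xlab = "time (s)", ylab = "min distance", ...)
  }
  invisible(x)
}

#' Write a trajectory record table as CSV
#'
#' Columns: `step`, `t`, `E`, `kind` (0 initial, 1 translation, 2 switch),
#' `d1..dM`, `shock` (0/1 drive flag).
#'
#' @param traj a `kmc_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "kmc_trajectory"))
  write.csv(traj$records, path, row.names = FALSE)
  invisible(path)
}

# de-duplicated (t, value) series from a record table, for segmentation
.records_series <- function(records, column = "E") {
  t <- records$t; y <- records[[column]]
  keep <- c(TRUE, diff(t) > 0)
  list(t = t[keep], y = y[keep])
}
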