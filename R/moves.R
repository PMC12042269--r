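#' Transition rate of a candidate move
#'
#' Rates follow the symmetric-barrier form
#' \deqn{r = r_0 \exp(-\Delta E / 2 k_B T)}
#' for translations and
#' \deqn{q = \frac{4 r_0}{M_T - 1} \exp(-\Delta E / 2 k_B T)}
#' for state switches, where \eqn{\Delta E = E_i - E_j} is the energy change
#' of the move.  Both satisfy detailed balance,
#' `rate(dE) / rate(-dE) = exp(-dE)`.  The switch prefactor makes
#' translation and switching equally likely for a particle when
#' `E_i = E_j`.  A Metropolis variant `r_0 * min(1, exp(-dE))` is available
#' behind `rate_law = "metropolis"`; it obeys the same detailed-balance
#' ratio.  Forbidden translations (occupied or off-board destination) carry
#' rate 0 and are handled by [enumerate_moves()], not here.
#'
#' @param kind `"translate"` or `"switch"`.
#' @param dE energy change `E_i - E_j` in k_BT.
#' @param params [interaction_params()] (supplies `r_0`).
#' @param m_targets number of targets `M_T` (needed for switch rates).
#' @param rate_law `"symmetric"` (default) or `"metropolis"`.
#' @return rate in 1/s.
#' @examples
#' move_rate("translate", 0, interaction_params(), 2)        # 2.5e6
#' move_rate("switch", 0, interaction_params(), 2)           # 1e7
#' @export
move_rate <- function(kind = c("translate", "switch"), dE, params, m_targets,
                      rate_law = c("symmetric", "metropolis")) {
  kind <- match.arg(kind); rate_law <- match.arg(rate_law)
  stopifnot(is.finite(dE))
  f <- if (rate_law == "symmetric") exp(-dE / 2) else pmin(1, exp(-dE))
  if (kind == "translate") return(params$r_0 * f)
  if (m_targets < 2)
    stop("state-switch moves do not exist for a single stored target")
  4 * params$r_0 / (m_targets - 1) * f
}

#' Enumerate all candidate moves of a configuration
#'
#' Builds the ordered move set of length `(3 + M_T) * N`: the `4N`
#' single-particle translations first (particle-major; directions up, down,
#' left, right), then the `(M_T - 1) N` state switches (particle-major;
#' candidate state ascending, skipping the current one).  Forbidden
#' translations keep their slot with rate 0 so the ordering is canonical.
#'
#' @param state [lattice_state()].
#' @param params [interaction_params()].
#' @param targets `target_set`.
#' @param rate_law passed to [move_rate()].
#' @return a data.frame with columns `index`, `kind`, `particle`, `dir`,
#'   `new_state`, `dE`, `rate`.
#' @export
enumerate_moves <- function(state, params, targets,
                            rate_law = c("symmetric", "metropolis")) {
  rate_law <- match.arg(rate_law)
  n <- nrow(state$positions); M <- targets$m; L <- state$L
  pos <- state$positions
  occ <- matrix(0L, L, L)
  occ[pos[, 1] + 1L + pos[, 2] * L] <- seq_len(n)
  drs <- c(-1L, 1L, 0L, 0L); dcs <- c(0L, 0L, -1L, 1L)
  n_tr <- 4L * n
  n_sw <- (M - 1L) * n
  kind <- c(rep("translate", n_tr), rep("switch", n_sw))
  particle <- c(rep(seq_len(n), each = 4L),
                if (n_sw) rep(seq_len(n), each = M - 1L) else integer(0))
  dir <- c(rep(1:4, times = n), rep(NA_integer_, n_sw))
  new_state <- c(rep(NA_integer_, n_tr),
                 if (n_sw) unlist(lapply(seq_len(n), function(a)
                   setdiff(seq_len(M), state$states[a]))) else integer(0))
  dE <- numeric(n_tr + n_sw); rate <- numeric(n_tr + n_sw)
  for (i in seq_len(n_tr)) {
    a <- particle[i]; d <- dir[i]
    nr <- pos[a, 1] + drs[d]; nc <- pos[a, 2] + dcs[d]
    if (nr < 0 || nr >= L || nc < 0 || nc >= L || occ[nr + 1L, nc + 1L] != 0L) {
      rate[i] <- 0; dE[i] <- 0
    } else {
      dE[i] <- delta_energy(state, list(kind = "translate", particle = a,
                                        dir = d), params, targets)
      rate[i] <- move_rate("translate", dE[i], params, M, rate_law)
    }
  }
  if (n_sw) for (i in (n_tr + 1L):(n_tr + n_sw)) {
    dE[i] <- delta_energy(state, list(kind = "switch", particle = particle[i],
                                      new_state = new_state[i]),
                          params, targets)
    rate[i] <- move_rate("switch", dE[i], params, M, rate_law)
  }
  data.frame(index = seq_along(kind), kind = kind, particle = particle,
             dir = dir, new_state = new_state, dE = dE, rate = rate)
}

#' Select the next move from cumulative rates
#'
#' Given the non-decreasing cumulative rate function `R_i` and a uniform
#' draw `u` in (0, 1], returns the smallest index `I` with
#' `R_{I-1} < u * Q <= R_I` (where `Q = R_{N_tot}` is the total escape
#' rate).  Zero-rate moves can never be selected.
#'
#' @param cumulative numeric vector of cumulative rates.
#' @param u uniform random number in (0, 1].
#' @return the selected move index.
#' @examples
#' select_move(cumsum(c(1, 2, 3)), 0.5)  # u*Q = 3 -> index 2
#' @export
select_move <- function(cumulative, u) {
  Q <- cumulative[length(cumulative)]
  if (!(Q > 0)) stop("stalled state: total escape rate is zero")
  stopifnot(u > 0, u <= 1)
  target <- u * Q
  which(cumulative >= target)[1]
}

#' Exponential waiting time of the n-fold way step
#'
#' The dwell time in the current state is `dt = log(1/u') / Q` with
#' `u'` uniform in (0, 1] — an exponential variate with mean `1/Q`.
#'
#' @param Q total escape rate (1/s), > 0.
#' @param u2 uniform random number(s) in (0, 1].
#' @return waiting time(s) in seconds.
#' @export
waiting_time <- function(Q, u2) {
  stopifnot(Q > 0, all(u2 > 0), all(u2 <= 1))
  log(1 / u2) / Q
}

#' One reference KMC step in pure R
#'
#' Executes a single n-fold way step with the documented RNG draw order
#' (`u` for selection, then `u'` for time), mirroring the compiled engine
#' move for move.  Used for oracle cross-checks and tiny systems.
#'
#' @inheritParams enumerate_moves
#' @return list with the updated `state`, `dt`, the chosen `move` (one row
#'   of the move set), and `dE`.
#' @export
kmc_step <- function(state, params, targets,
                     rate_law = c("symmetric", "metropolis")) {
  rate_law <- match.arg(rate_law)
  ms <- enumerate_moves(state, params, targets, rate_law)
  cum <- cumsum(ms$rate)
  u <- runif(1)
  sel <- select_move(cum, u)
  u2 <- runif(1)
  dt <- waiting_time(cum[length(cum)], u2)
  mv <- ms[sel, ]
  pos <- state$positions; st <- state$states
  if (mv$kind == "translate") {
    drs <- c(-1L, 1L, 0L, 0L); dcs <- c(0L, 0L, -1L, 1L)
    pos[mv$particle, ] <- pos[mv$particle, ] + c(drs[mv$dir], dcs[mv$dir])
  } else {
    st[mv$particle] <- mv$new_state
  }
  list(state = lattice_state(pos, st, state$L, state$m_targets),
       dt = dt, move = mv, dE = mv$dE)
}
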