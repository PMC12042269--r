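#' Pairwise interaction energy
#'
#' Two particles occupying edge-sharing tiles interact according to their
#' internal states and the stored targets: strong attraction `J_s` when the
#' pair is a neighbouring pair in both particles' state-targets (this
#' includes equal states `s_a = s_b = m` with `I^m(a,b) = 1`, and also
#' different states when the pair is bonded in both targets); weak
#' attraction `J_w` when in neither; and the intermediate value
#' `(J_s + J_w)/2` when in exactly one.  Equivalently,
#' \deqn{J = J_w + \frac{J_s - J_w}{2}\,(I^{s_a}(a,b) + I^{s_b}(a,b)),}
#' the unique affine form reproducing the three rules.
#'
#' @param params [interaction_params()].
#' @param targets [make_targets()] `target_set`.
#' @param a,b particle labels (1-based, distinct).
#' @param s_a,s_b internal states of `a` and `b`.
#' @return interaction energy in k_BT.
#' @examples
#' tg <- make_targets(25, 2); p <- interaction_params()
#' pair_interaction(p, tg, 1, 2, 1, 1)  # bonded in target 1: J_s = -2.5
#' @export
pair_interaction <- function(params, targets, a, b, s_a, s_b) {
  stopifnot(a != b)
  Ia <- targets$adjacency[[s_a]][a, b]
  Ib <- targets$adjacency[[s_b]][a, b]
  params$J_w + (params$J_s - params$J_w) / 2 * (Ia + Ib)
}

#' Total configurational energy
#'
#' Sum of [pair_interaction()] over unordered pairs of particles that are
#' currently nearest neighbours on the board; each physical pair is counted
#' once.  This is the reference (O(N^2)) implementation; the simulation
#' engine maintains the same quantity incrementally and re-validates
#' against a full recomputation every 1e5 steps.
#'
#' @param state [lattice_state()].
#' @inheritParams pair_interaction
#' @return energy in k_BT.
#' @export
total_energy <- function(state, params, targets) {
  pos <- state$positions; st <- state$states
  n <- nrow(pos); E <- 0
  if (n < 2) return(0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (abs(pos[a, 1] - pos[b, 1]) + abs(pos[a, 2] - pos[b, 2]) == 1L)
      E <- E + pair_interaction(params, targets, a, b, st[a], st[b])
  }
  E
}

#' Energy change of a candidate move
#'
#' Computes `total_energy(after) - total_energy(before)` from the moved (or
#' switched) particle's local neighbourhood only.  `move` is a list with
#' `kind` (`"translate"` or `"switch"`), `particle`, and either `dir`
#' (1=up, 2=down, 3=left, 4=right) or `new_state`.
#'
#' @param state [lattice_state()].
#' @param move candidate move (see Details).
#' @inheritParams pair_interaction
#' @return energy difference in k_BT.
#' @export
delta_energy <- function(state, move, params, targets) {
  pos <- state$positions; st <- state$states; L <- state$L
  a <- move$particle
  occ_at <- function(r, c) {
    if (r < 0 || r >= L || c < 0 || c >= L) return(0L)
    hit <- which(pos[, 1] == r & pos[, 2] == c)
    if (length(hit)) hit else 0L
  }
  nb_of <- function(r, c, excl = 0L) {
    out <- integer(0)
    for (d in 1:4) {
      b <- occ_at(r + c(-1L, 1L, 0L, 0L)[d], c + c(0L, 0L, -1L, 1L)[d])
      if (b != 0L && b != a && b != excl) out <- c(out, b)
    }
    out
  }
  if (identical(move$kind, "translate")) {
    dr <- c(-1L, 1L, 0L, 0L)[move$dir]; dc <- c(0L, 0L, -1L, 1L)[move$dir]
    r <- pos[a, 1]; c0 <- pos[a, 2]; nr <- r + dr; nc <- c0 + dc
    if (nr < 0 || nr >= L || nc < 0 || nc >= L || occ_at(nr, nc) != 0L)
      stop("illegal translation: destination off-board or occupied")
    old_nb <- nb_of(r, c0)
    new_nb <- nb_of(nr, nc)
    eJ <- function(b) pair_interaction(params, targets, a, b, st[a], st[b])
    sum(vapply(new_nb, eJ, numeric(1))) - sum(vapply(old_nb, eJ, numeric(1)))
  } else if (identical(move$kind, "switch")) {
    s_new <- move$new_state
    if (s_new == st[a] || s_new < 1 || s_new > state$m_targets)
      stop("illegal state switch")
    nb <- nb_of(pos[a, 1], pos[a, 2])
    if (!length(nb)) return(0)
    sum(vapply(nb, function(b)
      pair_interaction(params, targets, a, b, s_new, st[b]) -
      pair_interaction(params, targets, a, b, st[a], st[b]), numeric(1)))
  } else stop("unknown move kind")
}
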