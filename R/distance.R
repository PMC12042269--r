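#' Distance to the stored targets
#'
#' Measures how far the current configuration is from each stored target by
#' comparing the board adjacency matrix `B` with the target adjacency
#' matrices `I^m`, plus a state term.  Under the default convention,
#' \deqn{d_m = \#\{(a,b), a \ne b : B(a,b) \ne I^m(a,b)\} +
#'       \#\{a : s_a \ne m\},}
#' i.e. the ordered-pair Hamming distance between adjacency matrices plus
#' the count of particles whose internal state disagrees with the target,
#' and the overall distance is `d = min_m d_m`.  `d_m = 0` iff the board
#' exactly realizes target `m` with all internal states equal to `m`.
#'
#' The comparison sits behind a small convention interface:
#' `"ordered_state"` (default, above), `"unordered_state"` (each pair
#' counted once), and `"ordered"` (no state term).  The simulation engine
#' tracks the default convention incrementally.
#'
#' @param state [lattice_state()].
#' @param targets [make_targets()] `target_set`.
#' @param convention distance convention, see Details.
#' @return list with `d_m` (per-target distances) and `d` (their minimum).
#' @examples
#' tg <- make_targets(25, 2)
#' st <- assembled_state(tg, 1, L = 15)
#' distance_to_targets(st, tg)$d_m   # c(0, >0)
#' @export
distance_to_targets <- function(state, targets,
                                convention = c("ordered_state",
                                               "unordered_state", "ordered")) {
  convention <- match.arg(convention)
  B <- board_adjacency(state)
  d_m <- vapply(seq_len(targets$m), function(m) {
    ham <- sum(B != targets$adjacency[[m]])
    if (convention == "unordered_state") ham <- ham / 2
    sterm <- if (convention == "ordered") 0 else sum(state$states != m)
    ham + sterm
  }, numeric(1))
  list(d_m = d_m, d = min(d_m))
}
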