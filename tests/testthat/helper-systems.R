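# shared miniature systems for the suite (built in code, no stored fixtures)

default_targets <- function() make_targets(25, 2)
default_params <- function() interaction_params()

# exact Boltzmann distribution of the "toy2" system (2 labelled particles
# on a 3x3 board, one domino target): brute-force enumeration of all 72
# ordered injective placements
toy2_boltzmann <- function(params) {
  tiles <- expand.grid(a = 0:8, b = 0:8)
  tiles <- tiles[tiles$a != tiles$b, ]
  adj <- function(i, j) {
    abs(i %/% 3 - j %/% 3) + abs(i %% 3 - j %% 3) == 1
  }
  E <- ifelse(mapply(adj, tiles$a, tiles$b), params$J_s, 0)
  list(code = tiles$a + tiles$b * 9, p = exp(-E) / sum(exp(-E)), E = E)
}

# straight-chain trap of the trap4 system: particles 1-2-4-3 along the top
# row; three of the four target bonds present, unable to fold without
# breaking one
trap4_chain_state <- function() {
  lattice_state(rbind(c(0L, 0L), c(0L, 1L), c(0L, 3L), c(0L, 2L)),
                rep(1L, 4), L = 4, m_targets = 1)
}

# time-weighted state occupancy from a stride-1 record table
occupancy_weights <- function(records, codes) {
  w <- diff(records$t)
  cd <- records$state_code[-nrow(records)]
  occ <- tapply(w, factor(cd, levels = codes), sum)
  occ[is.na(occ)] <- 0
  occ / sum(occ)
}
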