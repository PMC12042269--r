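#' Lattice configuration of the particle system
#'
#' A configuration is an injective map from particle labels `1..N` to tiles
#' of the `L x L` board (0-based `(row, col)`, hard walls, no periodic
#' wrap-around) plus one internal state per particle in `1..M_T`.
#'
#' @param positions `N x 2` integer matrix of 0-based `(row, col)` tiles.
#' @param states integer vector of internal states in `1..m_targets`.
#' @param L board side length.
#' @param m_targets number of stored targets (upper bound for states).
#' @return an object of class `lattice_state`.
#' @export
lattice_state <- function(positions, states, L, m_targets = max(states)) {
  positions <- matrix(as.integer(positions), ncol = 2)
  states <- as.integer(states)
  n <- nrow(positions)
  if (length(states) != n) stop("positions and states disagree on N")
  if (any(positions < 0) || any(positions >= L))
    stop("positions must lie within [0, L)^2")
  if (anyDuplicated(positions[, 1] * L + positions[, 2]))
    stop("two particles share a tile")
  if (any(states < 1) || any(states > m_targets))
    stop("internal states out of range")
  structure(list(L = as.integer(L), positions = positions, states = states,
                 m_targets = as.integer(m_targets)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice state: %d particles on a %d x %d board, states in 1..%d\n",
              nrow(x$positions), x$L, x$L, x$m_targets))
  invisible(x)
}

#' Random initial configuration
#'
#' Positions are drawn uniformly among injective placements of `N` particles
#' on the `L x L` board; internal states uniformly on `1..M_T`.  Consumes
#' the R RNG stream (one `sample` call for tiles, one for states), so the
#' draw is reproducible under `set.seed()` or via the `seed` argument.
#'
#' @param L board side length.
#' @param targets a [make_targets()] `target_set` (supplies `N` and `M_T`).
#' @param seed optional integer seed (local to this call).
#' @return a [lattice_state()].
#' @export
random_initial_state <- function(L, targets, seed = NULL) {
  stopifnot(inherits(targets, "target_set"))
  n <- targets$n
  if (n > L * L) stop("cannot place N particles on an L x L board: N > L^2")
  draw <- function() {
    tiles <- sample.int(L * L, n)  # injective by construction
    pos <- cbind((tiles - 1L) %/% L, (tiles - 1L) %% L)
    st <- sample.int(targets$m, n, replace = TRUE)
    lattice_state(pos, st, L, targets$m)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Perfectly assembled configuration of one target
#'
#' Places the particles according to target `m`'s stored placement (offset
#' into the board) with every internal state set to `m`; by construction its
#' distance to target `m` is zero.
#'
#' @param targets a `target_set`.
#' @param m which target to realize.
#' @param L board side length.
#' @param offset 0-based `(row, col)` offset of the placement.
#' @return a [lattice_state()].
#' @export
assembled_state <- function(targets, m = 1, L, offset = c(0, 0)) {
  stopifnot(inherits(targets, "target_set"))
  pos <- targets$placements[[m]]
  pos <- cbind(pos[, 1] + offset[1], pos[, 2] + offset[2])
  lattice_state(pos, rep(m, targets$n), L, targets$m)
}

#' Board adjacency matrix
#'
#' `B(a, b) = 1` iff particles `a` and `b` currently occupy edge-sharing
#' tiles; symmetric, zero diagonal, row sums at most 4.
#'
#' @param state a [lattice_state()].
#' @return an `N x N` integer 0/1 matrix.
#' @export
board_adjacency <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  .adjacency_from_placement(state$positions)
}

#' Serialize / restore states and target sets as JSON
#'
#' Plain-text persistence of configurations and target sets: positions as
#' 0-based tile pairs, states as a vector, adjacency as index-pair lists.
#'
#' @param x a `lattice_state` or `target_set`.
#' @param path file path.
#' @name slm-json
#' @export
write_state_json <- function(x, path) {
  stopifnot(inherits(x, "lattice_state"))
  obj <- list(L = x$L, m_targets = x$m_targets,
              positions = unname(apply(x$positions, 1, as.list)),
              states = x$states)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slm-json
#' @export
read_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lattice_state(.as_pair_matrix(obj$positions), unlist(obj$states),
                obj$L, obj$m_targets)
}

# jsonlite may simplify a list of (row, col) pairs to a matrix or a
# data.frame (named pairs) on the way back in
.as_pair_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) return(unname(matrix(as.integer(x), ncol = 2)))
  matrix(as.integer(unlist(x)), ncol = 2, byrow = TRUE)
}

#' @rdname slm-json
#' @export
write_targets_json <- function(x, path) {
  stopifnot(inherits(x, "target_set"))
  pairs <- lapply(x$adjacency, function(I) {
    w <- which(upper.tri(I) & I == 1L, arr.ind = TRUE)
    dimnames(w) <- NULL
    unname(apply(w, 1, as.list))
  })
  obj <- list(n = x$n, m = x$m, bonds = pairs,
              placements = lapply(x$placements, function(p)
                unname(apply(p, 1, as.list))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slm-json
#' @export
read_targets_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- obj$n; m <- obj$m
  adjacency <- vector("list", m); placements <- vector("list", m)
  for (i in seq_len(m)) {
    I <- matrix(0L, n, n)
    b <- obj$bonds[[i]]
    if (length(unlist(b))) {
      bm <- .as_pair_matrix(b)
      for (r in seq_len(nrow(bm))) {
        I[bm[r, 1], bm[r, 2]] <- 1L; I[bm[r, 2], bm[r, 1]] <- 1L
      }
    }
    adjacency[[i]] <- I
    placements[[i]] <- .as_pair_matrix(obj$placements[[i]])
  }
  structure(list(n = n, m = m, adjacency = adjacency, placements = placements),
            class = "target_set")
}
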