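#' Construct a set of stored target structures
#'
#' Each target is a connected placement of the `n_particles` labelled
#' particles on the lattice; its adjacency matrix `I^m` (symmetric 0/1, zero
#' diagonal) records which particle pairs are nearest neighbours in that
#' target.  The default shape is the compact `sqrt(N) x sqrt(N)` square
#' block; targets beyond the first reuse the same footprint with a different
#' deterministic particle labelling (boustrophedon, then inward spiral, then
#' seeded random permutations), which guarantees pairwise-distinct adjacency
#' matrices while keeping every target maximally bonded.
#'
#' @param n_particles number of particles `N`; must be a perfect square for
#'   the default square shape.
#' @param m_targets number of stored targets `M_T` (>= 1).
#' @param shape_spec either `"square"` (default) or an explicit placement:
#'   an `N x 2` integer matrix of 0-based `(row, col)` tile offsets whose
#'   tiles form a connected polyomino.
#' @param seed optional seed used only when more labellings are needed than
#'   the three deterministic ones.
#' @return an object of class `target_set` with fields `n`, `m`,
#'   `adjacency` (list of `N x N` 0/1 matrices) and `placements` (list of
#'   `N x 2` matrices of 0-based tiles).
#' @examples
#' tg <- make_targets(25, 2)
#' sum(tg$adjacency[[1]]) / 2   # 40 internal bonds in a 5x5 block
#' @export
make_targets <- function(n_particles, m_targets = 2, shape_spec = "square",
                         seed = NULL) {
  stopifnot(n_particles >= 1, m_targets >= 1)
  if (is.character(shape_spec) && identical(shape_spec, "square")) {
    k <- round(sqrt(n_particles))
    if (k * k != n_particles)
      stop("n_particles must be a perfect square for the default square shape")
    tiles <- cbind(rep(0:(k - 1), each = k), rep(0:(k - 1), times = k))
  } else if (is.matrix(shape_spec)) {
    tiles <- shape_spec
    if (nrow(tiles) != n_particles || ncol(tiles) != 2)
      stop("shape_spec placement must be an N x 2 matrix")
    if (anyDuplicated(paste(tiles[, 1], tiles[, 2])))
      stop("shape_spec tiles must be distinct")
    if (!.tiles_connected(tiles))
      stop("shape_spec tiles do not form a connected polyomino")
  } else stop("unknown shape_spec")

  labelings <- .target_labelings(n_particles, m_targets, tiles, seed)
  placements <- vector("list", m_targets)
  adjacency <- vector("list", m_targets)
  for (m in seq_len(m_targets)) {
    plc <- matrix(NA_integer_, n_particles, 2)
    plc[labelings[[m]], ] <- tiles   # particle `lab` sits on tile i
    placements[[m]] <- plc
    adjacency[[m]] <- .adjacency_from_placement(plc)
  }
  # distinctness invariant
  if (m_targets > 1) {
    for (i in seq_len(m_targets - 1)) for (j in (i + 1):m_targets)
      if (identical(adjacency[[i]], adjacency[[j]]))
        stop("could not construct distinct target adjacency matrices")
  }
  structure(list(n = n_particles, m = m_targets,
                 adjacency = adjacency, placements = placements),
            class = "target_set")
}

# particle labels assigned to the ordered tile list, one permutation per target
.target_labelings <- function(n, m, tiles, seed) {
  k <- round(sqrt(n))
  ord <- order(tiles[, 1], tiles[, 2])  # row-major tile order
  out <- list()
  # labelling 1: row-major
  lab <- integer(n); lab[ord] <- seq_len(n); out[[1]] <- lab
  if (m >= 2) {  # labelling 2: boustrophedon over rows of the footprint
    rows <- tiles[, 1]
    lab2 <- integer(n); nxt <- 1L
    for (r in sort(unique(rows))) {
      idx <- which(rows == r)
      idx <- idx[order(tiles[idx, 2])]
      if ((r - min(rows)) %% 2 == 1) idx <- rev(idx)
      lab2[idx] <- nxt:(nxt + length(idx) - 1L); nxt <- nxt + length(idx)
    }
    out[[2]] <- lab2
  }
  if (m >= 3 && k * k == n && is.matrix(tiles) && nrow(tiles) == n) {
    # labelling 3: inward clockwise spiral over the square footprint
    sp <- .spiral_order(k)
    lab3 <- integer(n); lab3[ord[sp]] <- seq_len(n)
    out[[3]] <- lab3
  }
  if (m > length(out)) {
    if (is.null(seed)) seed <- 1L
    rng <- .with_seed(seed, {
      extra <- list()
      tries <- 0
      while (length(out) + length(extra) < m && tries < 1000) {
        cand <- sample.int(n)
        extra[[length(extra) + 1L]] <- cand
        tries <- tries + 1
      }
      extra
    })
    out <- c(out, rng)
  }
  out[seq_len(m)]
}

.spiral_order <- function(k) {
  g <- matrix(0L, k, k); top <- 1L; bot <- k; lef <- 1L; rig <- k; v <- 1L
  while (top <= bot && lef <= rig) {
    for (c in lef:rig) { g[top, c] <- v; v <- v + 1L }
    top <- top + 1L
    if (top > bot) break
    for (r in top:bot) { g[r, rig] <- v; v <- v + 1L }
    rig <- rig - 1L
    if (lef > rig) break
    for (c in rig:lef) { g[bot, c] <- v; v <- v + 1L }
    bot <- bot - 1L
    if (top > bot) break
    for (r in bot:top) { g[r, lef] <- v; v <- v + 1L }
    lef <- lef + 1L
  }
  order(as.vector(t(g)))  # row-major tile index -> spiral rank
}

.adjacency_from_placement <- function(plc) {
  n <- nrow(plc)
  I <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (abs(plc[a, 1] - plc[b, 1]) + abs(plc[a, 2] - plc[b, 2]) == 1L) {
      I[a, b] <- 1L; I[b, a] <- 1L
    }
  }
  I
}

.tiles_connected <- function(tiles) {
  n <- nrow(tiles)
  if (n <= 1) return(TRUE)
  key <- paste(tiles[, 1], tiles[, 2])
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- paste(tiles[i, 1] + c(-1, 1, 0, 0), tiles[i, 2] + c(0, 0, -1, 1))
      hit <- which(!seen & key %in% nb)
      seen[hit] <- TRUE; nxt <- c(nxt, hit)
    }
    frontier <- nxt
  }
  all(seen)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.target_set <- function(x, ...) {
  bonds <- vapply(x$adjacency, function(I) sum(I) / 2, numeric(1))
  cat(sprintf("target set: %d particles, %d target(s); bonds per target: %s\n",
              x$n, x$m, paste(bonds, collapse = ", ")))
  invisible(x)
}

#' Number of bonds in a stored target
#' @param targets a `target_set`.
#' @param m target index.
#' @return integer bond count of target `m`.
#' @export
target_bonds <- function(targets, m = 1) {
  stopifnot(inherits(targets, "target_set"))
  sum(targets$adjacency[[m]]) / 2
}
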