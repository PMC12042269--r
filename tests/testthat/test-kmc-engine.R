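test_that("move rates reproduce the base-rate conventions", {
  p <- interaction_params()
  expect_equal(move_rate("translate", 0, p, 2), 2.5e6)
  # switch prefactor 4 r0 / (M_T - 1): equal likelihood with translations
  expect_equal(move_rate("switch", 0, p, 2), 1e7)
  expect_equal(move_rate("switch", 0, p, 5), 2.5e6)
  expect_error(move_rate("switch", 0, p, 1), "single stored target")
})

test_that("both rate laws satisfy detailed balance exactly", {
  p <- interaction_params()
  for (law in c("symmetric", "metropolis")) {
    for (dE in c(-3.5, -1, -0.25, 0, 0.25, 1, 3.5)) {
      r_fwd <- move_rate("translate", dE, p, 2, law)
      r_bwd <- move_rate("translate", -dE, p, 2, law)
      expect_equal(r_fwd / r_bwd, exp(-dE), tolerance = 1e-12)
      q_fwd <- move_rate("switch", dE, p, 3, law)
      q_bwd <- move_rate("switch", -dE, p, 3, law)
      expect_equal(q_fwd / q_bwd, exp(-dE), tolerance = 1e-12)
    }
  }
})

test_that("move enumeration has canonical size, order and forbidden zeros", {
  tg <- default_targets(); p <- default_params()
  st <- random_initial_state(15, tg, seed = 1)
  ms <- enumerate_moves(st, p, tg)
  expect_equal(nrow(ms), (3 + 2) * 25)          # (3 + M_T) N candidates
  expect_equal(sum(ms$kind == "translate"), 100)
  expect_identical(ms$kind, c(rep("translate", 100), rep("switch", 25)))
  # a particle boxed in on all four sides has all-zero translation rates
  tgb <- make_targets(9, 2)
  box <- lattice_state(cbind(c(1L, 0L, 2L, 1L, 1L, 0L, 0L, 2L, 2L),
                             c(1L, 1L, 1L, 0L, 2L, 0L, 2L, 0L, 2L)),
                       rep(1L, 9), 3, 2)
  msb <- enumerate_moves(box, p, tgb)
  expect_true(all(msb$rate[msb$particle == 1 & msb$kind == "translate"] == 0))
  # an isolated particle with free neighbours translates at r_0
  tgi <- make_targets(4, 2)
  iso <- lattice_state(cbind(c(2L, 0L, 0L, 6L), c(2L, 0L, 6L, 0L)),
                       rep(1L, 4), 7, 2)
  msi <- enumerate_moves(iso, p, tgi)
  expect_equal(msi$rate[msi$kind == "translate" & msi$particle == 1],
               rep(2.5e6, 4))
})

test_that("move selection brackets the cumulative rate function", {
  expect_equal(select_move(cumsum(c(1, 2, 3)), 0.5), 2)  # uQ = 3 -> R_2
  expect_equal(select_move(cumsum(c(1, 2, 3)), 1), 3)
  # zero-rate moves are never selected
  cum <- cumsum(c(1, 0, 2, 0, 1))
  set.seed(1)
  sel <- vapply(runif(10000), function(u) select_move(cum, u), 1)
  expect_true(all(sel %in% c(1, 3, 5)))
  # equal rates select uniformly
  sel2 <- vapply(runif(30000), function(u) select_move(cumsum(rep(1, 4)), u), 1)
  expect_gt(stats::chisq.test(tabulate(sel2, 4))$p.value, 1e-4)
  expect_error(select_move(c(0, 0), 0.5), "stalled")
})

test_that("waiting times are exponential with mean 1/Q", {
  expect_equal(waiting_time(2.5e6, 1), 0)
  set.seed(3)
  u <- runif(1e5)
  dts <- waiting_time(4e6, u)
  expect_equal(mean(dts), 1 / 4e6, tolerance = 0.01)
  expect_equal(waiting_time(2e6, 0.3), 2 * waiting_time(4e6, 0.3))
})

test_that("compiled engine reproduces the R reference stepper move for move", {
  tg <- make_targets(4, 2); p <- interaction_params(J_s = -3)
  st0 <- random_initial_state(4, tg, seed = 7)
  set.seed(99)
  st <- st0; tR <- 0; ER <- total_energy(st0, p, tg)
  for (i in 1:150) {
    s <- kmc_step(st, p, tg)
    st <- s$state; tR <- tR + s$dt; ER <- ER + s$dE
  }
  tr <- run_trajectory(st0, p, tg, T_cap = 150, seed = 99)
  expect_identical(st$positions, tr$final_state$positions)
  expect_identical(st$states, tr$final_state$states)
  expect_equal(tR, tr$t_tot, tolerance = 1e-12)
  expect_equal(ER, utils::tail(tr$records$E, 1), tolerance = 1e-9)
  # and the same under the Metropolis rate law
  set.seed(17)
  st <- st0
  for (i in 1:80) st <- kmc_step(st, p, tg, rate_law = "metropolis")$state
  trm <- run_trajectory(st0, p, tg, T_cap = 80, seed = 17,
                        rate_law = "metropolis")
  expect_identical(st$positions, trm$final_state$positions)
})

test_that("trajectories are reproducible, time-ordered and bookkept", {
  tg <- make_targets(9, 2); p <- interaction_params(J_s = -3.2)
  st <- random_initial_state(9, tg, seed = 5)
  tr1 <- run_trajectory(st, p, tg, T_cap = 2e4, seed = 31, stride = 7)
  tr2 <- run_trajectory(st, p, tg, T_cap = 2e4, seed = 31, stride = 7)
  expect_identical(tr1$records, tr2$records)
  expect_true(all(diff(tr1$records$t) > 0))
  # recorded energy and distances match full recomputation at the end
  expect_equal(utils::tail(tr1$records$E, 1),
               total_energy(tr1$final_state, p, tg), tolerance = 1e-9)
  expect_equal(unlist(utils::tail(tr1$records[c("d1", "d2")], 1),
                      use.names = FALSE),
               distance_to_targets(tr1$final_state, tg)$d_m)
  # record count consistent with the stride (initial + every 7th + final)
  expect_lte(nrow(tr1$records), 2e4 / 7 + 3)
})

test_that("a time limit pauses a dwell without losing trajectory identity", {
  tg <- make_targets(4, 1)
  p <- interaction_params(J_s = -12)
  st <- trap4_chain_state()
  tr <- run_trajectory(st, p, tg, T_cap = 1e4, t_limit = 1e-6, seed = 2)
  expect_equal(tr$t_tot, 1e-6)       # stops exactly at the limit, mid-dwell
  expect_identical(tr$final_state$positions, st$positions)  # nothing moved
})

test_that("first-assembly time is detected exactly", {
  tg <- make_targets(4, 1); p <- interaction_params(J_s = -4)
  set.seed(123)
  hits <- 0
  for (i in 1:10) {
    st <- random_initial_state(4, tg)
    tr <- run_trajectory(st, p, tg, T_cap = 5e4, stop_on_assembly = TRUE,
                         stride = 1000)
    if (tr$assembled) {
      hits <- hits + 1
      expect_equal(distance_to_targets(tr$final_state, tg)$d, 0)
      expect_equal(tr$t_fas, tr$t_tot)
    }
  }
  expect_gt(hits, 0)
})
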