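test_that("first-assembly statistics follow the ensemble conventions", {
  df <- data.frame(t_fas = c(7, NA, NA, 2, 10, NA, NA, NA, NA, NA),
                   assembled = c(TRUE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 5)),
                   t_tot = rep(10, 10))
  fa <- first_assembly_stats(df)
  expect_equal(fa$sa_pct, 30)                   # 3 of 10 assembled
  expect_equal(fa$n, 10)
  # unassembled runs enter at T_tot and group at T_hat = 1
  expect_true(all(fa$table$t_hat[!fa$table$assembled] == 1))
  expect_equal(fa$table$t_hat[1], 0.7)          # 7 / max(10)
  expect_equal(fa$tbar, mean(c(7, 2, 10)))
  # order invariance
  fa2 <- first_assembly_stats(df[10:1, ])
  expect_equal(fa2$sa_pct, fa$sa_pct)
  expect_equal(fa2$median_tfas, fa$median_tfas)
})

test_that("assembly regions follow the boundary values", {
  expect_equal(classify_region(c(-3.5, -2.5, -2.2)), c("III", "II", "I"))
  expect_equal(classify_region(-3.15), "II")    # boundaries belong to II
  expect_equal(classify_region(-2.25), "II")
  expect_equal(classify_region(-3.1500001), "III")
  # total on a fine grid
  expect_false(anyNA(classify_region(seq(-3.6, -2, by = 0.05))))
})

test_that("equilibrium scans log seeds and summarise per energy", {
  tg <- make_targets(4, 2)
  sc <- equilibrium_scan(c(-4), reps = 3, targets = tg, L = 4, T_cap = 500,
                         seed = 5, stride = 100)
  expect_equal(nrow(sc$results), 3)
  expect_length(unique(sc$results$seed), 3)     # disjoint run seeds
  expect_s3_class(sc$stats[["-4"]], "assembly_ensemble")
  # single grid point scan is fine; rerun is identical
  sc2 <- equilibrium_scan(c(-4), reps = 3, targets = tg, L = 4, T_cap = 500,
                          seed = 5, stride = 100)
  expect_equal(sc$results, sc2$results)
})

test_that("control scans include the equilibrium reference", {
  tg <- make_targets(4, 1); p <- interaction_params(J_s = -12)
  trajs <- lapply(1:10, function(s) {
    st <- random_initial_state(4, tg, seed = s)
    run_trajectory(st, p, tg, T_cap = 1e5, t_limit = 1e-4,
                   seed = 600 + s, stride = 1)
  })
  fit <- suppressWarnings(slm_learn(trajs, mode = "offline", n_grid = 200,
                                    min_samples = 2))
  cs <- control_scan(fit, rho_values = c(1.5), reps = 6, targets = tg,
                     L = 4, J_s = -12, T_cap = 1e5, t_limit = 1e-4,
                     seed = 31, stride = 5, n_grid = 200, min_samples = 2)
  expect_true(1 %in% cs$summary$rho)            # reference added
  expect_equal(nrow(cs$summary), 2)
  expect_true(all(cs$summary$sa_pct >= 0 & cs$summary$sa_pct <= 100))
  if (cs$t_tilde_defined)
    expect_equal(cs$summary$t_tilde[cs$summary$rho == 1], 1)
})

test_that("shock distance triplets match a hand-built trajectory", {
  # synthetic controlled trajectory: piecewise-constant min distance,
  # two shocks, segments placed by hand
  rec <- data.frame(step = 0:10,
                    t = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                    E = 0,
                    kind = c(0, rep(1, 10)),
                    d1 = c(40, 40, 40, 20, 20, 20, 10, 10, 10, 5, 5),
                    shock = c(0, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0))
  shocks <- data.frame(t_on = c(3, 7), t_off = c(5, 9),
                       trigger_trend = c(0, 0))
  segs <- data.frame(t_start = c(0, 5), t_end = c(5, 10),
                     trend = c(0, 0), mean = 0, std = 0, dwell = 5)
  ctr <- structure(list(records = rec, shocks = shocks, assembled = FALSE,
                        t_fas = NA_real_, t_tot = 10,
                        meta = list(rho = 1.5)),
                   class = c("controlled_trajectory", "kmc_trajectory"))
  out <- distance_shock_analysis(ctr, segmentations = list(segs))
  expect_equal(nrow(out), 2)
  # activation 1: before = segment [0,5] clipped to [0,3): d = 40
  expect_equal(out$d_before[1], 40)
  # during = [3,5): d = 20
  expect_equal(out$d_during[1], 20)
  # after = segment [5,10] clipped to next activation [5,7): d constant 20,10
  expect_equal(out$d_after[1], (20 + 10) / 2)
  # activation 2: before = segment [5,10] clipped to [5,7)
  expect_equal(out$d_before[2], (20 + 10) / 2)
  expect_equal(out$d_during[2], 10)
  expect_equal(out$d_after[2], 5)
})

test_that("post-assembly activations are excluded from the analysis", {
  rec <- data.frame(step = 0:5, t = 0:5, E = 0, kind = c(0, rep(1, 5)),
                    d1 = c(10, 10, 0, 0, 0, 0), shock = 0)
  shocks <- data.frame(t_on = c(1, 4), t_off = c(1.5, 4.5),
                       trigger_trend = c(0, 0))
  segs <- data.frame(t_start = 0, t_end = 5, trend = 0, mean = 0, std = 0,
                     dwell = 5)
  ctr <- structure(list(records = rec, shocks = shocks, assembled = TRUE,
                        t_fas = 2, t_tot = 5, meta = list(rho = 1.4)),
                   class = c("controlled_trajectory", "kmc_trajectory"))
  out <- distance_shock_analysis(ctr, segmentations = list(segs))
  expect_equal(nrow(out), 1)          # the t_on = 4 activation is dropped
  expect_equal(out$t_on, 1)
})

test_that("distance records bin into the five abscissa boxes", {
  rec <- data.frame(realization = 1, t_on = 1:6, t_off = 2:7,
                    d_before = c(12, 8, 29, 31, 70, 95),
                    d_during = c(15, 9, 30, 33, 75, 90),
                    d_after = c(10, 7, 25, 28, 60, 80))
  bb <- bin_shock_distances(rec)
  expect_true(all(bb$bins$center %in% c(10, 30, 50, 70, 90)))
  b10 <- bb$bins[bb$bins$variable == "d_during" & bb$bins$center == 10, ]
  expect_equal(b10$n, 2)              # d_before 12 and 8 fall in [0, 20]
  b30 <- bb$bins[bb$bins$variable == "d_during" & bb$bins$center == 30, ]
  expect_equal(b30$n, 2)
  expect_true(all(bb$bins$q1 <= bb$bins$median))
  expect_true(all(bb$bins$median <= bb$bins$q3))
})

test_that("registered miniature fixtures are deterministic and sound", {
  f1 <- fixture_small_system("toy2", seed = 4)
  f2 <- fixture_small_system("toy2", seed = 4)
  expect_identical(f1$state, f2$state)
  expect_equal(f1$targets$n, 2)
  expect_equal(f1$L^2 * (f1$L^2 - 1), 72)       # enumerable state space
  f3 <- fixture_small_system("trap4")
  expect_equal(f3$targets$n, 4)
  expect_lt(f3$params$J_s, -6)                  # deep binding
  expect_true(is.finite(f3$t_limit))
  expect_error(fixture_small_system("nope"))
})

test_that("trajectory tables round-trip through CSV", {
  tg <- make_targets(4, 2)
  st <- random_initial_state(4, tg, seed = 2)
  tr <- run_trajectory(st, interaction_params(), tg, T_cap = 200, seed = 3,
                       stride = 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(tr$records))
  expect_equal(back$E, tr$records$E)
  unlink(f)
})
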