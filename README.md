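# slmassembly

Kinetic Monte Carlo simulation of multi-target lattice self-assembly with
a closed-loop control protocol that detects kinetic traps from the energy
trend of the *running* trajectory and rescues them with transient
interaction-energy shocks.

## The problem

Self-assembling systems — DNA bricks, patchy colloids, folding
biopolymers — face a universal trade-off: binding strong enough to hold
the target together is also strong enough to freeze misassembled
intermediates into long-lived **kinetic traps**. Annealing and other
open-loop schedules perturb the system blindly. This package implements a
*feedback* alternative: monitor one cheap global observable (the total
energy), decide in near-real time whether the system is trapped, and only
then kick it.

It is aimed at researchers in molecular simulation and nonequilibrium
statistical mechanics who want a compact, fully reproducible testbed for
trend-based trap detection and drive protocols.

## Model and method

`N` labelled particles move on a bounded `L x L` lattice; each carries an
internal state `s_a ∈ {1..M_T}`, one per stored target structure (encoded
as adjacency matrices `I^m`). Adjacent particles interact with

    J(a,b) = J_w + (J_s − J_w)/2 · ( I^{s_a}(a,b) + I^{s_b}(a,b) ),

i.e. strong binding `J_s` for pairs bonded in both state-targets, weak
`J_w` in neither, the midpoint in exactly one. Dynamics are rejection-free
(n-fold way) KMC: all `(3+M_T)N` move rates `r = r_0 e^{−ΔE/2}` are
enumerated, one move is chosen proportionally, and time advances by an
exponential waiting time with the total escape rate. Assembly is reached
when the distance `d = min_m d_m` (adjacency-mismatch plus state-mismatch
count) hits zero.

The **stochastic landscape method** segments the energy trajectory into
piecewise-linear trends (exact penalized dynamic programming behind a
swappable interface). A learning phase calibrates the monitoring window
`W2 = 0.01 · median(T_FAS)`, pools segment trends and dwelling times from
an equilibrium ensemble, and learns the **trap region** `T* = [−τ, +τ]` —
the near-zero-trend band holding 20–21% of segments, where dwelling times
are longest. During controlled runs, whenever the latest trend falls in
`T*`, all interaction energies are divided by the drive amplitude `ρ` for
`W1` seconds (a global pH-like shock), partially disassembling the trap
without resetting the system.

## Worked example

The bundled `trap4` benchmark (4 particles, one 2×2 target, deep binding
`J_s = −12 k_BT`) is engineered so misfolded chains persist as traps:

```r
library(slmassembly)

fx <- fixture_small_system("trap4")
tg <- fx$targets; p <- fx$params

# equilibrium ensemble -> learning phase
trajs <- lapply(1:50, function(s) {
  st <- random_initial_state(fx$L, tg, seed = s)
  run_trajectory(st, p, tg, T_cap = fx$T_cap, t_limit = fx$t_limit,
                 seed = 5000 + s, stride = 1)
})
mean(sapply(trajs, `[[`, "assembled"))   # 0.28 - most runs stay trapped
fit <- slm_learn(trajs, mode = "online", n_grid = 200, min_samples = 2)
fit
#> stochastic landscape fit (learning phase)
#>   J_s = -12 k_BT, 50 trajectories, 238 pooled segments
#>   W2 = 1e-06 s (0.01 x median T_FAS = 0.0001 s)
#>   T* = [-0, +0] k_BT/s (76.5% of segments)

# closed-loop drive at rho = 1.5
cfg <- control_config(rho = 1.5, trap = fit, n_grid = 200, min_samples = 2)
ct <- run_controlled(random_initial_state(fx$L, tg, seed = 3), p, tg, cfg,
                     fx$T_cap, t_limit = fx$t_limit, seed = 42, stride = 5)
ct
#> controlled KMC trajectory (rho = 1.5): 6 steps, T_tot = 1.027e-05 s,
#>   4 shock(s), assembled at t = 1.027e-05 s
```

Reading the output: only 28% of equilibrium runs assemble within the time
budget; the learned monitoring window is `W2 = 1e-6 s` and the trap region
degenerates to exactly-flat trends (`τ = 0`), which in this miniature
system hold 76% of all segments — trapped, energy-flat dwellings dominate.
The driven run above is detected as trapped, shocked four times, and
assembles. Over 100 paired seeds the drive raises the yield from 0.29
(`ρ = 1`) to 0.48 (`ρ = 1.5`), and the escape frequency from an engineered
chain trap from 0.10 to 0.38 (these ensembles are recomputed by the test
suite). A command-line front end for larger scans lives at
`inst/cli/slm-cli.R` (subcommands `simulate`, `learn`, `control`,
`scan-eq`, `scan-rho`).

The methods vignette (`vignettes/closed-loop-assembly.Rmd`) documents the
model, the segmentation engine, every protocol constant, and the
limitations of reduced-scale validation.

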