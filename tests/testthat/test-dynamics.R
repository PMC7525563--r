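test_that("a zero-step run returns only the initial frame", {
  sys <- build_system(1, 4, box = 20, seed = 1)
  traj <- run_dynamics(sys, force_field(),
                       integrator_config(n_steps = 0, save_every = 0))
  expect_equal(n_frames(traj), 1L)
  expect_equal(traj$frame_steps, 0L)
  expect_equal(traj$frames[[1]], sys$positions)
})

test_that("trajectories are reproducible per seed and diverge across seeds", {
  sys <- build_system(2, 5, box = 20, seed = 2)
  ff <- force_field()
  cfg <- integrator_config(n_steps = 2000, save_every = 500, seed = 9)
  t1 <- run_dynamics(sys, ff, cfg)
  t2 <- run_dynamics(sys, ff, cfg)
  expect_identical(t1$final_system$positions, t2$final_system$positions)
  cfg$seed <- 10L
  t3 <- run_dynamics(sys, ff, cfg)
  expect_false(identical(t1$final_system$positions,
                         t3$final_system$positions))
})

test_that("with zero friction the integrator conserves energy (NVE limit)", {
  # a single bonded three-site unit with soft springs: every pair is
  # excluded, so the motion is purely harmonic and dt resolves all modes
  ff <- force_field(k_bond_SO = 2, k_angle_OSO = 2)
  sys <- build_system(1, 1, box = 20, seed = 1,
                      geometry = monomer_geometry(q_plus = 0))
  set.seed(3)
  sys$positions <- sys$positions +
    matrix(stats::rnorm(length(sys$positions), 0, 0.05), ncol = 3)
  sys <- thermalize_velocities(sys, 1, seed = 4)
  cfg <- integrator_config(dt = 0.005, gamma = 0, n_steps = 2000,
                           save_every = 0, log_every = 20, seed = 1)
  traj <- run_dynamics(sys, ff, cfg)
  E <- traj$log$total + traj$log$kinetic
  expect_lt((max(E) - min(E)) / abs(E[1]), 1e-4)
})

test_that("thermostatted runs satisfy equipartition", {
  sys <- build_system(1, 20, density = 2e-3, seed = 5)
  cfg <- integrator_config(n_steps = 20000, save_every = 0,
                           log_every = 50, seed = 5)
  traj <- run_dynamics(sys, force_field(), cfg)
  temps <- traj$log$temperature
  temps <- temps[-seq_len(length(temps) %/% 3)]  # discard equilibration
  expect_equal(mean(temps), 1, tolerance = 0.03)
})

test_that("free-particle diffusion obeys the Einstein relation", {
  # independent single-monomer molecules, charges off: each 3-site
  # molecule diffuses with D = kT / (M gamma), M = 3
  g0 <- monomer_geometry(q_plus = 0)
  sys <- build_system(80, 1, density = 2e-4, seed = 6, geometry = g0)
  cfg <- integrator_config(dt = 0.005, gamma = 1, n_steps = 20000,
                           save_every = 2000, seed = 6)
  traj <- run_dynamics(sys, force_field(), cfg)
  t_frames <- traj$frame_steps * cfg$dt
  com <- function(f) {
    p <- traj$frames[[f]]
    t(sapply(seq_len(traj$n_chains), function(c)
      colMeans(p[traj$chain_id == c, , drop = FALSE])))
  }
  c0 <- com(1)
  msd <- sapply(seq_along(traj$frames), function(f)
    mean(rowSums((com(f) - c0)^2)))
  # late-time slope against 6 D t with D = kT/(3 gamma)
  late <- t_frames >= 20
  slope <- sum(msd[late] * t_frames[late]) / sum(t_frames[late]^2)
  expect_equal(slope, 6 * 1 / 3, tolerance = 0.12)
})

test_that("equilibrated bond lengths are centred on their rest length", {
  sys <- build_system(1, 20, density = 2e-3, seed = 7)
  cfg <- integrator_config(n_steps = 30000, save_every = 1000, seed = 7)
  ff <- force_field()
  traj <- run_dynamics(sys, ff, cfg)
  bb_len <- unlist(lapply(seq(10, n_frames(traj)), function(f) {
    bb <- backbone_positions(traj, f, 1)
    sqrt(rowSums(diff(bb)^2))
  }))
  expect_equal(mean(bb_len), ff$r0_backbone, tolerance = 0.02)
})

test_that("the dielectric schedule is applied per frame", {
  sys <- build_system(1, 4, box = 20, seed = 8)
  eps_vec <- rep(c(47, 60, 73.4), each = 100)
  cfg <- integrator_config(n_steps = 300, save_every = 100, seed = 8)
  traj <- run_dynamics(sys, force_field(), cfg, schedule = eps_vec)
  expect_equal(traj$frame_eps, c(47, 47, 60, 73.4))
})

test_that("annealing follows a linear temperature ramp", {
  sys <- build_system(1, 20, density = 2e-3, seed = 9)
  cfg <- integrator_config(n_steps = 40000, save_every = 0,
                           log_every = 50, seed = 9)
  traj <- anneal(sys, force_field(), cfg, kT_start = 2, kT_end = 1)
  lg <- traj$log[-1, ]
  ramp <- 2 - lg$step / 40000
  # windowed kinetic temperature tracks the ramp
  win <- cut(lg$step, 8)
  t_win <- tapply(lg$temperature, win, mean)
  r_win <- tapply(ramp, win, mean)
  expect_lt(max(abs(t_win - r_win) / r_win), 0.05)
  expect_gt(stats::cor(t_win, r_win, method = "spearman"), 0.9)
  # flat schedule behaves like a plain run at that temperature
  cfg2 <- integrator_config(n_steps = 300, save_every = 100, seed = 11)
  flat <- anneal(sys, force_field(), cfg2, kT_start = 1, kT_end = 1)
  plain <- run_dynamics(sys, force_field(), cfg2)
  expect_equal(flat$final_system$positions, plain$final_system$positions)
})

test_that("failed propagation returns a truncated trajectory with the step", {
  sys <- build_system(1, 3, box = 20, seed = 10)
  sys$velocities <- matrix(1e150, nrow(sys$positions), 3)
  cfg <- integrator_config(n_steps = 100, save_every = 10, gamma = 0,
                           seed = 1)
  traj <- run_dynamics(sys, force_field(), cfg)
  expect_false(traj$ok)
  expect_gte(traj$fail_step, 1)
  expect_lte(n_frames(traj), 11)
})
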