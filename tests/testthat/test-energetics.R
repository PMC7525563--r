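test_that("WCA potential matches its closed form and cutoff", {
  expect_equal(wca_energy(2^(1 / 6)), 0, tolerance = 1e-14)
  expect_equal(wca_energy(1.5), 0)
  expect_equal(wca_energy(1), 1)  # LJ vanishes at sigma, shift adds epsilon
  expect_equal(wca_energy(0.95), 4 * (0.95^-12 - 0.95^-6) + 1,
               tolerance = 1e-14)
  expect_equal(wca_energy(0.95), 2.9608, tolerance = 1e-3)
  # continuity at the cutoff
  expect_lt(wca_energy(2^(1 / 6) - 1e-8), 1e-6)
  expect_equal(wca_energy(0.5, epsilon = 3), 3 * wca_energy(0.5))
  expect_error(wca_energy(0), "r must be")
})

test_that("Coulomb pair energy is screened, truncated and unit-consistent", {
  ff47 <- force_field(dielectric_eps_r = 47)
  ff80 <- force_field(dielectric_eps_r = 80)
  expect_equal(coulomb_pair_energy(8.5, 1, 1, ff47), 0)
  expect_equal(coulomb_pair_energy(8, 1, 1, ff47),
               ff47$coulomb_prefactor / (47 * 8))
  # pure 1/eps_r scaling
  r <- 2
  expect_equal(coulomb_pair_energy(r, 1, -1, ff80),
               (47 / 80) * coulomb_pair_energy(r, 1, -1, ff47),
               tolerance = 1e-12)
  # independent SI evaluation: e^2/(4 pi eps0 eps_r r) / kT at 298 K
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  r_m <- 2 * 3.6e-10
  expected_kT <- e^2 / (4 * pi * eps0 * 47 * r_m) / (kB * 298)
  expect_equal(coulomb_pair_energy(2, 1, 1, ff47), expected_kT,
               tolerance = 1e-10)
  expect_error(coulomb_pair_energy(-1, 1, 1, ff47), "r must be")
})

test_that("harmonic bond and angle energies are exact and symmetric", {
  expect_equal(bond_energy(1, 10, 1), 0)
  expect_equal(bond_energy(1.2, 10, 1), 0.2, tolerance = 1e-14)
  expect_equal(bond_energy(0.8, 10, 1), bond_energy(1.2, 10, 1))
  expect_equal(angle_energy(119.3, 100, 119.3), 0)
  d <- 7.3
  expect_equal(angle_energy(119.3 + d, 100, 119.3),
               angle_energy(119.3 - d, 100, 119.3))
  expect_equal(angle_energy(90, 2, 0), 0.5 * 2 * (pi / 2)^2,
               tolerance = 1e-14)
  expect_error(bond_energy(1, -1, 1), "k must be")
  expect_error(angle_energy(200, 1, 90), "theta")
})

test_that("production energies and forces equal the brute-force oracle", {
  set.seed(1)
  for (k in 1:50) {
    sys <- jittered_system(n_chains = 2, N = 3, box = 18 + (k %% 3),
                           seed = k, noise = 0.08)
    ff <- force_field(dielectric_eps_r = c(47, 80, 20)[1 + k %% 3])
    ef <- energy_forces(sys, ff)
    bf <- brute_force_reference(sys, ff, use_cutoff = TRUE)
    for (term in c("wca", "coulomb", "bond", "angle", "total"))
      expect_lt(relerr(ef$energy[[term]], bf[[term]]), 1e-8)
  }
})

test_that("energy breakdown total is the sum of its terms", {
  sys <- jittered_system(2, 4, seed = 5)
  e <- energy_forces(sys, force_field())$energy
  expect_equal(e$total, e$wca + e$coulomb + e$bond + e$angle,
               tolerance = 1e-10)
})

test_that("forces are the negative gradient of the energy", {
  sys <- jittered_system(n_chains = 2, N = 3, seed = 11, noise = 0.1)
  ff <- force_field()
  ef <- energy_forces(sys, ff)
  set.seed(2)
  h <- 1e-5
  for (i in sample(nrow(sys$positions), 10)) {
    for (d in 1:3) {
      sp <- sys; sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- sys; sm$positions[i, d] <- sm$positions[i, d] - h
      fnum <- -(energy_forces(sp, ff)$energy$total -
                  energy_forces(sm, ff)$energy$total) / (2 * h)
      expect_lt(abs(fnum - ef$forces[i, d]) /
                  max(1, abs(ef$forces[i, d])), 1e-5)
    }
  }
})

test_that("energies are translation invariant and net force vanishes", {
  sys <- jittered_system(2, 4, seed = 21)
  ff <- force_field()
  e0 <- energy_forces(sys, ff)
  shift <- c(3.1, -7.4, 12.9)
  sys2 <- sys
  sys2$positions <- sweep(sys$positions, 2, -shift)
  e1 <- energy_forces(sys2, ff)
  for (term in c("wca", "coulomb", "bond", "angle"))
    expect_equal(e1$energy[[term]], e0$energy[[term]], tolerance = 1e-9)
  expect_lt(max(abs(colSums(e0$forces))), 1e-9)
})

test_that("two neutral excluded-volume sites at the WCA minimum feel no force", {
  g0 <- monomer_geometry(q_plus = 0)
  sys <- build_system(2, 1, box = 20, seed = 1, geometry = g0)
  # S sites exactly 2^(1/6) sigma apart along x, oxygens pointing away
  # so only the S-S excluded-volume pair is in range
  half <- g0$theta_OSO / 2 * pi / 180
  m1 <- rbind(c(0, 0, 0),
              g0$d_SO * c(-cos(half),  sin(half), 0),
              g0$d_SO * c(-cos(half), -sin(half), 0))
  m2 <- rbind(c(2^(1 / 6), 0, 0),
              c(2^(1 / 6), 0, 0) + g0$d_SO * c(cos(half),  sin(half), 0),
              c(2^(1 / 6), 0, 0) + g0$d_SO * c(cos(half), -sin(half), 0))
  sys$positions <- sweep(rbind(m1, m2), 2, -sys$box / 2)
  ef <- energy_forces(sys, force_field())
  expect_equal(ef$energy$wca, 0, tolerance = 1e-12)
  expect_lt(max(abs(ef$forces[c(1, 4), ])), 1e-8)
})

test_that("truncated Coulomb converges to the untruncated direct sum", {
  sys <- jittered_system(2, 4, box = 60, seed = 31)
  sys$periodic <- FALSE
  ref <- brute_force_reference(sys, force_field(), use_cutoff = FALSE)
  errs <- sapply(c(6, 10, 16, 30), function(rc) {
    e <- brute_force_reference(sys, force_field(r_cut_coulomb = rc),
                               use_cutoff = TRUE)
    abs(e$coulomb - ref$coulomb)
  })
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-10)
})

test_that("dielectric screening scales the Coulomb energy by 1/eps_r", {
  sys <- jittered_system(2, 4, seed = 41)
  e47 <- energy_forces(sys, force_field(dielectric_eps_r = 47))$energy
  e80 <- energy_forces(sys, force_field(dielectric_eps_r = 80))$energy
  expect_gt(abs(e47$coulomb), abs(e80$coulomb))
  expect_equal(e80$coulomb * 80, e47$coulomb * 47, tolerance = 1e-9)
})

test_that("undersized periodic boxes are rejected", {
  sys <- jittered_system(1, 3, box = 10, seed = 2)
  expect_error(energy_forces(sys, force_field()), "minimum-image")
})
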