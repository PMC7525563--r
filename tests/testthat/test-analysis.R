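test_that("dipole of the rigid three-site water fixture is 2.347 D", {
  w <- tip3p_water()
  expect_equal(dipole_moment(w$positions, w$charges), 2.347,
               tolerance = 5e-4)
})

test_that("dipole moments use the e-Angstrom/Debye conversion and symmetry", {
  # +1 e and -1 e separated by 1 Angstrom
  expect_equal(dipole_moment(rbind(c(0, 0, 0), c(1, 0, 0)), c(-1, 1)),
               4.80320, tolerance = 1e-12)
  # mirror-symmetric charges with coincident centroids
  pos <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(dipole_moment(pos, c(0.5, 0.5, -0.5, -0.5)), 0,
               tolerance = 1e-12)
  expect_error(dipole_moment(rbind(c(0, 0, 0)), 0.1), "neutral")
})

test_that("dipole moment is invariant under rigid transforms", {
  w <- tip3p_water()
  set.seed(4)
  for (k in 1:5) {
    R <- random_rotation()
    shifted <- w$positions %*% t(R) +
      matrix(stats::rnorm(3), 3, 3, byrow = TRUE)
    expect_equal(dipole_moment(shifted, w$charges), 2.347,
                 tolerance = 5e-4)
  }
})

test_that("dipolar pair energy has the point-dipole far field", {
  g <- monomer_geometry()
  u <- rbind(g$backbone_site_offset, g$oxygen_site_offsets)
  q <- c(g$q_plus, rep(g$q_minus_each, 2))
  mu_vec <- colSums(u * q)  # reduced units (e sigma), along -y
  eps_r <- 47
  C <- coulomb_coupling()
  # antiparallel side-by-side pair at contact is attractive
  flip <- u; flip[, 2] <- -flip[, 2]
  expect_lt(dipolar_pair_energy(u, q, sweep(flip, 2, c(1, 0, 0), "+"),
                                q, eps_r), 0)
  # zero-charge unit
  expect_equal(dipolar_pair_energy(u, 0 * q, u + 5, q, eps_r), 0)
  # far field: parallel dipoles displaced along x (perpendicular to mu)
  Rs <- c(8, 16, 32, 80)
  e_num <- sapply(Rs, function(R)
    dipolar_pair_energy(u, q, sweep(u, 2, c(R, 0, 0), "+"), q, eps_r))
  mu2 <- sum(mu_vec^2)
  e_ana <- C / eps_r * mu2 / Rs^3  # perpendicular parallel dipoles: +mu^2/R^3
  expect_lt(max(abs(e_num - e_ana) / abs(e_ana)), 0.05)
  slope <- stats::coef(stats::lm(log(abs(e_num)) ~ log(Rs)))[2]
  expect_equal(unname(slope), -3, tolerance = 0.1)
  expect_error(dipolar_pair_energy(u, q + 0.1, u + 5, q, eps_r), "neutral")
})

test_that("persistence length estimator recovers known decay constants", {
  for (c0 in c(0.5, 0.8, 0.9, 0.95)) {
    chains <- lapply(1:200, function(s)
      freely_rotating_chain(50, c0, seed = s))
    r <- persistence_length(chains, fit_range = 1:8, min_frames = 1)
    expect_lt(abs(r$L_p - (-1 / log(c0))) / (-1 / log(c0)), 0.05)
    expect_equal(r$mean_cos_curve[1], 1, tolerance = 1e-12)
  }
})

test_that("a perfectly straight chain reports an infinite persistence length", {
  straight <- cbind(0:30, 0, 0)
  r <- persistence_length(straight, min_frames = 1)
  expect_identical(r$L_p, Inf)
})

test_that("fully flexible chains fail the correlation fit informatively", {
  # freely jointed: correlations at s >= 1 vanish within noise
  set.seed(8)
  chains <- lapply(1:50, function(s) freely_rotating_chain(40, 0, seed = s))
  expect_error(persistence_length(chains, fit_range = 3:8, min_frames = 1,
                                  min_cos = 0.9),
               "non-positive")
})

test_that("end-to-end distance handles extended, single-monomer and wrapped chains", {
  ch <- build_chain(20, "extended")
  sys <- build_system(1, 20, box = 25, seed = 1)
  cfg <- integrator_config(n_steps = 0, save_every = 0)
  traj <- run_dynamics(sys, force_field(), cfg)
  expect_equal(end_to_end(traj)$mean, 19, tolerance = 1e-8)
  # wrap the chain across the boundary: distance must be unchanged
  traj_w <- traj
  traj_w$frames[[1]] <- wrap_positions(traj$frames[[1]] +
                                         matrix(c(20, 0, 0),
                                                nrow(traj$frames[[1]]), 3,
                                                byrow = TRUE), traj$box)
  expect_equal(end_to_end(traj_w)$mean, 19, tolerance = 1e-6)
  s1 <- build_system(1, 1, box = 25, seed = 1)
  t1 <- run_dynamics(s1, force_field(), cfg)
  expect_equal(end_to_end(t1)$mean, 0)
})

test_that("cluster analysis matches trivial cases and is label-invariant", {
  # one chain -> one cluster of size 1
  sys <- build_system(1, 3, box = 20, seed = 1)
  rep1 <- cluster_analysis(sys$positions, sys$box, sys$chain_id)
  expect_equal(rep1$sizes, 1L)
  # two chains farther apart than the cutoff -> two clusters
  pos <- rbind(build_chain(2)$positions,
               sweep(build_chain(2)$positions, 2, c(0, 5, 0), "+"))
  cid <- rep(1:2, each = 6)
  rep2 <- cluster_analysis(pos, box = c(40, 40, 40), chain_id = cid,
                           cutoff = 1.5)
  expect_equal(rep2$sizes, c(1L, 1L))
  expect_equal(rep2$largest_size, 1L)
  # touching chains -> one cluster
  pos[cid == 2, 2] <- pos[cid == 2, 2] - 4
  rep3 <- cluster_analysis(pos, box = c(40, 40, 40), chain_id = cid,
                           cutoff = 1.5)
  expect_equal(rep3$sizes, 2L)
  # chain relabelling leaves the size multiset stable
  ord <- c(which(cid == 2), which(cid == 1))
  rep4 <- cluster_analysis(pos[ord, ], box = c(40, 40, 40),
                           chain_id = cid[ord], cutoff = 1.5)
  expect_equal(rep4$sizes, rep3$sizes)
})

test_that("cluster partition equals the graph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:50) {
    n_chain <- 20
    box <- c(12, 12, 12)
    pos <- matrix(stats::runif(n_chain * 3) * box[1], ncol = 3)
    cid <- seq_len(n_chain)   # single-site chains
    cutoff <- stats::runif(1, 1, 3)
    mine <- cluster_analysis(pos, box, cid, cutoff = cutoff)
    # oracle: explicit adjacency + igraph components
    adj <- matrix(FALSE, n_chain, n_chain)
    for (i in 1:(n_chain - 1)) for (j in (i + 1):n_chain) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      adj[i, j] <- adj[j, i] <- sqrt(sum(d^2)) <= cutoff
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    # same partition: co-membership matrices identical
    expect_identical(outer(unname(mine$labels), unname(mine$labels), "=="),
                     outer(unname(comp), unname(comp), "=="))
  }
})

test_that("shape metrics reproduce isotropic, rod and tabulated cases", {
  ico <- shape_metrics(icosahedron_vertices())
  expect_lt(ico$kappa2, 1e-10)
  rod <- shape_metrics(cbind(seq(0, 10), 0, 0))
  expect_equal(rod$kappa2, 1, tolerance = 1e-10)
  # four tabulated points; eigenvalues computed independently beforehand
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  sm <- shape_metrics(pts)
  expect_equal(sm$eigenvalues, c(0.796535165, 0.25, 0.078464835),
               tolerance = 1e-8)
  expect_equal(sm$Rg^2, sum(diag(sm$gyration_tensor)), tolerance = 1e-12)
  expect_error(shape_metrics(rbind(c(0, 0, 0))), "at least 2")
})

test_that("shape metrics are invariant under rigid transforms", {
  set.seed(12)
  pts <- matrix(stats::rnorm(60), ncol = 3)
  ref <- shape_metrics(pts)
  for (k in 1:5) {
    R <- random_rotation()
    moved <- pts %*% t(R) + matrix(stats::rnorm(3), 20, 3, byrow = TRUE)
    got <- shape_metrics(moved)
    expect_equal(got$eigenvalues, ref$eigenvalues, tolerance = 1e-8)
    expect_equal(got$kappa2, ref$kappa2, tolerance = 1e-8)
  }
})

test_that("surface enrichment sees constructed segregation and the random null", {
  # all O- strictly outside all S+
  set.seed(5)
  n_in <- 40; n_out <- 60
  dir_in <- matrix(stats::rnorm(n_in * 3), ncol = 3)
  dir_in <- dir_in / sqrt(rowSums(dir_in^2))
  dir_out <- matrix(stats::rnorm(n_out * 3), ncol = 3)
  dir_out <- dir_out / sqrt(rowSums(dir_out^2))
  pos <- rbind(dir_in * stats::runif(n_in, 0, 1),
               dir_out * stats::runif(n_out, 3, 4))
  roles <- c(rep("S+", n_in), rep("O-", n_out))
  expect_equal(surface_enrichment(pos, roles, shell_fraction = 0.3), 1.0)
  # random labels in a ball: enrichment equals the global fraction 2/3
  set.seed(6)
  n <- 3000
  u <- matrix(stats::rnorm(n * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ball <- u * stats::runif(n)^(1 / 3)
  lab <- sample(c("O-", "S+"), n, replace = TRUE, prob = c(2 / 3, 1 / 3))
  expect_equal(surface_enrichment(ball, lab), 2 / 3, tolerance = 0.03)
  expect_error(surface_enrichment(matrix(0, 20, 3), rep("O-", 20)),
               "degenerate")
  expect_error(surface_enrichment(ball, lab, shell_fraction = 1.2),
               "shell_fraction")
})
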