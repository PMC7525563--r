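# shared fixtures: everything is generated in code, nothing is stored

# small multi-chain system with positions jittered off the perfect lattice
# (keeps pair distances away from the exact Coulomb cutoff boundary)
jittered_system <- function(n_chains = 2, N = 3, box = 20, seed = 1,
                            noise = 0.05) {
  sys <- build_system(n_chains, N, box = box, seed = seed)
  set.seed(seed + 10000)
  sys$positions <- sys$positions +
    matrix(stats::rnorm(length(sys$positions), 0, noise), ncol = 3)
  sys
}

# neutral version of a system (all charges zeroed) for bonded-only checks
uncharged <- function(sys) {
  sys$charge[] <- 0
  sys
}

relerr <- function(a, b) abs(a - b) / max(1e-12, abs(b))

# unit icosahedron vertices (isotropic point set, kappa^2 = 0)
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
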