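#' Three-site geometry of a coarse-grained sulfone monomer
#'
#' Each monomer is a charge-neutral unit of three point charges: one
#' positive backbone site (the S atom plus its neighbouring backbone
#' carbons) and two negative oxygen sites.  The unit carries a net dipole
#' along the O-S-O bisector.  Offsets are expressed in the local monomer
#' frame, in sigma units: the backbone site at the origin, the bisector
#' along +y and the two oxygens split symmetrically along +/-x.
#'
#' @param d_SO S-O site distance in sigma units (default 1.43 A / 3.6 A).
#' @param theta_OSO O-S-O angle in degrees (default 119.3).
#' @param q_plus charge on the backbone site in elementary charges; each
#'   oxygen carries `-q_plus/2` so the unit is exactly neutral.  The
#'   default reproduces a net monomer dipole of 6.534 D.
#' @param sigma_angstrom physical size of sigma, used for Debye conversion.
#' @return An object of class `monomer_geometry`.
#' @seealso [calibrate_monomer_charge()], [dipole_moment()]
#' @export
monomer_geometry <- function(d_SO = 1.43 / SIGMA_ANGSTROM,
                             theta_OSO = 119.3,
                             q_plus = NULL,
                             sigma_angstrom = SIGMA_ANGSTROM) {
  if (!is.numeric(d_SO) || length(d_SO) != 1 || d_SO <= 0)
    stop("d_SO must be a positive length", call. = FALSE)
  if (!is.numeric(theta_OSO) || theta_OSO <= 0 || theta_OSO >= 180)
    stop("theta_OSO must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  if (is.null(q_plus))
    q_plus <- calibrate_monomer_charge(6.534,
                                       d_SO_angstrom = d_SO * sigma_angstrom,
                                       theta_OSO = theta_OSO)
  half <- theta_OSO / 2 * pi / 180
  s  <- c(0, 0, 0)
  o1 <- c( d_SO * sin(half), d_SO * cos(half), 0)
  o2 <- c(-d_SO * sin(half), d_SO * cos(half), 0)
  structure(list(
    backbone_site_offset = s,
    oxygen_site_offsets  = rbind(o1, o2, deparse.level = 0),
    q_plus        = q_plus,
    q_minus_each  = -q_plus / 2,
    d_SO          = d_SO,
    theta_OSO     = theta_OSO,
    sigma_angstrom = sigma_angstrom
  ), class = "monomer_geometry")
}

#' @export
print.monomer_geometry <- function(x, ...) {
  cat("CG sulfone monomer geometry\n")
  cat(sprintf("  d_SO      : %.4f sigma (%.3f A)\n",
              x$d_SO, x$d_SO * x$sigma_angstrom))
  cat(sprintf("  theta_OSO : %.2f deg\n", x$theta_OSO))
  cat(sprintf("  charges   : S+ %+0.4f e, O- %+0.4f e each\n",
              x$q_plus, x$q_minus_each))
  cat(sprintf("  net dipole: %.4f D\n", geometry_dipole_debye(x)))
  invisible(x)
}

#' Net dipole moment of a monomer geometry, in Debye
#'
#' Closed-form evaluation on the explicit sites via [dipole_moment()].
#'
#' @param geom a [monomer_geometry()] object.
#' @return dipole magnitude in Debye.
#' @export
geometry_dipole_debye <- function(geom) {
  stopifnot(inherits(geom, "monomer_geometry"))
  pos_A <- rbind(geom$backbone_site_offset, geom$oxygen_site_offsets) *
    geom$sigma_angstrom
  q <- c(geom$q_plus, geom$q_minus_each, geom$q_minus_each)
  dipole_moment(pos_A, q)
}

#' Calibrate the monomer charge against a target dipole moment
#'
#' Inverts the closed-form point-charge dipole of the three-site unit,
#' \eqn{\mu = q\, d_{SO} \cos(\theta/2)} (in e Angstrom, converted to
#' Debye), so that the returned backbone charge reproduces `target_dipole`
#' exactly when re-evaluated on the explicit sites.  The default target of
#' 6.534 D is the all-atom dipole moment of the sulfone unit.
#'
#' @param target_dipole target net dipole in Debye (>= 0).
#' @param d_SO_angstrom S-O distance in Angstrom (default 1.43).
#' @param theta_OSO O-S-O angle in degrees.
#' @return backbone charge `q_plus` in elementary charges.
#' @export
calibrate_monomer_charge <- function(target_dipole = 6.534,
                                     d_SO_angstrom = 1.43,
                                     theta_OSO = 119.3) {
  if (!is.numeric(target_dipole) || target_dipole < 0)
    stop("target_dipole must be >= 0", call. = FALSE)
  proj <- d_SO_angstrom * cos(theta_OSO / 2 * pi / 180)
  if (!is.finite(proj) || abs(proj) < 1e-12)
    stop("degenerate geometry: zero bisector projection, cannot calibrate",
         call. = FALSE)
  target_dipole / (DEBYE_PER_E_ANGSTROM * proj)
}

#' Force field for the coarse-grained sulfone homopolymer
#'
#' Collects every interaction parameter in reduced units (length sigma,
#' energy kT, charge e).  Excluded volume is the Weeks-Chandler-Andersen
#' potential; backbone sites have diameter `sigma`, oxygen sites a smaller
#' core `sigma_o` (arithmetic mixing) that prevents point-charge fusion.
#' Electrostatics is a sharply truncated Coulomb sum screened by the
#' uniform solvent dielectric `dielectric_eps_r` (47 for DMSO, 80 for
#' water); the absolute coupling comes from the Bjerrum length at 298 K
#' with sigma = 3.6 A.  `k_bend_backbone` is the chain-stiffness knob; the
#' default is the package's persistence-length calibration at eps_r = 47
#' (see [calibrate_stiffness()]).
#'
#' @param dielectric_eps_r relative solvent permittivity (> 0).
#' @param k_bend_backbone backbone bending constant, kT/rad^2 (>= 0).
#' @param sigma,epsilon_wca WCA diameter and well depth of backbone sites.
#' @param sigma_o WCA diameter of oxygen sites.
#' @param k_bond_SO,r0_SO S-O spring constant (kT/sigma^2) and rest length.
#' @param k_angle_OSO,theta0_OSO O-S-O angle spring (kT/rad^2) and rest
#'   angle in degrees.
#' @param k_bond_backbone,r0_backbone backbone spring and rest length.
#' @param r_cut_coulomb sharp Coulomb cutoff in sigma (default 8).
#' @param temperature_kT thermostat temperature in reduced units.
#' @param sigma_angstrom physical sigma used in the Bjerrum conversion.
#' @return An object of class `cg_forcefield`.
#' @export
force_field <- function(dielectric_eps_r = 47,
                        k_bend_backbone = CALIBRATED_K_BEND,
                        sigma = 1, epsilon_wca = 1, sigma_o = 0.35,
                        k_bond_SO = 1000, r0_SO = 1.43 / SIGMA_ANGSTROM,
                        k_angle_OSO = 100, theta0_OSO = 119.3,
                        k_bond_backbone = 1000, r0_backbone = 1.0,
                        r_cut_coulomb = 8,
                        temperature_kT = 1,
                        sigma_angstrom = SIGMA_ANGSTROM) {
  if (dielectric_eps_r <= 0) stop("dielectric_eps_r must be > 0", call. = FALSE)
  ks <- c(k_bond_SO, k_angle_OSO, k_bond_backbone, k_bend_backbone)
  if (any(ks < 0)) stop("spring constants must be >= 0", call. = FALSE)
  if (r_cut_coulomb <= 2^(1 / 6) * sigma)
    stop("r_cut_coulomb must exceed the WCA cutoff 2^(1/6)*sigma",
         call. = FALSE)
  if (temperature_kT <= 0) stop("temperature_kT must be > 0", call. = FALSE)
  structure(list(
    sigma = sigma, epsilon_wca = epsilon_wca, sigma_o = sigma_o,
    k_bond_SO = k_bond_SO, r0_SO = r0_SO,
    k_angle_OSO = k_angle_OSO, theta0_OSO = theta0_OSO,
    k_bond_backbone = k_bond_backbone, r0_backbone = r0_backbone,
    k_bend_backbone = k_bend_backbone,
    dielectric_eps_r = dielectric_eps_r,
    r_cut_coulomb = r_cut_coulomb,
    coulomb_prefactor = coulomb_coupling(sigma_angstrom),
    temperature_kT = temperature_kT,
    sigma_angstrom = sigma_angstrom
  ), class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("CG force field (reduced units)\n")
  cat(sprintf("  eps_r = %g, r_cut = %g sigma, Coulomb coupling %.3f\n",
              x$dielectric_eps_r, x$r_cut_coulomb, x$coulomb_prefactor))
  cat(sprintf("  WCA: sigma %g (S), %g (O), epsilon %g\n",
              x$sigma, x$sigma_o, x$epsilon_wca))
  cat(sprintf("  bonds: S-O k=%g r0=%.4g; backbone k=%g r0=%g\n",
              x$k_bond_SO, x$r0_SO, x$k_bond_backbone, x$r0_backbone))
  cat(sprintf("  angles: O-S-O k=%g theta0=%g deg; bend k=%g\n",
              x$k_angle_OSO, x$theta0_OSO, x$k_bend_backbone))
  invisible(x)
}

#' Topology of one linear chain of three-site monomers
#'
#' Sites are ordered monomer by monomer as (S, O1, O2).  A chain of `N`
#' monomers has `3N` sites, `2N` S-O bonds, `N-1` backbone bonds, `N`
#' O-S-O angles and `N-2` backbone bending angles.
#'
#' @param N number of monomers (>= 1).
#' @param chain_id integer chain label attached to every site.
#' @return list with `site_role` (character, "S+" / "O-"), `monomer_id`,
#'   `chain_id`, `bonds` (data.frame i, j, kind) and `angles` (data.frame
#'   i, j, k, kind); indices are 1-based.
#' @export
chain_topology <- function(N, chain_id = 1L) {
  if (!is.numeric(N) || N < 1 || N != round(N))
    stop("N must be a positive integer", call. = FALSE)
  N <- as.integer(N)
  s_of <- function(i) 3L * (i - 1L) + 1L
  site_role  <- rep(c("S+", "O-", "O-"), N)
  monomer_id <- rep(seq_len(N), each = 3L)
  bonds <- rbind(
    data.frame(i = s_of(seq_len(N)), j = s_of(seq_len(N)) + 1L, kind = "SO"),
    data.frame(i = s_of(seq_len(N)), j = s_of(seq_len(N)) + 2L, kind = "SO"),
    if (N > 1) data.frame(i = s_of(seq_len(N - 1L)),
                          j = s_of(seq_len(N - 1L) + 1L), kind = "backbone")
  )
  angles <- rbind(
    data.frame(i = s_of(seq_len(N)) + 1L, j = s_of(seq_len(N)),
               k = s_of(seq_len(N)) + 2L, kind = "OSO"),
    if (N > 2) data.frame(i = s_of(seq_len(N - 2L)),
                          j = s_of(seq_len(N - 2L) + 1L),
                          k = s_of(seq_len(N - 2L) + 2L),
                          kind = "backbone_bend")
  )
  list(site_role = site_role, monomer_id = monomer_id,
       chain_id = rep(as.integer(chain_id), 3L * N),
       bonds = bonds, angles = angles, n_monomers = N)
}

## orientation frame for monomer i of a chain with backbone tangent t:
## bisector u alternates sign monomer to monomer (zigzag trans-planar
## arrangement); oxygens split along w = t x u.
.monomer_site_positions <- function(s_pos, tangent, flip, geom) {
  t_hat <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t_hat[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- ref - sum(ref * t_hat) * t_hat
  u <- u / sqrt(sum(u^2)) * flip
  w <- c(t_hat[2] * u[3] - t_hat[3] * u[2],
         t_hat[3] * u[1] - t_hat[1] * u[3],
         t_hat[1] * u[2] - t_hat[2] * u[1])
  half <- geom$theta_OSO / 2 * pi / 180
  o1 <- s_pos + geom$d_SO * (cos(half) * u + sin(half) * w)
  o2 <- s_pos + geom$d_SO * (cos(half) * u - sin(half) * w)
  rbind(s_pos, o1, o2, deparse.level = 0)
}

.chain_positions_from_backbone <- function(bb, geom) {
  N <- nrow(bb)
  pos <- matrix(0, 3 * N, 3)
  for (i in seq_len(N)) {
    tangent <-
      if (N == 1) c(1, 0, 0)
      else if (i == 1) bb[2, ] - bb[1, ]
      else if (i == N) bb[N, ] - bb[N - 1, ]
      else bb[i + 1, ] - bb[i - 1, ]
    pos[(3 * i - 2):(3 * i), ] <-
      .monomer_site_positions(bb[i, ], tangent, (-1)^(i - 1), geom)
  }
  pos
}

#' Build one chain with explicit site positions
#'
#' The backbone is either fully extended along x or a self-avoiding random
#' walk with fixed step `r0_backbone`; oxygen sites are placed in the plane
#' perpendicular to the local backbone tangent with the bisector direction
#' alternating monomer to monomer (zigzag convention).
#'
#' @param N number of monomers.
#' @param conformation `"extended"` or `"random_walk"`.
#' @param seed RNG seed for the random walk (ignored for extended chains).
#' @param geometry a [monomer_geometry()].
#' @param r0_backbone backbone bond rest length in sigma.
#' @param min_dist self-avoidance threshold between non-bonded backbone
#'   sites, in sigma.
#' @param max_retries restarts allowed before the walk is declared failed.
#' @return list with `topology` (see [chain_topology()]) and `positions`
#'   (3N x 3 matrix, sigma units).
#' @export
build_chain <- function(N, conformation = c("extended", "random_walk"),
                        seed = 1L, geometry = monomer_geometry(),
                        r0_backbone = 1.0, min_dist = 0.9,
                        max_retries = 200L) {
  conformation <- match.arg(conformation)
  topo <- chain_topology(N)
  N <- topo$n_monomers
  if (conformation == "extended" || N <= 2) {
    bb <- cbind((seq_len(N) - 1) * r0_backbone, 0, 0)
  } else {
    rng <- .make_rng(seed)
    bb <- NULL
    for (try in seq_len(max_retries)) {
      cand <- matrix(0, N, 3)
      cand[2, ] <- c(r0_backbone, 0, 0)
      ok <- TRUE
      for (i in seq(3, N)) {
        placed <- FALSE
        for (att in seq_len(50L)) {
          step <- .rng_unit_vector(rng)
          p <- cand[i - 1, ] + r0_backbone * step
          d2 <- rowSums((cand[seq_len(i - 2), , drop = FALSE] -
                           matrix(p, i - 2, 3, byrow = TRUE))^2)
          if (all(d2 >= min_dist^2)) {
            cand[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { bb <- cand; break }
    }
    if (is.null(bb))
      stop(sprintf(
        "self-avoiding walk failed after %d retries (N = %d, seed = %d)",
        max_retries, N, seed), call. = FALSE)
  }
  list(topology = topo,
       positions = .chain_positions_from_backbone(bb, geometry))
}

## internal deterministic RNG wrapper: isolates package RNG use from the
## global .Random.seed
.make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  env
}

.with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

.rng_unit_vector <- function(rng) {
  v <- .with_rng(rng, stats::rnorm(3))
  v / sqrt(sum(v^2))
}

#' Assemble a periodic multi-chain system
#'
#' Chains are placed on a cubic sub-lattice (`packing = "lattice"`) or at
#' uniform random positions (`packing = "random"`) with random rigid
#' orientations, rejecting placements that bring any two sites of
#' different chains closer than `min_dist` under the minimum-image
#' convention.  The box is cubic, either given explicitly or sized so the
#' monomer number density equals `density`.
#'
#' @param n_chains number of chains.
#' @param N monomers per chain.
#' @param box cubic box edge in sigma, or `NULL` to derive from `density`.
#' @param density monomer number density in sigma^-3 (used when `box` is
#'   `NULL`).
#' @param packing `"lattice"` or `"random"`.
#' @param conformation initial chain conformation, see [build_chain()].
#' @param seed RNG seed; the same seed reproduces the system exactly.
#' @param geometry a [monomer_geometry()].
#' @param r0_backbone backbone rest length.
#' @param min_dist minimum allowed inter-chain site distance, sigma.
#' @param max_retries placement attempts per chain before failure.
#' @return An object of class `cg_system` with positions, zero velocities,
#'   box, per-site metadata (role, charge, chain and monomer ids) and the
#'   bond/angle lists.
#' @export
build_system <- function(n_chains, N, box = NULL, density = 2e-3,
                         packing = c("lattice", "random"),
                         conformation = c("extended", "random_walk"),
                         seed = 1L, geometry = monomer_geometry(),
                         r0_backbone = 1.0, min_dist = 0.9,
                         max_retries = 500L) {
  packing <- match.arg(packing)
  conformation <- match.arg(conformation)
  if (n_chains < 1 || n_chains != round(n_chains))
    stop("n_chains must be a positive integer", call. = FALSE)
  if (is.null(box)) box <- (n_chains * N / density)^(1 / 3)
  box <- rep(as.numeric(box), length.out = 3)
  rng <- .make_rng(seed)

  role <- character(0); mono <- integer(0); chain <- integer(0)
  bonds <- NULL; angles <- NULL
  pos <- NULL
  n_cell <- ceiling(n_chains^(1 / 3))
  cell <- box / n_cell
  lat_pts <- as.matrix(expand.grid(seq_len(n_cell), seq_len(n_cell),
                                   seq_len(n_cell)))[seq_len(n_chains), ,
                                                     drop = FALSE]
  for (c_id in seq_len(n_chains)) {
    ch <- build_chain(N, conformation,
                      seed = .with_rng(rng, sample.int(2^30, 1)),
                      geometry = geometry, r0_backbone = r0_backbone)
    p0 <- sweep(ch$positions, 2, colMeans(ch$positions))
    placed <- FALSE
    for (att in seq_len(max_retries)) {
      R <- .rng_rotation(rng)
      centre <- if (n_chains == 1) box / 2
        else if (packing == "lattice")
          (lat_pts[c_id, ] - 0.5) * cell +
            .with_rng(rng, stats::runif(3, -0.1, 0.1)) * cell
        else .with_rng(rng, stats::runif(3)) * box
      p <- p0 %*% t(R) + matrix(centre, nrow(p0), 3, byrow = TRUE)
      if (is.null(pos) || .min_image_ok(p, pos, box, min_dist)) {
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place chain %d without overlap (density too high?)",
                   c_id), call. = FALSE)
    pos <- rbind(pos, p)
    topo <- ch$topology
    off <- 3L * N * (c_id - 1L)
    role  <- c(role, topo$site_role)
    mono  <- c(mono, topo$monomer_id)
    chain <- c(chain, rep(c_id, 3L * N))
    b <- topo$bonds;  b$i <- b$i + off; b$j <- b$j + off
    a <- topo$angles; a$i <- a$i + off; a$j <- a$j + off; a$k <- a$k + off
    bonds <- rbind(bonds, b); angles <- rbind(angles, a)
  }
  charge <- ifelse(role == "S+", geometry$q_plus, geometry$q_minus_each)
  structure(list(
    positions = pos,
    velocities = matrix(0, nrow(pos), 3),
    box = box, periodic = TRUE,
    site_role = role, monomer_id = mono, chain_id = chain,
    charge = charge, bonds = bonds, angles = angles,
    n_chains = as.integer(n_chains), N = as.integer(N),
    geometry = geometry, rng_seed = as.integer(seed)
  ), class = "cg_system")
}

.rng_rotation <- function(rng) {
  ## uniform random rotation from a normalized quaternion
  q <- .with_rng(rng, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.min_image_ok <- function(new_pos, old_pos, box, min_dist) {
  for (i in seq_len(nrow(new_pos))) {
    d <- old_pos - matrix(new_pos[i, ], nrow(old_pos), 3, byrow = TRUE)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    if (any(rowSums(d^2) < min_dist^2)) return(FALSE)
  }
  TRUE
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("CG system: %d chain(s) x %d monomers = %d sites\n",
              x$n_chains, x$N, nrow(x$positions)))
  cat(sprintf("  box %.2f x %.2f x %.2f sigma (periodic), net charge %.3g e\n",
              x$box[1], x$box[2], x$box[3], sum(x$charge)))
  invisible(x)
}

#' Total charge of a system (exactly zero for neutral monomers)
#' @param system a `cg_system`.
#' @return net charge in e.
#' @export
total_charge <- function(system) sum(system$charge)
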