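#' Weeks-Chandler-Andersen pair energy
#'
#' The Lennard-Jones potential truncated and shifted to zero at its
#' minimum \eqn{2^{1/6}\sigma}, leaving a purely repulsive excluded-volume
#' core: \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond.
#'
#' @param r pair distance (> 0), sigma units; vectorized.
#' @param epsilon well depth (reduced energy).
#' @param sigma pair diameter.
#' @return energy in reduced units.
#' @export
wca_energy <- function(r, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  sr6 <- (sigma / r)^6
  ifelse(r < 2^(1 / 6) * sigma, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0)
}

#' Sharply truncated Coulomb pair energy
#'
#' \eqn{C q_i q_j / (\varepsilon_r r)} for \eqn{r \le r_c}, exactly zero
#' beyond the cutoff; `C` is the force field's reduced Coulomb coupling
#' (vacuum Bjerrum length in sigma units).
#'
#' @param r pair distance (> 0), sigma units; vectorized.
#' @param qi,qj charges in e.
#' @param ff a [force_field()] providing `coulomb_prefactor`,
#'   `dielectric_eps_r` and `r_cut_coulomb`.
#' @return energy in reduced units.
#' @export
coulomb_pair_energy <- function(r, qi, qj, ff) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  e <- ff$coulomb_prefactor * qi * qj / (ff$dielectric_eps_r * r)
  ifelse(r <= ff$r_cut_coulomb, e, 0)
}

#' Harmonic bond and angle energies
#'
#' @param r bond length (> 0); `theta` angle in degrees in `[0, 180]`.
#' @param k spring constant (>= 0), energy/sigma^2 for bonds and
#'   energy/rad^2 for angles.
#' @param r0,theta0 rest length / rest angle (degrees).
#' @return energy in reduced units; angles are converted to radians
#'   internally.
#' @export
bond_energy <- function(r, k, r0) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  0.5 * k * (r - r0)^2
}

#' @rdname bond_energy
#' @param theta angle in degrees.
#' @export
angle_energy <- function(theta, k, theta0) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  if (any(theta < 0 | theta > 180))
    stop("theta must lie in [0, 180] degrees", call. = FALSE)
  0.5 * k * ((theta - theta0) * pi / 180)^2
}

.energy_breakdown <- function(wca, coulomb, bond, angle) {
  structure(list(wca = wca, coulomb = coulomb, bond = bond, angle = angle,
                 total = wca + coulomb + bond + angle),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "energy breakdown (kT): wca %.6g  coulomb %.6g  bond %.6g  angle %.6g  total %.6g\n",
    x$wca, x$coulomb, x$bond, x$angle, x$total))
  invisible(x)
}

.bond_kind_int <- function(kind) ifelse(kind == "SO", 0L, 1L)
.angle_kind_int <- function(kind) ifelse(kind == "OSO", 0L, 1L)

.system_meta <- function(system) {
  list(chain = as.integer(system$chain_id),
       mono = as.integer(system$monomer_id),
       isS = as.integer(system$site_role == "S+"),
       charge = as.numeric(system$charge),
       bonds = cbind(as.integer(system$bonds$i), as.integer(system$bonds$j),
                     .bond_kind_int(system$bonds$kind)),
       angles = cbind(as.integer(system$angles$i),
                      as.integer(system$angles$j),
                      as.integer(system$angles$k),
                      .angle_kind_int(system$angles$kind)))
}

.check_box <- function(system, ff) {
  if (isTRUE(system$periodic) && any(system$box < 2 * ff$r_cut_coulomb))
    stop(sprintf(
      "box (%.3g) smaller than 2*r_cut_coulomb (%.3g): minimum-image violation",
      min(system$box), 2 * ff$r_cut_coulomb), call. = FALSE)
}

#' Total energy and forces of a system
#'
#' Evaluates the full Hamiltonian: WCA excluded volume and truncated
#' Coulomb over all non-excluded site pairs (minimum image in periodic
#' boxes), plus harmonic S-O bonds, backbone bonds, O-S-O angles and
#' backbone bending.  Excluded pairs are the directly bonded ones (S-O
#' within a monomer, backbone S-S neighbours) and the two oxygens of the
#' same monomer; all other pairs interact.  Forces are the exact negative
#' gradient of the total energy.
#'
#' @param system a `cg_system`.
#' @param ff a [force_field()].
#' @return list with `energy` (an `energy_breakdown`) and `forces`
#'   (n_sites x 3 matrix).
#' @export
energy_forces <- function(system, ff) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "cg_forcefield"))
  .check_box(system, ff)
  m <- .system_meta(system)
  res <- cpp_energy_forces(system$positions, system$box,
                           isTRUE(system$periodic), m$chain, m$mono, m$isS,
                           m$charge, m$bonds, m$angles, unclass(ff))
  list(energy = .energy_breakdown(res$wca, res$coulomb, res$bond, res$angle),
       forces = res$forces)
}

#' Brute-force reference energies (oracle)
#'
#' Independent O(n^2) double-loop evaluation in plain R, intended for
#' systems of at most a few hundred sites.  With `use_cutoff = TRUE` the
#' pair selection matches the production path exactly; with
#' `use_cutoff = FALSE` the Coulomb sum is untruncated and stands in for a
#' long-range (Ewald-type) cross-check.
#'
#' @param system a `cg_system`.
#' @param ff a [force_field()].
#' @param use_cutoff apply the sharp Coulomb cutoff (default `TRUE`).
#' @return an `energy_breakdown`.
#' @export
brute_force_reference <- function(system, ff, use_cutoff = TRUE) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "cg_forcefield"))
  pos <- system$positions
  n <- nrow(pos)
  box <- system$box
  periodic <- isTRUE(system$periodic)
  role <- system$site_role
  qv <- system$charge
  chain <- system$chain_id
  mono <- system$monomer_id
  wca <- 0; coul <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (chain[i] == chain[j] &&
            (mono[i] == mono[j] ||
             (role[i] == "S+" && role[j] == "S+" &&
              abs(mono[i] - mono[j]) == 1))) next
        d <- pos[i, ] - pos[j, ]
        if (periodic) d <- d - box * round(d / box)
        r <- sqrt(sum(d^2))
        sig <- if (role[i] == "S+" && role[j] == "S+") ff$sigma
          else if (role[i] == "O-" && role[j] == "O-") ff$sigma_o
          else (ff$sigma + ff$sigma_o) / 2
        if (r < 2^(1 / 6) * sig)
          wca <- wca + wca_energy(r, ff$epsilon_wca, sig)
        if (qv[i] != 0 && qv[j] != 0 && (!use_cutoff || r <= ff$r_cut_coulomb))
          coul <- coul + ff$coulomb_prefactor * qv[i] * qv[j] /
            (ff$dielectric_eps_r * r)
      }
    }
  }
  bond <- 0
  for (b in seq_len(nrow(system$bonds))) {
    i <- system$bonds$i[b]; j <- system$bonds$j[b]
    d <- pos[i, ] - pos[j, ]
    if (periodic) d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (system$bonds$kind[b] == "SO")
      bond <- bond + bond_energy(r, ff$k_bond_SO, ff$r0_SO)
    else
      bond <- bond + bond_energy(r, ff$k_bond_backbone, ff$r0_backbone)
  }
  ang <- 0
  for (a in seq_len(nrow(system$angles))) {
    i <- system$angles$i[a]; j <- system$angles$j[a]; k <- system$angles$k[a]
    va <- pos[i, ] - pos[j, ]; vb <- pos[k, ] - pos[j, ]
    if (periodic) {
      va <- va - box * round(va / box)
      vb <- vb - box * round(vb / box)
    }
    cth <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    th <- acos(max(-1, min(1, cth))) * 180 / pi
    if (system$angles$kind[a] == "OSO")
      ang <- ang + angle_energy(th, ff$k_angle_OSO, ff$theta0_OSO)
    else
      ang <- ang + angle_energy(th, ff$k_bend_backbone, 180)
  }
  .energy_breakdown(wca, coul, bond, ang)
}
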