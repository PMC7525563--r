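#' Dipole moment of a charge-neutral unit
#'
#' \eqn{|\sum_i q_i r_i|} for a set of point charges summing to zero,
#' converted to Debye via 1 e Angstrom = 4.80320 D.  The dipole of a
#' non-neutral unit is origin-dependent and is rejected.
#'
#' @param positions_angstrom n x 3 matrix of site positions in Angstrom.
#' @param charges site charges in e; must sum to zero within 1e-9.
#' @return dipole magnitude in Debye.
#' @examples
#' w <- tip3p_water()
#' dipole_moment(w$positions, w$charges)  # 2.347 D
#' @export
dipole_moment <- function(positions_angstrom, charges) {
  positions_angstrom <- as.matrix(positions_angstrom)
  if (nrow(positions_angstrom) != length(charges))
    stop("positions and charges disagree in length", call. = FALSE)
  net <- sum(charges)
  if (abs(net) > 1e-9)
    stop(sprintf("unit is not charge neutral (net charge %.3g e)", net),
         call. = FALSE)
  mu <- colSums(positions_angstrom * charges)
  sqrt(sum(mu^2)) * DEBYE_PER_E_ANGSTROM
}

#' Rigid three-site TIP3P water fixture
#'
#' CHARMM TIP3P geometry: O at the origin, O-H bond length 0.9572 Angstrom,
#' H-O-H angle 104.52 degrees; charges O -0.834 e, H +0.417 e.
#'
#' @return list with `positions` (3 x 3 matrix, Angstrom) and `charges`.
#' @export
tip3p_water <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  pos <- rbind(c(0, 0, 0),
               c(r_oh * sin(half),  r_oh * cos(half), 0),
               c(-r_oh * sin(half), r_oh * cos(half), 0))
  list(positions = pos, charges = c(-0.834, 0.417, 0.417))
}

#' Dipolar interaction energy between two charge-neutral units
#'
#' Untruncated Coulomb sum over all cross pairs of the two units,
#' \eqn{\sum_{i \in A, j \in B} C q_i q_j / (\varepsilon_r r_{ij})}, in
#' reduced energy units (positions in sigma, charges in e).  In the far
#' field this reduces to the ideal point-dipole interaction with its
#' \eqn{1/R^3} decay.
#'
#' @param pos_a,pos_b site positions of units A and B (sigma units).
#' @param q_a,q_b site charges (e); each unit must be neutral within 1e-9.
#' @param eps_r relative permittivity.
#' @param coupling reduced Coulomb coupling (default [coulomb_coupling()]).
#' @return pair energy in kT.
#' @export
dipolar_pair_energy <- function(pos_a, q_a, pos_b, q_b, eps_r,
                                coupling = coulomb_coupling()) {
  pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
  for (q in list(A = q_a, B = q_b))
    if (abs(sum(q)) > 1e-9)
      stop(sprintf("unit is not charge neutral (net charge %.3g e)", sum(q)),
           call. = FALSE)
  e <- 0
  for (i in seq_len(nrow(pos_a))) {
    d <- sweep(pos_b, 2, pos_a[i, ])
    r <- sqrt(rowSums(d^2))
    if (any(r == 0)) stop("overlapping sites between units", call. = FALSE)
    e <- e + sum(coupling * q_a[i] * q_b / (eps_r * r))
  }
  e
}

## bond-walk unwrap: every site is placed in the periodic image nearest to
## its parent (O sites -> own S; S of monomer i -> S of monomer i-1)
#' Unwrap chains across periodic boundaries
#'
#' @param positions n x 3 matrix (any image).
#' @param box edge lengths.
#' @param chain_id,monomer_id,site_role per-site metadata as in
#'   `cg_system`.
#' @return n x 3 matrix with every chain made whole.
#' @export
unwrap_chains <- function(positions, box, chain_id, monomer_id, site_role) {
  out <- as.matrix(positions)
  for (c_id in unique(chain_id)) {
    idx <- which(chain_id == c_id)
    s_idx <- idx[site_role[idx] == "S+"]
    s_idx <- s_idx[order(monomer_id[s_idx])]
    for (k in seq_along(s_idx)) {
      if (k > 1) {
        d <- out[s_idx[k], ] - out[s_idx[k - 1], ]
        out[s_idx[k], ] <- out[s_idx[k], ] - box * round(d / box)
      }
      mono <- monomer_id[s_idx[k]]
      o_idx <- idx[site_role[idx] == "O-" & monomer_id[idx] == mono]
      for (o in o_idx) {
        d <- out[o, ] - out[s_idx[k], ]
        out[o, ] <- out[o, ] - box * round(d / box)
      }
    }
  }
  out
}

.traj_frame_meta <- function(traj) {
  list(chain_id = traj$chain_id, monomer_id = traj$monomer_id,
       site_role = traj$site_role, box = traj$box)
}

#' Backbone site positions of one chain in one frame
#'
#' @param traj a `cg_trajectory`.
#' @param frame frame index (1-based).
#' @param chain chain id.
#' @param unwrap make the chain whole across periodic boundaries first.
#' @return N x 3 matrix of backbone (S+) positions.
#' @export
backbone_positions <- function(traj, frame, chain, unwrap = TRUE) {
  pos <- traj$frames[[frame]]
  m <- .traj_frame_meta(traj)
  if (unwrap)
    pos <- unwrap_chains(pos, m$box, m$chain_id, m$monomer_id, m$site_role)
  idx <- which(m$chain_id == chain & m$site_role == "S+")
  pos[idx[order(m$monomer_id[idx])], , drop = FALSE]
}

#' Backbone end-to-end distance
#'
#' Per-frame, per-chain distance between the first and last backbone
#' sites, after bond-walk unwrapping across periodic boundaries.
#'
#' @param traj a `cg_trajectory`.
#' @param frames frame indices to use (default all).
#' @param chains chain ids (default all).
#' @return list with `mean`, `values` (frames x chains matrix) and the
#'   frame/chain indices used.
#' @export
end_to_end <- function(traj, frames = NULL, chains = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(frames)) frames <- seq_along(traj$frames)
  if (is.null(chains)) chains <- seq_len(traj$n_chains)
  vals <- matrix(NA_real_, length(frames), length(chains))
  for (fi in seq_along(frames)) {
    for (ci in seq_along(chains)) {
      bb <- backbone_positions(traj, frames[fi], chains[ci])
      vals[fi, ci] <- if (nrow(bb) < 2) 0
        else sqrt(sum((bb[nrow(bb), ] - bb[1, ])^2))
    }
  }
  list(mean = mean(vals), values = vals, frames = frames, chains = chains)
}

#' Persistence length from backbone bond-vector correlations
#'
#' Computes \eqn{\langle \cos\theta(s) \rangle} between backbone bond
#' vectors separated by `s` bonds, pooled over chains and frames, and fits
#' \eqn{\ln\langle\cos\theta(s)\rangle = -s / L_p} over `fit_range` by
#' least squares through the origin.  `L_p` is reported in backbone-bond
#' (monomer) units.  A chain with no measurable decay over the fit range
#' is reported as `L_p = Inf` ("exceeds chain length").
#'
#' @param x a `cg_trajectory`, a list of backbone-position matrices
#'   (each N x 3, one conformation), or a single such matrix.
#' @param fit_range bond separations used in the fit (default 1:8).
#' @param frames,chains subset selection when `x` is a trajectory.
#' @param min_frames warn when fewer decorrelated conformations than this
#'   enter the average (default 50).
#' @param min_cos separations whose mean correlation has decayed below
#'   this floor are dropped from the fit (default 0.05): the log of a
#'   small noisy average is biased and would corrupt the slope.
#' @return An object of class `persistence_result` with `L_p`,
#'   `mean_cos_curve` (starting at s = 0), `fit_range` and `fit_quality`
#'   (squared correlation of ln-cos with s over the fit range).
#' @export
persistence_length <- function(x, fit_range = 1:8, frames = NULL,
                               chains = NULL, min_frames = 50L,
                               min_cos = 0.05) {
  confs <- if (inherits(x, "cg_trajectory")) {
    if (is.null(frames)) frames <- seq_along(x$frames)
    if (is.null(chains)) chains <- seq_len(x$n_chains)
    out <- list()
    for (f in frames) for (c_id in chains)
      out[[length(out) + 1L]] <- backbone_positions(x, f, c_id)
    out
  } else if (is.matrix(x)) list(x) else x
  if (length(confs) < min_frames)
    warning(sprintf(
      "only %d conformations entered the average; >= %d recommended",
      length(confs), min_frames), call. = FALSE)
  n_bonds <- nrow(confs[[1]]) - 1L
  if (n_bonds < 3L)
    stop("chains of at least 4 monomers are required", call. = FALSE)
  fit_range <- fit_range[fit_range >= 1 & fit_range <= n_bonds - 1]
  s_max <- n_bonds - 1L
  acc <- numeric(s_max + 1L); cnt <- numeric(s_max + 1L)
  for (bb in confs) {
    b <- diff(bb)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (s in 0:min(s_max, nb - 1L)) {
      i <- seq_len(nb - s)
      acc[s + 1L] <- acc[s + 1L] + sum(rowSums(b[i, , drop = FALSE] *
                                                 b[i + s, , drop = FALSE]))
      cnt[s + 1L] <- cnt[s + 1L] + length(i)
    }
  }
  curve <- acc / cnt
  cs <- curve[fit_range + 1L]
  keep <- cs >= min_cos
  if (any(keep)) {
    fit_range <- fit_range[keep]
    cs <- cs[keep]
  }
  if (any(cs <= 0))
    stop(paste0(
      "non-positive bond correlations inside the fit range (chain too ",
      "flexible for this range); mean cos curve: ",
      paste(sprintf("%.3f", curve[seq_len(min(10, length(curve)))]),
            collapse = ", ")), call. = FALSE)
  slope <- sum(fit_range * log(cs)) / sum(fit_range^2)
  lp <- if (slope >= -1e-10) Inf else -1 / slope
  r2 <- if (length(fit_range) > 2 && is.finite(lp))
    stats::cor(log(cs), fit_range)^2 else 1
  structure(list(L_p = lp, fit_range = fit_range, fit_quality = r2,
                 mean_cos_curve = curve, n_conformations = length(confs)),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  lp <- if (is.finite(x$L_p)) sprintf("%.3f monomer units", x$L_p)
    else "exceeds chain length (no measurable decay)"
  cat(sprintf("persistence length: %s\n", lp))
  cat(sprintf("  fit over s = %s, R^2 = %.4f, %d conformations\n",
              paste(range(x$fit_range), collapse = ".."), x$fit_quality,
              x$n_conformations))
  invisible(x)
}

#' Synthetic freely rotating chain
#'
#' Backbone generator with a fixed bending angle between successive
#' bonds, so \eqn{\langle\cos\theta(s)\rangle = c^s} exactly and the
#' persistence length is \eqn{-1/\ln c}.  Used as the known-decay test
#' bed for [persistence_length()].
#'
#' @param n_bonds number of bonds (monomers - 1).
#' @param cos_theta cosine of the fixed angle between successive bonds.
#' @param seed RNG seed for the free azimuthal rotations.
#' @param bond_length bond length (default 1).
#' @return (n_bonds + 1) x 3 matrix of backbone positions.
#' @export
freely_rotating_chain <- function(n_bonds, cos_theta, seed = 1L,
                                  bond_length = 1.0) {
  rng <- .make_rng(seed)
  pos <- matrix(0, n_bonds + 1L, 3)
  b <- c(1, 0, 0)
  pos[2, ] <- b * bond_length
  sin_theta <- sqrt(1 - cos_theta^2)
  for (i in seq_len(n_bonds - 1L)) {
    ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    u <- ref - sum(ref * b) * b
    u <- u / sqrt(sum(u^2))
    w <- c(b[2] * u[3] - b[3] * u[2],
           b[3] * u[1] - b[1] * u[3],
           b[1] * u[2] - b[2] * u[1])
    phi <- .with_rng(rng, stats::runif(1, 0, 2 * pi))
    b <- cos_theta * b + sin_theta * (cos(phi) * u + sin(phi) * w)
    b <- b / sqrt(sum(b^2))
    pos[i + 2L, ] <- pos[i + 1L, ] + b * bond_length
  }
  pos
}

#' Cluster formation analysis
#'
#' Two chains are linked when any inter-chain site pair is within
#' `cutoff` under the minimum-image convention; clusters are the
#' connected components of the resulting chain graph (union-find).
#'
#' @param positions n x 3 site positions (any image) — or a
#'   `cg_trajectory`, in which case `frame` selects the frame.
#' @param box periodic box edges.
#' @param chain_id per-site chain ids.
#' @param cutoff linkage distance in sigma (default 1.5, the first
#'   excluded-volume coordination shell plus margin).
#' @param frame frame index when `positions` is a trajectory.
#' @return An object of class `cluster_report`: per-chain `labels`
#'   (canonical, by first occurrence), `sizes` (decreasing), `largest_size`
#'   and the linking site pairs per chain pair (used for unwrapping).
#' @export
cluster_analysis <- function(positions, box = NULL, chain_id = NULL,
                             cutoff = 1.5, frame = NULL) {
  if (inherits(positions, "cg_trajectory")) {
    traj <- positions
    if (is.null(frame)) frame <- length(traj$frames)
    box <- traj$box; chain_id <- traj$chain_id
    positions <- traj$frames[[frame]]
  }
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  positions <- as.matrix(positions)
  chains <- sort(unique(chain_id))
  nc <- length(chains)
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  links <- list()
  if (nc >= 2) {
    for (a in seq_len(nc - 1)) {
      ia <- which(chain_id == chains[a])
      pa <- positions[ia, , drop = FALSE]
      for (b in seq(a + 1, nc)) {
        ib <- which(chain_id == chains[b])
        pb <- positions[ib, , drop = FALSE]
        best <- Inf; best_pair <- NULL
        for (k in seq_len(nrow(pa))) {
          d <- sweep(pb, 2, pa[k, ])
          if (!is.null(box))
            d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
          d2 <- rowSums(d^2)
          m <- which.min(d2)
          if (d2[m] < best) { best <- d2[m]; best_pair <- c(ia[k], ib[m]) }
        }
        if (best <= cutoff^2) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[rb] <- ra
          links[[length(links) + 1L]] <-
            list(a = chains[a], b = chains[b], sites = best_pair)
        }
      }
    }
  }
  root <- vapply(seq_len(nc), find, integer(1))
  labels <- match(root, unique(root))
  sizes <- sort(as.integer(table(labels)), decreasing = TRUE)
  structure(list(labels = stats::setNames(labels, chains),
                 sizes = sizes, cutoff = cutoff,
                 largest_size = if (nc > 0) max(sizes) else 0L,
                 links = links, chains = chains),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster report (cutoff %g sigma): %d cluster(s), sizes %s\n",
              x$cutoff, length(x$sizes), paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Sites of the largest cluster, made whole across the box
#'
#' Unwraps every chain, then walks the cluster's chain graph shifting
#' each chain by whole box vectors so that every linked pair obeys the
#' minimum image — the cluster becomes a single connected object suitable
#' for [shape_metrics()].
#'
#' @param positions n x 3 site positions, or a `cg_trajectory` (+ `frame`).
#' @param box,chain_id,monomer_id,site_role per-site metadata.
#' @param cutoff linkage cutoff, as in [cluster_analysis()].
#' @param frame frame index for trajectories.
#' @return list with `positions` (sites of the largest cluster, common
#'   image), `site_index`, `chains` and the `cluster_report`.
#' @export
largest_cluster_sites <- function(positions, box = NULL, chain_id = NULL,
                                  monomer_id = NULL, site_role = NULL,
                                  cutoff = 1.5, frame = NULL) {
  if (inherits(positions, "cg_trajectory")) {
    traj <- positions
    if (is.null(frame)) frame <- length(traj$frames)
    box <- traj$box; chain_id <- traj$chain_id
    monomer_id <- traj$monomer_id; site_role <- traj$site_role
    positions <- traj$frames[[frame]]
  }
  rep_ <- cluster_analysis(positions, box, chain_id, cutoff)
  big <- which.max(tabulate(rep_$labels))
  members <- rep_$chains[rep_$labels == big]
  pos <- unwrap_chains(positions, box, chain_id, monomer_id, site_role)
  shift <- matrix(NA_real_, length(members), 3,
                  dimnames = list(as.character(members), NULL))
  shift[1, ] <- 0
  queue <- members[1]
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    for (lk in rep_$links) {
      for (dir in 1:2) {
        from <- if (dir == 1) lk$a else lk$b
        to <- if (dir == 1) lk$b else lk$a
        if (from != a || !(to %in% members)) next
        if (!any(is.na(shift[as.character(to), ]))) next
        s_from <- if (dir == 1) lk$sites[1] else lk$sites[2]
        s_to <- if (dir == 1) lk$sites[2] else lk$sites[1]
        d <- pos[s_to, ] - (pos[s_from, ] + shift[as.character(a), ])
        shift[as.character(to), ] <- -box * round(d / box)
        queue <- c(queue, to)
      }
    }
  }
  shift[is.na(shift)] <- 0
  idx <- which(chain_id %in% members)
  out <- pos[idx, , drop = FALSE] +
    shift[as.character(chain_id[idx]), , drop = FALSE]
  list(positions = out, site_index = idx, chains = members,
       cluster_report = rep_)
}

#' Gyration-tensor shape metrics
#'
#' Mass-weighted gyration tensor about the selection centroid, with
#' descriptors distinguishing spherical aggregates from rod-like bundles:
#' radius of gyration, asphericity \eqn{b = \lambda_1 -
#' (\lambda_2+\lambda_3)/2}, relative shape anisotropy \eqn{\kappa^2 = 1 -
#' 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#' \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2 \in [0, 1]}, and
#' the principal-axis ratio \eqn{\lambda_1/\lambda_3}.
#'
#' @param positions n x 3 matrix (n >= 2), already made whole (no
#'   periodic wrapping applied here).
#' @param masses optional site masses (default equal).
#' @return An object of class `shape_metrics` with the tensor, sorted
#'   eigenvalues, `Rg`, `asphericity`, `kappa2` and `axis_ratio`.
#' @export
shape_metrics <- function(positions, masses = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("at least 2 sites are required", call. = FALSE)
  if (is.null(masses)) masses <- rep(1, n)
  m <- masses / sum(masses)
  centroid <- colSums(positions * m)
  d <- sweep(positions, 2, centroid)
  S <- t(d * m) %*% d
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  tr <- sum(ev)
  kappa2 <- if (tr > 0) 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] +
                                   ev[1] * ev[3]) / tr^2 else 0
  structure(list(gyration_tensor = S, eigenvalues = ev,
                 Rg = sqrt(tr),
                 asphericity = ev[1] - (ev[2] + ev[3]) / 2,
                 kappa2 = kappa2,
                 axis_ratio = if (ev[3] > 0) ev[1] / ev[3] else Inf),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf(
    "shape: Rg %.3f, asphericity %.3f, kappa^2 %.3f, axis ratio %.3g\n",
    x$Rg, x$asphericity, x$kappa2, x$axis_ratio))
  invisible(x)
}

#' Oxygen enrichment in the outer shell of a cluster
#'
#' Sites are ranked by distance from the cluster centroid; the outer
#' shell is the top `shell_fraction` by count.  Returns the fraction of
#' O- sites in that shell, to be compared against the global O- fraction
#' of 2/3 for the three-site monomer.
#'
#' @param positions n x 3 site positions of one cluster, common image.
#' @param site_role per-site roles ("S+" / "O-").
#' @param shell_fraction outer-shell fraction by site count, in (0, 1)
#'   (default 0.3).
#' @return fraction of O- sites in the outer shell.
#' @export
surface_enrichment <- function(positions, site_role, shell_fraction = 0.3) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 10) stop("cluster must have at least 10 sites", call. = FALSE)
  if (shell_fraction <= 0 || shell_fraction >= 1)
    stop("shell_fraction must lie in (0, 1)", call. = FALSE)
  centroid <- colMeans(positions)
  r <- sqrt(rowSums(sweep(positions, 2, centroid)^2))
  if (max(r) < 1e-12)
    stop("degenerate cluster: all sites coincident", call. = FALSE)
  n_shell <- max(1L, ceiling(shell_fraction * n))
  shell <- order(r, decreasing = TRUE)[seq_len(n_shell)]
  mean(site_role[shell] == "O-")
}
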