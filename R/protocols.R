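#' Stepwise hydration schedule
#'
#' Encodes a hydration history — stepwise additions of water to a DMSO
#' solution — as a piecewise-constant dielectric schedule.  After the
#' k-th addition the water volume fraction is \eqn{\phi_w = \sum v_i /
#' (V_0 + \sum v_i)} and the dielectric interpolates linearly between the
#' DMSO and water endpoints: \eqn{\varepsilon_r = 47 + \phi_w (80 - 47)}.
#' Volumes are in arbitrary (microlitre-equivalent) units; only the
#' ratios matter.
#'
#' @param initial_volume solvent volume before any addition (> 0).
#' @param additions vector of water volumes added per step (each > 0);
#'   empty for a constant-dielectric schedule.
#' @param hold_steps integration steps spent on each post-addition
#'   plateau (scalar or one per addition).
#' @param initial_hold steps on the initial pure-DMSO plateau (default
#'   `hold_steps[1]`).
#' @param eps_dmso,eps_water dielectric endpoints (defaults 47 and 80).
#' @return An object of class `hydration_schedule` with a `plateaus`
#'   data.frame (phi_w, eps_r, hold_steps).
#' @export
hydration_schedule <- function(initial_volume, additions = numeric(0),
                               hold_steps = 50000L, initial_hold = NULL,
                               eps_dmso = 47, eps_water = 80) {
  if (initial_volume <= 0) stop("initial_volume must be > 0", call. = FALSE)
  if (length(additions) > 0 && any(additions <= 0))
    stop("additions must be positive volumes", call. = FALSE)
  hold_steps <- rep(as.integer(hold_steps), length.out =
                      max(1L, length(additions)))
  if (is.null(initial_hold)) initial_hold <- hold_steps[1]
  cum <- if (length(additions)) cumsum(additions) else numeric(0)
  phi <- c(0, cum / (initial_volume + cum))
  eps <- eps_dmso + phi * (eps_water - eps_dmso)
  plateaus <- data.frame(
    plateau = seq_along(phi) - 1L,
    phi_w = phi, eps_r = eps,
    hold_steps = c(as.integer(initial_hold),
                   if (length(additions)) hold_steps else integer(0)))
  structure(list(plateaus = plateaus, initial_volume = initial_volume,
                 additions = additions, eps_dmso = eps_dmso,
                 eps_water = eps_water),
            class = "hydration_schedule")
}

#' @export
print.hydration_schedule <- function(x, ...) {
  cat(sprintf(
    "hydration schedule: V0 = %g, %d addition(s), final phi_w = %.3f, eps_r %.4g -> %.4g\n",
    x$initial_volume, length(x$additions),
    x$plateaus$phi_w[nrow(x$plateaus)], x$eps_dmso,
    x$plateaus$eps_r[nrow(x$plateaus)]))
  print(x$plateaus, row.names = FALSE)
  invisible(x)
}

#' Total integration steps of a schedule
#' @param schedule a `hydration_schedule`.
#' @return integer step count over all plateaus.
#' @export
schedule_total_steps <- function(schedule)
  sum(schedule$plateaus$hold_steps)

#' Per-step dielectric vector of a schedule
#'
#' @param schedule a `hydration_schedule`.
#' @param n_steps target length; must be at least the schedule's total
#'   steps (the final dielectric is held for any excess).
#' @return numeric vector of length `n_steps`.
#' @export
schedule_eps_steps <- function(schedule, n_steps) {
  total <- schedule_total_steps(schedule)
  if (n_steps < total)
    stop(sprintf("n_steps (%d) < schedule total steps (%d)",
                 n_steps, total), call. = FALSE)
  eps <- rep(schedule$plateaus$eps_r, schedule$plateaus$hold_steps)
  c(eps, rep(eps[length(eps)], n_steps - total))
}

## per-plateau observables, averaged over the final half of the plateau's
## saved frames (single-snapshot shape metrics of a small aggregate are
## noisy)
.plateau_metrics <- function(traj, cutoff) {
  nf <- length(traj$frames)
  frames <- seq(max(1L, floor(nf / 2) + 1L), nf)
  rows <- lapply(frames, function(f) {
    lc <- largest_cluster_sites(traj, cutoff = cutoff, frame = f)
    sm <- shape_metrics(lc$positions)
    rep_ <- lc$cluster_report
    data.frame(n_clusters = length(rep_$sizes),
               largest_size = rep_$largest_size,
               largest_Rg = sm$Rg, asphericity = sm$asphericity,
               kappa2 = sm$kappa2, axis_ratio = sm$axis_ratio,
               surface_O_fraction = if (nrow(lc$positions) >= 10)
                 surface_enrichment(lc$positions,
                                    traj$site_role[lc$site_index])
               else NA_real_)
  })
  out <- as.data.frame(t(colMeans(do.call(rbind, rows), na.rm = TRUE)))
  out$largest_size <- max(vapply(rows, function(r) r$largest_size,
                                 numeric(1)))
  out$mean_end_to_end <- mean(end_to_end(traj, frames = frames)$values)
  out
}

#' Run a hydration history and analyse each plateau
#'
#' Advances the system plateau by plateau: the dielectric is set from the
#' schedule, the system is propagated for the plateau's hold steps, and
#' the final configuration of each plateau is analysed (cluster report,
#' largest-cluster size and gyration-tensor shape, mean backbone
#' end-to-end distance, surface oxygen fraction).
#'
#' @param system a `cg_system`.
#' @param ff a [force_field()]; its dielectric is overridden per plateau.
#' @param cfg an [integrator_config()]; `n_steps` is taken from the
#'   schedule, `seed` is advanced per plateau.
#' @param schedule a [hydration_schedule()].
#' @param cutoff cluster linkage cutoff in sigma.
#' @return An object of class `hydration_history`: per-plateau `table`,
#'   the `final_system`, and the final plateau's trajectory.
#' @export
run_hydration_history <- function(system, ff, cfg, schedule, cutoff = 1.5) {
  stopifnot(inherits(schedule, "hydration_schedule"))
  rows <- NULL
  traj <- NULL
  cur <- system
  for (p in seq_len(nrow(schedule$plateaus))) {
    pl <- schedule$plateaus[p, ]
    ff_p <- ff
    ff_p$dielectric_eps_r <- pl$eps_r
    cfg_p <- cfg
    cfg_p$n_steps <- pl$hold_steps
    cfg_p$seed <- cfg$seed + 1000L * (p - 1L)
    traj <- run_dynamics(cur, ff_p, cfg_p)
    cur <- traj$final_system
    met <- .plateau_metrics(traj, cutoff)
    rows <- rbind(rows, cbind(pl, met))
    if (!isTRUE(traj$ok)) {
      warning(sprintf("propagation failed in plateau %d (step %d); table truncated",
                      pl$plateau, traj$fail_step), call. = FALSE)
      break
    }
  }
  structure(list(table = rows, final_system = cur, last_trajectory = traj,
                 schedule = schedule, ok = isTRUE(traj$ok)),
            class = "hydration_history")
}

#' @export
print.hydration_history <- function(x, ...) {
  cat("hydration history run\n")
  print(x$table[, c("plateau", "phi_w", "eps_r", "n_clusters",
                    "largest_size", "largest_Rg", "kappa2",
                    "mean_end_to_end")], row.names = FALSE)
  invisible(x)
}

.final_third_frames <- function(traj) {
  nf <- length(traj$frames)
  seq(max(1L, floor(2 * nf / 3) + 1L), nf)
}

#' Chain-stiffness morphology scan
#'
#' Runs a multi-chain system at fixed dielectric for each backbone
#' bending constant and reports the largest-cluster shape metrics
#' (averaged over the final third of frames and over seeds): rigid chains
#' bundle into elongated aggregates, flexible chains collapse into
#' near-spherical ones.
#'
#' @param k_bend_values backbone bending constants to scan (kT/rad^2).
#' @param n_chains,N system composition (defaults 6 chains of 20).
#' @param ff base [force_field()] (dielectric overridden by `eps_r`).
#' @param cfg an [integrator_config()].
#' @param eps_r solvent dielectric for the scan (default 80, water).
#' @param seeds seeds for independent replicas (>= 3 recommended).
#' @param density monomer number density in sigma^-3 used to size the box.
#' @param cutoff cluster linkage cutoff.
#' @return data.frame, one row per (k_bend, seed), plus attribute
#'   `"summary"` with per-k_bend means.
#' @export
stiffness_scan <- function(k_bend_values, n_chains = 6L, N = 20L,
                           ff = force_field(), cfg = integrator_config(),
                           eps_r = 80, seeds = 1:3, density = 0.02,
                           cutoff = 1.5) {
  if (any(k_bend_values < 0))
    stop("k_bend_values must be >= 0", call. = FALSE)
  rows <- NULL
  for (kb in k_bend_values) {
    for (sd in seeds) {
      ff_k <- ff
      ff_k$k_bend_backbone <- kb
      ff_k$dielectric_eps_r <- eps_r
      sys <- build_system(n_chains, N, density = density,
                          packing = "lattice", seed = sd)
      cfg_s <- cfg; cfg_s$seed <- sd
      traj <- run_dynamics(sys, ff_k, cfg_s)
      met <- do.call(rbind, lapply(.final_third_frames(traj), function(f) {
        lc <- largest_cluster_sites(traj, cutoff = cutoff, frame = f)
        sm <- shape_metrics(lc$positions)
        rep_ <- lc$cluster_report
        data.frame(n_clusters = length(rep_$sizes),
                   largest_size = rep_$largest_size, largest_Rg = sm$Rg,
                   asphericity = sm$asphericity, kappa2 = sm$kappa2,
                   axis_ratio = sm$axis_ratio)
      }))
      rows <- rbind(rows, cbind(data.frame(k_bend = kb, seed = sd),
                                as.data.frame(t(colMeans(met)))))
    }
  }
  summ <- stats::aggregate(rows[, -(1:2)], by = list(k_bend = rows$k_bend),
                           FUN = mean)
  attr(rows, "summary") <- summ
  rows
}

#' Oligomer-length aggregation scan
#'
#' For each degree of polymerization, runs replicas at fixed dielectric
#' and reports the fraction of seeds in which a multi-chain cluster of at
#' least half the chains persists throughout the final third of the run
#' (an operational aggregation criterion).
#'
#' @param N_values degrees of polymerization to scan.
#' @param n_chains chains per system.
#' @param ff,cfg force field and integrator settings.
#' @param eps_r solvent dielectric (default 80).
#' @param seeds replica seeds (>= 5 recommended).
#' @param density monomer number density in sigma^-3.  Held fixed across
#'   `N_values` so the monomer concentration is comparable.
#' @param cutoff cluster linkage cutoff.
#' @param persist_fraction cluster must contain at least this fraction of
#'   the chains (default 0.5).
#' @return data.frame with one row per N: `aggregation_fraction` plus the
#'   per-seed outcomes as attribute `"detail"`.
#' @export
oligomer_length_scan <- function(N_values, n_chains = 6L,
                                 ff = force_field(),
                                 cfg = integrator_config(), eps_r = 80,
                                 seeds = 1:5, density = 0.02, cutoff = 1.5,
                                 persist_fraction = 0.5) {
  if (any(N_values < 1)) stop("N_values must be >= 1", call. = FALSE)
  detail <- NULL
  for (N in N_values) {
    for (sd in seeds) {
      ff_n <- ff; ff_n$dielectric_eps_r <- eps_r
      sys <- build_system(n_chains, N, density = density,
                          packing = "lattice", seed = sd)
      cfg_s <- cfg; cfg_s$seed <- sd
      traj <- run_dynamics(sys, ff_n, cfg_s)
      need <- ceiling(persist_fraction * n_chains)
      persists <- all(vapply(.final_third_frames(traj), function(f) {
        cluster_analysis(traj, frame = f, cutoff = cutoff)$largest_size >=
          max(2L, need)
      }, logical(1)))
      detail <- rbind(detail,
                      data.frame(N = N, seed = sd, aggregated = persists))
    }
  }
  out <- stats::aggregate(list(aggregation_fraction = detail$aggregated),
                          by = list(N = detail$N), FUN = mean)
  attr(out, "detail") <- detail
  out
}
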