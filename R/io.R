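## atomic write: temp file in the same directory, then rename
.atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temp file onto '%s'", path), call. = FALSE)
  invisible(path)
}

.traj_species <- function(role) ifelse(role == "S+", "S", "O")

#' Write a trajectory to disk
#'
#' Two plain-text dialects: extended XYZ (per-frame comment line carries
#' the lattice, step index and dielectric; per-site columns species,
#' position, role, charge, chain and monomer ids) and LAMMPS-dump
#' compatible text (`ITEM:` sections; type 1 = S+, type 2 = O-).  Writes
#' are atomic (temp file + rename).
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param format `"extxyz"` or `"lammps_dump"`.
#' @param charges per-site charges; defaults to the trajectory's final
#'   system.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("extxyz", "lammps_dump"),
                             charges = NULL) {
  format <- match.arg(format)
  if (is.null(charges))
    charges <- if (!is.null(traj$final_system)) traj$final_system$charge
      else traj$charge
  n <- length(traj$site_role)
  lines <- character(0)
  for (f in seq_along(traj$frames)) {
    pos <- traj$frames[[f]]
    if (format == "extxyz") {
      lattice <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"',
                         traj$box[1], traj$box[2], traj$box[3])
      props <- "Properties=species:S:1:pos:R:3:role:S:1:charge:R:1:chain:I:1:monomer:I:1"
      lines <- c(lines, as.character(n),
                 sprintf("%s %s step=%d eps_r=%.10g", lattice, props,
                         traj$frame_steps[f], traj$frame_eps[f]),
                 sprintf("%s %.8f %.8f %.8f %s %.8f %d %d",
                         .traj_species(traj$site_role), pos[, 1], pos[, 2],
                         pos[, 3], traj$site_role, charges,
                         traj$chain_id, traj$monomer_id))
    } else {
      lines <- c(lines,
                 "ITEM: TIMESTEP", as.character(traj$frame_steps[f]),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", traj$box),
                 sprintf("ITEM: ATOMS id type x y z q mol monomer eps_r"),
                 sprintf("%d %d %.8f %.8f %.8f %.8f %d %d %.10g",
                         seq_len(n), ifelse(traj$site_role == "S+", 1L, 2L),
                         pos[, 1], pos[, 2], pos[, 3], charges,
                         traj$chain_id, traj$monomer_id, traj$frame_eps[f]))
    }
  }
  .atomic_write(lines, path)
}

.parse_error <- function(path, line, msg)
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)

.read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(0); eps <- numeric(0)
  role <- NULL; charge <- NULL; chain <- NULL; mono <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      .parse_error(path, i, "expected atom count")
    n <- as.integer(lines[i])
    if (i + 1L > length(lines)) .parse_error(path, i + 1L, "missing comment line")
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) < 2) .parse_error(path, i + 1L, "missing Lattice")
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    box <- lv[c(1, 5, 9)]
    step <- regmatches(comment, regexec("step=(\\d+)", comment))[[1]]
    ep <- regmatches(comment,
                     regexec("eps_r=([0-9.eE+-]+)", comment))[[1]]
    if (i + 1L + n > length(lines))
      .parse_error(path, length(lines), "truncated frame")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rows, length, integer(1)) < 8)
    if (length(bad))
      .parse_error(path, i + 1L + bad[1], "malformed atom line")
    m <- do.call(rbind, rows)
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(m[, 2:4]), ncol = 3)
    steps <- c(steps, if (length(step) >= 2) as.integer(step[2]) else
      length(frames) - 1L)
    eps <- c(eps, if (length(ep) >= 2) as.numeric(ep[2]) else NA_real_)
    role <- m[, 5]; charge <- as.numeric(m[, 6])
    chain <- as.integer(m[, 7]); mono <- as.integer(m[, 8])
    i <- i + 2L + n
  }
  list(frames = frames, frame_steps = steps, frame_eps = eps, box = box,
       site_role = role, charge = charge, chain_id = chain,
       monomer_id = mono)
}

.read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(0); eps <- numeric(0)
  role <- NULL; charge <- NULL; chain <- NULL; mono <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      .parse_error(path, i, "expected ITEM: TIMESTEP")
    step <- as.integer(lines[i + 1L])
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L]))
      .parse_error(path, i + 2L, "expected ITEM: NUMBER OF ATOMS")
    n <- as.integer(lines[i + 3L])
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4L]))
      .parse_error(path, i + 4L, "missing ITEM: BOX BOUNDS section")
    bounds <- do.call(rbind, strsplit(trimws(lines[(i + 5L):(i + 7L)]),
                                      "\\s+"))
    box <- as.numeric(bounds[, 2]) - as.numeric(bounds[, 1])
    if (!grepl("^ITEM: ATOMS", lines[i + 8L]))
      .parse_error(path, i + 8L, "expected ITEM: ATOMS")
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i + 8L]), "\\s+")[[1]]
    if (i + 8L + n > length(lines))
      .parse_error(path, length(lines), "truncated frame")
    m <- do.call(rbind, strsplit(trimws(lines[(i + 9L):(i + 8L + n)]),
                                 "\\s+"))
    get <- function(name) {
      k <- match(name, cols)
      if (is.na(k)) .parse_error(path, i + 8L,
                                 sprintf("missing atom column '%s'", name))
      m[, k]
    }
    ord <- order(as.integer(get("id")))
    m <- m[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(c(get("x"), get("y"), get("z"))), ncol = 3)
    steps <- c(steps, step)
    eps <- c(eps, if ("eps_r" %in% cols) as.numeric(get("eps_r")[1])
      else NA_real_)
    role <- ifelse(as.integer(get("type")) == 1L, "S+", "O-")
    charge <- if ("q" %in% cols) as.numeric(get("q")) else rep(0, n)
    chain <- if ("mol" %in% cols) as.integer(get("mol")) else rep(1L, n)
    mono <- if ("monomer" %in% cols) as.integer(get("monomer")) else
      seq_len(n)
    i <- i + 9L + n
  }
  list(frames = frames, frame_steps = steps, frame_eps = eps, box = box,
       site_role = role, charge = charge, chain_id = chain,
       monomer_id = mono)
}

#' Read a trajectory from disk
#'
#' Accepts both dialects written by [write_trajectory()]; the format is
#' detected from the first line unless given.
#'
#' @param path input file.
#' @param format `"auto"`, `"extxyz"` or `"lammps_dump"`.
#' @return a `cg_trajectory` (without integrator metadata; analysis
#'   operations work on it directly).
#' @export
read_trajectory <- function(path, format = c("auto", "extxyz",
                                             "lammps_dump")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^ITEM:", first)) "lammps_dump" else "extxyz"
  }
  raw <- if (format == "extxyz") .read_extxyz(path) else
    .read_lammps_dump(path)
  chains <- unique(raw$chain_id)
  structure(c(raw, list(
    n_chains = length(chains),
    N = max(raw$monomer_id),
    final_system = NULL, log = NULL, forcefield = NULL, config = NULL,
    ok = TRUE, fail_step = -1L
  )), class = "cg_trajectory")
}

#' Write the per-step energy log as CSV
#'
#' Columns: step, wca, coulomb, bond, angle, total, kinetic, temperature.
#'
#' @param traj a `cg_trajectory` from [run_dynamics()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_run_log <- function(traj, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(traj$log, tmp, row.names = FALSE)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temp file onto '%s'", path), call. = FALSE)
  invisible(path)
}

#' Serialize a system (sites, roles, bonds, angles, box) to JSON
#'
#' @param system a `cg_system`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or path, invisibly.
#' @export
system_to_json <- function(system, path = NULL) {
  doc <- list(
    box = system$box, periodic = system$periodic,
    n_chains = system$n_chains, N = system$N,
    sites = data.frame(
      x = system$positions[, 1], y = system$positions[, 2],
      z = system$positions[, 3], role = system$site_role,
      charge = system$charge, chain = system$chain_id,
      monomer = system$monomer_id),
    bonds = system$bonds, angles = system$angles,
    rng_seed = system$rng_seed)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  .atomic_write(js, path)
}

## ---- run configuration ---------------------------------------------------

.default_run_config <- function() {
  list(
    system = list(n_chains = 1L, n_monomers = 20L, box = NULL, density = 2e-3,
                  packing = "lattice", conformation = "extended",
                  seed = 1L),
    forcefield = list(dielectric_eps_r = 47, k_bend_backbone =
                        CALIBRATED_K_BEND, sigma = 1, sigma_o = 0.35,
                      epsilon_wca = 1, k_bond_SO = 1000,
                      r0_SO = 1.43 / SIGMA_ANGSTROM, k_angle_OSO = 100,
                      theta0_OSO = 119.3, k_bond_backbone = 1000,
                      r0_backbone = 1.0, r_cut_coulomb = 8,
                      temperature_kT = 1),
    integrator = list(dt = 0.005, gamma = 1.0, temperature_kT = 1.0,
                      n_steps = 10000L, save_every = 1000L, seed = 1L),
    protocol = list(type = "run", initial_volume = 200,
                    additions = numeric(0), hold_steps = 50000L,
                    eps_r = NULL, k_bend_values = NULL, N_values = NULL,
                    seeds = 1:3),
    output = list(trajectory = NULL, format = "extxyz", table = NULL,
                  log = NULL)
  )
}

.merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s'", path), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], path)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) document with sections `system`, `forcefield`,
#' `integrator`, `protocol` and `output`.  Unknown keys are rejected with
#' an error naming the key; every omitted key is materialized with its
#' default, so the echoed configuration is complete.
#'
#' @param path config file path.
#' @return An object of class `run_config` (a fully materialized nested
#'   list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.default_run_config(), user)
  # YAML reads an empty sequence as list(); canonicalize to numeric
  if (length(cfg$protocol$additions) == 0)
    cfg$protocol$additions <- numeric(0)
  else cfg$protocol$additions <- as.numeric(unlist(cfg$protocol$additions))
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param cfg a `run_config` (or compatible nested list).
#' @return `write_config` returns the path invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- .merge_config(.default_run_config(), unclass(cfg))
  .atomic_write(yaml::as.yaml(cfg, precision = 15), path)
}
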