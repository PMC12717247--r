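## Whole-cell translocation stage: multi-species Brownian dynamics in the
## cytosol with periodic boundaries, collision-mediated binding to
## mitochondrial surfaces, lateral membrane diffusion and stochastic
## retrotranslocation. The compiled engine does the stepping; this file owns
## configuration, validation, particle placement and the snapshot format.

AVOGADRO_PER_NM_UM3 <- 0.602214076  # molecules per (nM * um^3)

#' Convert a concentration to a particle count
#'
#' `N = round(conc[nM] * 0.602214076 * volume[um^3])`.
#'
#' @param conc_nM concentration in nanomolar (>= 0).
#' @param volume_um3 compartment volume in cubic micrometres (> 0).
#' @return integer particle count.
#' @export
concentration_to_count <- function(conc_nM, volume_um3) {
  if (any(conc_nM < 0)) stop_ms("concentration must be >= 0")
  if (any(volume_um3 <= 0)) stop_ms("volume must be > 0")
  as.integer(round(conc_nM * AVOGADRO_PER_NM_UM3 * volume_um3))
}

#' Convert a particle count to a concentration (nM)
#' @param count particle count.
#' @param volume_um3 compartment volume (um^3).
#' @return concentration in nM.
#' @export
count_to_concentration <- function(count, volume_um3) {
  if (any(count < 0)) stop_ms("count must be >= 0")
  count / (AVOGADRO_PER_NM_UM3 * volume_um3)
}

#' Species parameter table row
#'
#' @param name species identifier (e.g. `"MCL1"`).
#' @param conc_nM initial total concentration (nM).
#' @param D_cyto cytosolic diffusion coefficient (um^2/s).
#' @param D_mem lateral membrane diffusion coefficient (um^2/s).
#' @param p_bind translocation probability per mitochondrial collision.
#' @param k_off retrotranslocation rate (1/s).
#' @return one-row data.frame; rbind rows to form a species table.
#' @export
species_params <- function(name, conc_nM, D_cyto, D_mem, p_bind, k_off) {
  stopifnot(p_bind >= 0, p_bind <= 1, k_off >= 0, D_cyto >= 0, D_mem >= 0)
  data.frame(name = name, conc_nM = conc_nM, D_cyto = D_cyto, D_mem = D_mem,
             p_bind = p_bind, k_off = k_off)
}

#' Simulation configuration for the translocation stage
#'
#' @param species species table ([species_params()] rows).
#' @param dt time step (s).
#' @param duration simulated time (s).
#' @param record_interval interval between recorded time points (s).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param collide_from time (s) from which collision counters accumulate
#'   (use > 0 to exclude the equilibration transient from rate estimates).
#' @return a `sim_config` list.
#' @export
sim_config <- function(species, dt, duration, record_interval = duration / 20,
                       seed = 1L, collide_from = 0) {
  req <- c("name", "conc_nM", "D_cyto", "D_mem", "p_bind", "k_off")
  miss <- setdiff(req, names(species))
  if (length(miss)) {
    stop_ms("species table is missing required column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (any(!is.finite(species$D_cyto))) stop_ms("D_cyto must be finite")
  if (dt <= 0) stop_ms("dt must be > 0")
  if (duration < dt) stop_ms("duration must be >= dt")
  structure(list(species = species, dt = dt, duration = duration,
                 record_interval = record_interval, seed = as.integer(seed),
                 collide_from = collide_from),
            class = "sim_config")
}

#' Validate a configuration against a geometry
#'
#' Enforces the step-size invariant: the per-axis RMS cytosolic step
#' `sqrt(2 D dt)` must not exceed a quarter of the smallest mitochondrial
#' half-dimension, so particles cannot step across thin mitochondria.
#'
#' @param config a [sim_config()].
#' @param geometry a [cell_geometry()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_sim_config <- function(config, geometry) {
  if (nrow(geometry$boxes) > 0) {
    hmin <- min(as.matrix(geometry$boxes[, c("hx", "hy", "hz")]))
    rms <- sqrt(2 * max(config$species$D_cyto) * config$dt)
    if (rms > hmin / 4 + 1e-12) {
      stop_ms("RMS step %.4g um exceeds a quarter of the smallest half-dimension %.4g um; reduce dt",
              rms, hmin / 4)
    }
  }
  if (any(config$species$p_bind < 0 | config$species$p_bind > 1)) {
    stop_ms("p_bind must lie in [0, 1]")
  }
  invisible(TRUE)
}

# uniform cytosolic positions outside all mitochondria (vectorized rejection)
place_cytosol <- function(geometry, n, oversample = 1.5) {
  L <- geometry$cell_dims
  b <- geometry$boxes
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * oversample) + 100
    p <- cbind(runif(m, -L[1] / 2, L[1] / 2), runif(m, -L[2] / 2, L[2] / 2),
               runif(m, -L[3] / 2, L[3] / 2))
    if (nrow(b) > 0) {
      inside <- rep(FALSE, m)
      for (i in seq_len(nrow(b))) {
        inside <- inside | (abs(p[, 1] - b$cx[i]) < b$hx[i] &
                            abs(p[, 2] - b$cy[i]) < b$hy[i] &
                            abs(p[, 3] - b$cz[i]) < b$hz[i])
      }
      p <- p[!inside, , drop = FALSE]
    }
    out <- rbind(out, p)
  }
  out[seq_len(n), , drop = FALSE]
}

empty_snapshot <- function() {
  data.frame(species = character(), compartment = character(),
             mito_id = integer(), face_id = integer(), x = numeric(),
             y = numeric(), z = numeric(), u = numeric(), v = numeric())
}

# convert engine output to the snapshot data.frame contract
engine_to_snapshot <- function(out, species_names, box_ids) {
  memb <- out$compartment == 1L
  data.frame(
    species = species_names[out$species + 1L],
    compartment = ifelse(memb, "membrane", "cytosol"),
    mito_id = ifelse(memb, box_ids[out$box + 1L], NA_integer_),
    face_id = ifelse(memb, out$face, NA_integer_),
    x = out$xyz[, 1], y = out$xyz[, 2], z = out$xyz[, 3],
    u = ifelse(memb, out$uv[, 1], NA_real_),
    v = ifelse(memb, out$uv[, 2], NA_real_))
}

snapshot_to_engine <- function(snapshot, species_names, box_ids) {
  sp <- match(snapshot$species, species_names) - 1L
  if (anyNA(sp)) stop_ms("snapshot contains species missing from the config")
  memb <- snapshot$compartment == "membrane"
  bx <- rep(-1L, nrow(snapshot))
  if (any(memb)) {
    bx[memb] <- match(snapshot$mito_id[memb], box_ids) - 1L
    if (anyNA(bx[memb])) stop_ms("snapshot references unknown mito_id")
  }
  list(sp = as.integer(sp),
       comp = as.integer(memb),
       xyz = cbind(ifelse(is.na(snapshot$x), 0, snapshot$x),
                   ifelse(is.na(snapshot$y), 0, snapshot$y),
                   ifelse(is.na(snapshot$z), 0, snapshot$z)),
       box = as.integer(bx),
       face = as.integer(ifelse(memb, snapshot$face_id, -1L)),
       uv = cbind(ifelse(memb, snapshot$u, 0), ifelse(memb, snapshot$v, 0)))
}

run_engine <- function(geometry, config, state, n_steps, record_every,
                       seed, collide_from_step = 0L) {
  b <- geometry$boxes
  run_translocation_cpp(
    geometry$cell_dims,
    as.matrix(b[, c("cx", "cy", "cz")]), as.matrix(b[, c("hx", "hy", "hz")]),
    state$sp, state$comp, state$xyz, state$box, state$face, state$uv,
    config$species$D_cyto, config$species$D_mem, config$species$p_bind,
    config$species$k_off, config$dt, as.integer(n_steps),
    as.integer(record_every), as.numeric(seed), as.integer(collide_from_step))
}

#' Run the whole-cell translocation simulation
#'
#' Particles start uniformly distributed in the cytosol (outside all
#' mitochondria), diffuse, collide with mitochondria (binding with
#' probability `p_bind`, otherwise reflecting specularly), diffuse laterally
#' on membranes with face transitions, and retrotranslocate with per-step
#' probability `1 - exp(-k_off dt)`. Total particle number is conserved
#' exactly at every step.
#'
#' @param geometry a [cell_geometry()].
#' @param config a [sim_config()].
#' @param initial_snapshot optional snapshot to start from instead of uniform
#'   cytosolic placement.
#' @return a `whole_cell_run` list: `snapshot` (final particle table),
#'   `series` (tidy time series of compartment counts per species),
#'   `per_mito` (per-mitochondrion membrane counts and cumulative collision
#'   counts per species), `config`, `geometry`.
#' @export
run_whole_cell <- function(geometry, config, initial_snapshot = NULL) {
  validate_sim_config(config, geometry)
  spn <- config$species$name
  box_ids <- geometry$boxes$id
  if (is.null(initial_snapshot)) {
    counts <- concentration_to_count(config$species$conc_nM,
                                     prod(geometry$cell_dims))
    pos <- with_seed(derive_seed(config$seed, 1L),
                     place_cytosol(geometry, sum(counts)))
    state <- list(sp = rep(seq_along(spn) - 1L, counts),
                  comp = rep(0L, sum(counts)), xyz = pos,
                  box = rep(-1L, sum(counts)), face = rep(-1L, sum(counts)),
                  uv = matrix(0, sum(counts), 2))
  } else {
    state <- snapshot_to_engine(initial_snapshot, spn, box_ids)
  }
  n_steps <- max(1L, as.integer(round(config$duration / config$dt)))
  record_every <- max(1L, as.integer(round(config$record_interval / config$dt)))
  collide_from <- as.integer(round((config$collide_from %||% 0) / config$dt))
  out <- run_engine(geometry, config, state, n_steps, record_every,
                    derive_seed(config$seed, 2L), collide_from)
  K <- length(spn)
  ser <- out$series
  series <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(time = ser[, 1], species = spn[k], n_cyto = ser[, 1 + k],
               n_mem = ser[, 1 + K + k])
  }))
  gs <- geometry_summary(geometry)
  per_mito <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(mito_id = box_ids, species = spn[k],
               collisions = out$collisions[, k], count = out$mem_counts[, k],
               volume = gs$volume, area = gs$area, fragmented = gs$fragmented)
  }))
  structure(list(snapshot = engine_to_snapshot(out, spn, box_ids),
                 series = series, per_mito = per_mito, config = config,
                 geometry = geometry, time = n_steps * config$dt),
            class = "whole_cell_run")
}

#' Single cytosolic Brownian step
#'
#' Advances only the cytosolic particles of a snapshot by one time step
#' (Gaussian displacement, periodic wrap, collision handling); membrane
#' particles are left untouched and no retrotranslocation occurs.
#'
#' @param snapshot particle snapshot data.frame.
#' @param geometry a [cell_geometry()].
#' @param config a [sim_config()].
#' @param seed integer seed for this step.
#' @return the updated snapshot.
#' @export
step_cytosol <- function(snapshot, geometry, config, seed = config$seed) {
  cfg <- config
  cfg$species$D_mem <- 0
  cfg$species$k_off <- 0
  state <- snapshot_to_engine(snapshot, cfg$species$name, geometry$boxes$id)
  out <- run_engine(geometry, cfg, state, 1L, 1L, seed)
  engine_to_snapshot(out, cfg$species$name, geometry$boxes$id)
}

#' Single lateral membrane diffusion step
#'
#' Advances only membrane particles (2D Gaussian step in face coordinates
#' with unfolding at edges); cytosolic particles and binding are frozen.
#'
#' @inheritParams step_cytosol
#' @return the updated snapshot.
#' @export
step_membrane <- function(snapshot, geometry, config, seed = config$seed) {
  cfg <- config
  cfg$species$D_cyto <- 0
  cfg$species$k_off <- 0
  state <- snapshot_to_engine(snapshot, cfg$species$name, geometry$boxes$id)
  out <- run_engine(geometry, cfg, state, 1L, 1L, seed)
  engine_to_snapshot(out, cfg$species$name, geometry$boxes$id)
}

#' Single retrotranslocation step
#'
#' Each membrane particle is released with probability
#' `1 - exp(-k_off dt)` and placed 1 nm outside its face along the outward
#' normal; diffusion is frozen.
#'
#' @inheritParams step_cytosol
#' @return the updated snapshot.
#' @export
retrotranslocate <- function(snapshot, geometry, config, seed = config$seed) {
  cfg <- config
  cfg$species$D_cyto <- 0
  cfg$species$D_mem <- 0
  cfg$species$p_bind <- 0
  state <- snapshot_to_engine(snapshot, cfg$species$name, geometry$boxes$id)
  out <- run_engine(geometry, cfg, state, 1L, 1L, seed)
  engine_to_snapshot(out, cfg$species$name, geometry$boxes$id)
}

#' Collision outcome of one displacement segment
#'
#' Traces the segment from `start` to `end` against the mitochondria of a
#' geometry: the earliest intersection either binds the particle (with
#' probability `p_bind`) at the hit point, converted to face coordinates, or
#' reflects it specularly, re-checking further collisions within the step.
#'
#' @param start,end numeric 3-vectors (um).
#' @param geometry a [cell_geometry()].
#' @param p_bind binding probability per collision.
#' @param seed integer seed for the binding draws.
#' @return list with `outcome` (`"no_hit"`, `"reflected"` or `"bound"`),
#'   `mito_id`, `face_id`, `u`, `v`, final `pos`, and `n_collisions`.
#' @export
collide_and_partition <- function(start, end, geometry, p_bind, seed = 1L) {
  b <- geometry$boxes
  out <- collide_partition_cpp(as.numeric(start), as.numeric(end),
                               geometry$cell_dims,
                               as.matrix(b[, c("cx", "cy", "cz")]),
                               as.matrix(b[, c("hx", "hy", "hz")]),
                               p_bind, as.numeric(seed))
  list(outcome = out$outcome,
       mito_id = if (out$mito >= 0) b$id[out$mito + 1L] else NA_integer_,
       face_id = if (out$mito >= 0) out$face else NA_integer_,
       u = out$u, v = out$v, pos = out$pos, n_collisions = out$n_collisions)
}

#' Calibrate the translocation probability for a target membrane fraction
#'
#' Bisection over `p_bind` such that a steady-state run of the given
#' geometry/config reproduces the requested membrane-bound particle fraction
#' (averaged over the final quarter of the recorded series) within `tol`.
#' The calibration runs use a fixed seed, making the result deterministic.
#'
#' @param target_membrane_fraction requested bound fraction in `[0, 1)`.
#' @param k_off retrotranslocation rate (1/s) used during calibration.
#' @param geometry a [cell_geometry()].
#' @param config a [sim_config()] defining particle number, dt and duration
#'   of each calibration run (keep these small).
#' @param tol acceptable absolute deviation of the bound fraction.
#' @param max_iter bisection iteration cap.
#' @return calibrated `p_bind`.
#' @export
calibrate_p_bind <- function(target_membrane_fraction, k_off, geometry,
                             config, tol = 0.02, max_iter = 20L) {
  if (target_membrane_fraction < 0 || target_membrane_fraction >= 1) {
    stop_ms("target membrane fraction must lie in [0, 1)")
  }
  if (target_membrane_fraction == 0) return(0)
  eval_frac <- function(p) {
    cfg <- config
    cfg$species$p_bind <- p
    cfg$species$k_off <- k_off
    run <- run_whole_cell(geometry, cfg)
    ser <- run$series
    tailr <- ser[ser$time >= 0.75 * max(ser$time), , drop = FALSE]
    sum(tailr$n_mem) / sum(tailr$n_mem + tailr$n_cyto)
  }
  hi_frac <- eval_frac(1)
  if (hi_frac < target_membrane_fraction - tol) {
    stop_ms("target membrane fraction %.3f unreachable: bound fraction at p_bind = 1 is %.3f",
            target_membrane_fraction, hi_frac)
  }
  lo <- 0; hi <- 1
  mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- eval_frac(mid)
    if (abs(f - target_membrane_fraction) <= tol) return(mid)
    if (f < target_membrane_fraction) lo <- mid else hi <- mid
  }
  mid
}

#' Write a snapshot with its JSON header
#'
#' One CSV row per particle plus a side-car JSON header carrying time, seed
#' and a hash of the generating configuration.
#'
#' @param run a `whole_cell_run` (or a list with `snapshot`, `config`, `time`).
#' @param path CSV output path; the header is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(run, path) {
  write.csv(run$snapshot, path, row.names = FALSE)
  hdr <- list(time = run$time, seed = run$config$seed,
              config_hash = config_hash(run$config))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  digest_input <- jsonlite::toJSON(unclass(config), digits = NA,
                                   auto_unbox = TRUE, force = TRUE)
  tf <- tempfile()
  writeLines(digest_input, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
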