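## Reduced MCL-1/tBID/BAK interactome at single-mitochondrion resolution.
## All reactions occur in 2D on the mitochondrial outer membrane;
## retrotranslocation is disabled at this stage. Mass-action rates estimated
## at whole-cell scale are rescaled to mitochondrial volume (k_f = k_est *
## V_m / V_c), which makes the per-particle-pair interaction propensity
## independent of the compartment, and are then converted to mesoscopic
## parameters (binding radius, per-step unbinding probability).

#' Species of the reduced MOMP interactome
#'
#' `MCL1` (anti-apoptotic guard), `tBID` (BH3-only activator), `BAK`
#' (inactive effector), `aBAK` (activated BAK), `aBAK2`/`aBAK4`/`aBAK6`
#' (dimer ladder; tetramers and hexamers count as pores), and the inhibitory
#' complexes `tBID_MCL1` and `aBAK_MCL1`.
#'
#' @return character vector of the nine species identifiers.
#' @export
momp_species <- function() {
  c("MCL1", "tBID", "BAK", "aBAK", "aBAK2", "aBAK4", "aBAK6",
    "tBID_MCL1", "aBAK_MCL1")
}

#' Default kinetic rate constants
#'
#' Forward rates are second-order in nM^-1 s^-1 at whole-cell reference and
#' reverse rates first-order in s^-1. The source model's estimated constants
#' are not reproduced here; these defaults span the range typical of
#' deterministic BCL-2 interaction models, rescaled so that pore formation
#' unfolds over tens of seconds at desk-scale cell volumes.
#'
#' @return named list of rate constants.
#' @export
default_rates <- function() {
  list(k_act = 2.0,            # tBID-catalyzed BAK activation
       kf_tBID_MCL1 = 0.1, kr_tBID_MCL1 = 0.02,
       kf_aBAK_MCL1 = 0.1, kr_aBAK_MCL1 = 0.1,
       kf_dimer = 1.5, kr_dimer = 0.01,
       kf_tetramer = 1.5, kr_tetramer = 0.01,
       kf_hexamer = 1.5, kr_hexamer = 0.01)
}

#' The reduced MOMP reaction network
#'
#' Reactions: (R1) `tBID + BAK -> tBID + aBAK` (catalytic activation);
#' (R2) `tBID + MCL1 <-> tBID_MCL1`; (R3) `aBAK + MCL1 <-> aBAK_MCL1`;
#' (R4) `aBAK + aBAK <-> aBAK2`; (R5) `aBAK2 + aBAK2 <-> aBAK4`;
#' (R6) `aBAK4 + aBAK2 <-> aBAK6`. MCL-1 binds activated BAK only; higher
#' oligomers assemble strictly through the dimer ladder.
#'
#' @param rates named list as from [default_rates()].
#' @param explicit_intermediate if `TRUE`, model BAK activation through an
#'   explicit `tBID_BAK`-style reversible encounter instead of catalytic
#'   conversion (not used by the default pipeline).
#' @return data.frame with columns `id, r1, r2, product, catalytic, kf, kr,
#'   reversible`.
#' @export
default_network <- function(rates = default_rates(),
                            explicit_intermediate = FALSE) {
  if (explicit_intermediate) {
    stop_ms("the explicit tBID:BAK intermediate variant is a configuration stub")
  }
  data.frame(
    id = paste0("R", 1:6),
    r1 = c("tBID", "tBID", "aBAK", "aBAK", "aBAK2", "aBAK4"),
    r2 = c("BAK", "MCL1", "MCL1", "aBAK", "aBAK2", "aBAK2"),
    product = c("aBAK", "tBID_MCL1", "aBAK_MCL1", "aBAK2", "aBAK4", "aBAK6"),
    catalytic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    kf = c(rates$k_act, rates$kf_tBID_MCL1, rates$kf_aBAK_MCL1,
           rates$kf_dimer, rates$kf_tetramer, rates$kf_hexamer),
    kr = c(0, rates$kr_tBID_MCL1, rates$kr_aBAK_MCL1, rates$kr_dimer,
           rates$kr_tetramer, rates$kr_hexamer),
    reversible = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
}

# per-species content in BAK-monomer / MCL-1 / tBID equivalents
equivalence_matrix <- function(species = momp_species()) {
  eq <- rbind(
    BAK_eq  = c(MCL1 = 0, tBID = 0, BAK = 1, aBAK = 1, aBAK2 = 2, aBAK4 = 4,
                aBAK6 = 6, tBID_MCL1 = 0, aBAK_MCL1 = 1),
    MCL1_eq = c(MCL1 = 1, tBID = 0, BAK = 0, aBAK = 0, aBAK2 = 0, aBAK4 = 0,
                aBAK6 = 0, tBID_MCL1 = 1, aBAK_MCL1 = 1),
    tBID_eq = c(MCL1 = 0, tBID = 1, BAK = 0, aBAK = 0, aBAK2 = 0, aBAK4 = 0,
                aBAK6 = 0, tBID_MCL1 = 1, aBAK_MCL1 = 0))
  eq[, species, drop = FALSE]
}

#' Stoichiometry matrix of a network
#'
#' One column per elementary direction (forward reactions first, then the
#' reverse of each reversible reaction), one row per species.
#'
#' @param network a [default_network()]-style data.frame.
#' @param species species ordering.
#' @return integer matrix with reaction direction names as columns.
#' @export
stoichiometry_matrix <- function(network, species = momp_species()) {
  cols <- list()
  for (i in seq_len(nrow(network))) {
    v <- setNames(numeric(length(species)), species)
    if (network$catalytic[i]) {
      # r1 is the catalyst: r2 -> product
      v[network$r2[i]] <- v[network$r2[i]] - 1
      v[network$product[i]] <- v[network$product[i]] + 1
    } else {
      v[network$r1[i]] <- v[network$r1[i]] - 1
      v[network$r2[i]] <- v[network$r2[i]] - 1
      v[network$product[i]] <- v[network$product[i]] + 1
    }
    cols[[paste0(network$id[i], "_f")]] <- v
  }
  for (i in which(network$reversible)) {
    cols[[paste0(network$id[i], "_r")]] <- -cols[[paste0(network$id[i], "_f")]]
  }
  S <- do.call(cbind, cols)
  rownames(S) <- species
  S
}

#' Verify equivalence-mass balance of every reaction
#'
#' Each reaction must conserve BAK-monomer, MCL-1 and tBID equivalents;
#' equivalently the equivalence vectors must annihilate the stoichiometry
#' matrix.
#'
#' @param network a network data.frame.
#' @return `TRUE` invisibly; errors naming the offending reaction otherwise.
#' @export
check_mass_balance <- function(network) {
  S <- stoichiometry_matrix(network)
  E <- equivalence_matrix(rownames(S))
  bad <- which(colSums(abs(E %*% S)) > 1e-12)
  if (length(bad)) {
    stop_ms("reaction direction %s violates equivalence mass balance",
            colnames(S)[bad[1]])
  }
  invisible(TRUE)
}

#' Rescale a whole-cell rate to single-mitochondrion resolution
#'
#' `k_f = k_est * V_m / V_c`. With propensities referenced to the local
#' compartment volume this keeps the per-pair interaction rate identical
#' between the whole-cell and single-mitochondrion descriptions.
#'
#' @param k_est whole-cell estimated rate constant.
#' @param V_m mitochondrial volume (um^3).
#' @param V_c cell volume (um^3).
#' @return rescaled rate `k_f`.
#' @export
scale_rate <- function(k_est, V_m, V_c) {
  if (any(V_m <= 0) || any(V_c <= 0)) stop_ms("volumes must be > 0")
  k_est * V_m / V_c
}

#' Per-step unbinding probability from a dissociation rate
#'
#' `p = 1 - exp(-k_r dt)`.
#'
#' @param k_r dissociation rate (1/s), >= 0.
#' @param dt time step (s), > 0.
#' @return per-step probability.
#' @export
kr_to_punbind <- function(k_r, dt) {
  if (any(k_r < 0)) stop_ms("k_r must be >= 0")
  if (any(dt <= 0)) stop_ms("dt must be > 0")
  1 - exp(-k_r * dt)
}

# run a two-species association on a well-mixed periodic patch and estimate
# the realized 2D rate constant from the integrated second-order law
# 1/N(T) - 1/N0 = (k/A) T (equal initial counts); the endpoint uses every
# reaction event and the law is exact for ideal mass action, so the
# estimator noise is ~1/sqrt(events) with negligible bias
measure_k2d <- function(radius, D_sum, dt, patch_dim, n_each, n_steps, seed) {
  sp <- c(rep(0L, n_each), rep(1L, n_each))
  pos <- with_seed(seed, matrix(runif(2 * 2 * n_each, 0, patch_dim), ncol = 2))
  out <- run_reactions_cpp(
    0L, c(patch_dim, patch_dim), 3L, rep(D_sum / 2, 3), sp,
    rep(0L, 2 * n_each), pos[, 1], pos[, 2],
    0L, 1L, 2L, 0L, radius,
    integer(), integer(), integer(), numeric(), numeric(),
    dt, as.integer(n_steps), max(1L, as.integer(n_steps / 50)),
    as.numeric(seed) + 17)
  ser <- out$series
  # read the integrated law at ~50% depletion (or the endpoint when slower):
  # all events up to that record contribute and the estimate stays valid in
  # fast-depleting regimes where the endpoint would saturate
  idx <- which(ser[, 2] <= n_each / 2)
  i <- if (length(idx)) min(idx[idx > 1], nrow(ser)) else nrow(ser)
  if (i <= 1) i <- 2
  n_t <- max(ser[i, 2], 3)
  (1 / n_t - 1 / n_each) / ser[i, 1] * patch_dim^2
}

#' Convert a 2D mass-action rate constant to a binding radius
#'
#' Finds the mesoscopic binding radius at which a well-mixed simulation of
#' `A + B -> C` on a periodic 2D patch reproduces the target mass-action
#' rate `k_f_2D` (um^2/s) within `tol`. The search starts from the
#' step-resampling estimate `r = sqrt(k dt / pi)` (exact when the diffusive
#' step much exceeds the radius) and refines it against simulated estimates
#' averaged over `n_reps` replicate fits.
#'
#' @param k_f_2D target 2D rate constant (um^2/s), >= 0.
#' @param D_sum relative diffusion coefficient of the pair (um^2/s).
#' @param dt reaction-stage time step (s).
#' @param tol relative tolerance on the reproduced rate.
#' @param patch_dim calibration patch edge (um).
#' @param n_each particles of each reactant in the calibration patch.
#' @param n_steps calibration run length (steps).
#' @param n_reps replicate calibration fits to average.
#' @param seed calibration seed.
#' @param max_iter refinement iteration cap.
#' @return binding radius (um); 0 when `k_f_2D` is 0.
#' @export
kf_to_binding_radius <- function(k_f_2D, D_sum, dt, tol = 0.05,
                                 patch_dim = 1, n_each = 200L,
                                 n_steps = 600L, n_reps = 3L, seed = 1L,
                                 max_iter = 8L) {
  if (k_f_2D < 0) stop_ms("k_f_2D must be >= 0")
  if (k_f_2D == 0) return(0)
  r <- sqrt(k_f_2D * dt / pi)
  if (r > patch_dim / 4) {
    stop_ms("required binding radius %.3g um exceeds a quarter of the %.3g um calibration patch",
            r, patch_dim)
  }
  est <- function(radius, iter) {
    ks <- vapply(seq_len(n_reps), function(j) {
      measure_k2d(radius, D_sum, dt, patch_dim, n_each, n_steps,
                  derive_seed(seed, 1000L * iter + j))
    }, numeric(1))
    c(mean(ks), sd(ks) / sqrt(n_reps))
  }
  for (it in seq_len(max_iter)) {
    kh <- est(r, it)
    # accept when within tolerance, or when the misfit is statistically
    # indistinguishable from the measurement noise of the calibration run
    # (the radius is only adjusted on significant, out-of-tolerance misfit)
    if (abs(kh[1] - k_f_2D) <= max(tol * k_f_2D, 2 * kh[2])) return(r)
    # k scales ~ r^2 in the step-resampling regime
    r <- r * sqrt(k_f_2D / kh[1])
    if (r > patch_dim / 4) {
      stop_ms("required binding radius exceeds a quarter of the calibration patch")
    }
  }
  r
}

# cache of calibrated radii keyed by (k2D, D_sum, dt) rounded signatures
.radius_cache <- new.env(parent = emptyenv())

cached_binding_radius <- function(k_f_2D, D_sum, dt, ...) {
  key <- paste(signif(k_f_2D, 6), signif(D_sum, 6), signif(dt, 6), sep = "|")
  if (!is.null(.radius_cache[[key]])) return(.radius_cache[[key]])
  r <- kf_to_binding_radius(k_f_2D, D_sum, dt, ...)
  .radius_cache[[key]] <- r
  r
}

#' Mesoscopic parameters for a network on one mitochondrion
#'
#' Converts each whole-cell second-order rate to a per-reaction binding
#' radius for a mitochondrion of membrane area `area`: the per-pair
#' propensity is `kf / (0.602214076 V_c)` (s^-1), giving a 2D rate constant
#' `k2D = propensity * area` which is calibrated to a binding radius.
#' Reverse rates become per-step unbinding probabilities; the unbinding
#' radius is twice the binding radius (products separate beyond immediate
#' recapture).
#'
#' @param network a [default_network()]-style data.frame.
#' @param area membrane surface area of the mitochondrion (um^2).
#' @param cell_volume whole-cell reference volume (um^3).
#' @param dt reaction-stage time step (s).
#' @param D_mem lateral diffusion coefficient of all membrane species
#'   (um^2/s); the pair-relative coefficient is `2 * D_mem`.
#' @param cache reuse previously calibrated radii for identical
#'   `(k2D, D_sum, dt)` signatures.
#' @param ... passed to [kf_to_binding_radius()].
#' @return data.frame with per-reaction `binding_radius`, `unbinding_radius`
#'   and `p_unbind` joined to the network.
#' @export
build_meso_params <- function(network, area, cell_volume, dt, D_mem = 0.25,
                              cache = TRUE, ...) {
  k2d <- network$kf / (AVOGADRO_PER_NM_UM3 * cell_volume) * area
  # same-species reactions: the engine fires once per unordered pair
  # (N^2/2 pairs) while the mass-action propensity convention is k N^2, so
  # the pair-capture rate must be doubled
  k2d_eff <- k2d * ifelse(network$r1 == network$r2, 2, 1)
  fn <- if (cache) cached_binding_radius else kf_to_binding_radius
  radius <- vapply(k2d_eff, function(k) fn(k, 2 * D_mem, dt, ...), numeric(1))
  data.frame(id = network$id, k2D = k2d, binding_radius = radius,
             unbinding_radius = 2 * radius,
             p_unbind = kr_to_punbind(network$kr, dt))
}

#' Seed a single-mitochondrion reaction state from a whole-cell snapshot
#'
#' Copies the per-species membrane counts of the chosen mitochondrion from
#' the final whole-cell snapshot and redraws particle positions uniformly
#' over the box surface (faces weighted by area). Retrotranslocation is
#' disabled in the downstream reaction stage.
#'
#' @param run a `whole_cell_run` (or a list with `snapshot` and `geometry`).
#' @param mito_id id of the mitochondrion to extract.
#' @param seed integer seed for position redraw.
#' @return a `mito_state` list: `mito_id`, `box` (center, half), `particles`
#'   data.frame (`species, face, u, v`), `area`, `time`.
#' @export
seed_single_mito <- function(run, mito_id, seed = 1L) {
  b <- run$geometry$boxes
  i <- match(mito_id, b$id)
  if (is.na(i)) stop_ms("unknown mito_id %s", mito_id)
  snap <- run$snapshot
  rows <- snap$compartment == "membrane" & snap$mito_id == mito_id
  species <- snap$species[rows & !is.na(snap$mito_id)]
  ctr <- as.numeric(b[i, c("cx", "cy", "cz")])
  half <- as.numeric(b[i, c("hx", "hy", "hz")])
  pos <- with_seed(seed, sample_surface_positions(half, length(species)))
  structure(list(mito_id = mito_id, center = ctr, half = half,
                 particles = data.frame(species = species,
                                        face = pos$face, u = pos$u,
                                        v = pos$v),
                 area = box_surface_area(2 * half), time = 0),
            class = "mito_state")
}

# area-weighted uniform positions on the 6 faces of a box with half extents
sample_surface_positions <- function(half, n) {
  # face f: fixed axis a = f %/% 2, chart axes (a+1)%%3, (a+2)%%3 (0-based)
  dims_u <- 2 * half[((0:5) %/% 2 + 1) %% 3 + 1]
  dims_v <- 2 * half[((0:5) %/% 2 + 2) %% 3 + 1]
  areas <- dims_u * dims_v
  if (n == 0) {
    return(list(face = integer(), u = numeric(), v = numeric()))
  }
  f <- sample.int(6, n, replace = TRUE, prob = areas) - 1L
  list(face = f, u = runif(n, 0, dims_u[f + 1]), v = runif(n, 0, dims_v[f + 1]))
}

state_to_engine <- function(state, species = momp_species()) {
  sp <- match(state$particles$species, species) - 1L
  if (anyNA(sp)) stop_ms("state contains unknown species")
  list(sp = as.integer(sp), face = as.integer(state$particles$face),
       u = state$particles$u, v = state$particles$v)
}

network_to_engine <- function(network, meso, species = momp_species()) {
  bi <- list(rA = match(network$r1, species) - 1L,
             rB = match(network$r2, species) - 1L,
             prod = match(network$product, species) - 1L,
             cat = as.integer(network$catalytic),
             rbind = meso$binding_radius)
  rev <- which(network$reversible & network$kr > 0)
  un <- list(re = match(network$product[rev], species) - 1L,
             p1 = match(network$r1[rev], species) - 1L,
             p2 = match(network$r2[rev], species) - 1L,
             prob = meso$p_unbind[rev],
             rd = meso$unbinding_radius[rev])
  list(bi = bi, un = un)
}

#' Advance a single-mitochondrion reaction state by one step
#'
#' One membrane-diffusion substep followed by bimolecular reactions (each
#' unordered pair within its binding radius reacts; conflicts resolved in
#' randomized order with each particle reacting at most once per step) and
#' unimolecular dissociations (products placed an unbinding radius apart).
#'
#' @param state a `mito_state`.
#' @param network reaction network data.frame.
#' @param meso mesoscopic parameters from [build_meso_params()].
#' @param dt time step (s).
#' @param D_mem membrane diffusion coefficient (um^2/s).
#' @param seed integer seed.
#' @return the updated `mito_state`.
#' @export
step_reactions <- function(state, network, meso, dt, D_mem = 0.25,
                           seed = 1L) {
  run_single_mito(state, network, meso, duration = dt, dt = dt,
                  record_interval = dt, D_mem = D_mem, seed = seed)$state
}

#' Simulate the reaction network on one mitochondrion
#'
#' @param state a `mito_state` from [seed_single_mito()].
#' @param network reaction network data.frame.
#' @param meso mesoscopic parameters from [build_meso_params()].
#' @param duration simulated time (s).
#' @param dt time step (s).
#' @param record_interval recording interval (s).
#' @param D_mem membrane diffusion coefficient (um^2/s).
#' @param seed integer seed; identical seeds reproduce identical series.
#' @return list with `series` (tidy `time, species, count`), terminal
#'   `state`, and `pore_series` (`time, pores`), where pores = aBAK4 + aBAK6.
#' @export
run_single_mito <- function(state, network, meso, duration, dt = 1e-3,
                            record_interval = duration / 20, D_mem = 0.25,
                            seed = 1L) {
  species <- momp_species()
  st <- state_to_engine(state, species)
  net <- network_to_engine(network, meso, species)
  n_steps <- max(1L, as.integer(round(duration / dt)))
  rec <- max(1L, as.integer(round(record_interval / dt)))
  out <- run_reactions_cpp(
    1L, c(state$center, state$half), length(species),
    rep(D_mem, length(species)), st$sp, st$face, st$u, st$v,
    net$bi$rA, net$bi$rB, net$bi$prod, net$bi$cat, net$bi$rbind,
    net$un$re, net$un$p1, net$un$p2, net$un$prob, net$un$rd,
    dt, n_steps, rec, as.numeric(seed))
  ser <- out$series
  series <- do.call(rbind, lapply(seq_along(species), function(k) {
    data.frame(time = ser[, 1] + state$time, species = species[k],
               count = ser[, 1 + k])
  }))
  st2 <- state
  st2$particles <- data.frame(species = species[out$species + 1L],
                              face = out$face, u = out$u, v = out$v)
  st2$time <- state$time + n_steps * dt
  pore <- data.frame(time = ser[, 1] + state$time,
                     pores = ser[, 1 + match("aBAK4", species)] +
                             ser[, 1 + match("aBAK6", species)])
  list(series = series, state = st2, pore_series = pore)
}

#' Simulate a reaction network on a well-mixed periodic patch
#'
#' Used for oracle-equivalence checks: rates are given directly as 2D rate
#' constants (um^2/s) in `network$kf`, converted to binding radii for the
#' patch via [kf_to_binding_radius()].
#'
#' @param patch_dim square patch edge length (um).
#' @param counts named integer vector of initial counts per species.
#' @param network network data.frame with `kf` in um^2/s and `kr` in 1/s.
#' @param duration simulated time (s).
#' @param dt time step (s).
#' @param record_interval recording interval (s).
#' @param D_mem diffusion coefficient of every species (um^2/s).
#' @param seed integer seed.
#' @param ... calibration arguments passed to [kf_to_binding_radius()].
#' @return list with tidy `series` and the `meso` table used.
#' @export
run_wellmixed_patch <- function(patch_dim, counts, network, duration,
                                dt = 1e-3, record_interval = duration / 20,
                                D_mem = 0.25, seed = 1L, ...) {
  species <- momp_species()
  stopifnot(all(names(counts) %in% species))
  kf_eff <- network$kf * ifelse(network$r1 == network$r2, 2, 1)
  radius <- vapply(kf_eff, function(k) {
    cached_binding_radius(k, 2 * D_mem, dt, ...)
  }, numeric(1))
  meso <- data.frame(id = network$id, k2D = network$kf,
                     binding_radius = radius, unbinding_radius = 2 * radius,
                     p_unbind = kr_to_punbind(network$kr, dt))
  n <- sum(counts)
  sp <- rep(match(names(counts), species) - 1L, counts)
  pos <- with_seed(derive_seed(seed, 3L),
                   matrix(runif(2 * n, 0, patch_dim), ncol = 2))
  net <- network_to_engine(network, meso, species)
  n_steps <- max(1L, as.integer(round(duration / dt)))
  rec <- max(1L, as.integer(round(record_interval / dt)))
  out <- run_reactions_cpp(
    0L, c(patch_dim, patch_dim), length(species), rep(D_mem, length(species)),
    as.integer(sp), rep(0L, n), pos[, 1], pos[, 2],
    net$bi$rA, net$bi$rB, net$bi$prod, net$bi$cat, net$bi$rbind,
    net$un$re, net$un$p1, net$un$p2, net$un$prob, net$un$rd,
    dt, n_steps, rec, as.numeric(seed))
  ser <- out$series
  series <- do.call(rbind, lapply(seq_along(species), function(k) {
    data.frame(time = ser[, 1], species = species[k], count = ser[, 1 + k])
  }))
  list(series = series, meso = meso)
}

#' Pore metric: activated-BAK tetramers plus hexamers
#'
#' @param state a `mito_state`, or a named count vector.
#' @return integer `aBAK4 + aBAK6` complex count.
#' @export
pore_metric <- function(state) {
  counts <- if (inherits(state, "mito_state")) {
    table(factor(state$particles$species, levels = momp_species()))
  } else {
    state
  }
  as.integer(counts[["aBAK4"]] + counts[["aBAK6"]])
}

#' Equivalence totals of a state (conservation audit)
#'
#' @param state a `mito_state` or tidy series row set with `species, count`.
#' @return named vector of BAK-, MCL-1- and tBID-equivalents.
#' @export
equivalence_totals <- function(state) {
  if (inherits(state, "mito_state")) {
    cnt <- as.numeric(table(factor(state$particles$species,
                                   levels = momp_species())))
  } else {
    cnt <- state$count[match(momp_species(), state$species)]
    cnt[is.na(cnt)] <- 0
  }
  drop(equivalence_matrix() %*% cnt)
}

#' Write a network definition (reactions, rates, mesoscopic parameters) to JSON
#' @param network network data.frame.
#' @param meso optional mesoscopic parameter table.
#' @param path output path.
#' @return `path` invisibly.
#' @export
network_to_json <- function(network, meso = NULL, path) {
  obj <- list(species = momp_species(), reactions = network)
  if (!is.null(meso)) obj$meso_params <- meso
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
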