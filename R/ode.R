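## Deterministic mass-action twin of the interactome network. Used only as a
## correctness oracle for the particle engine and for rate-scaling
## consistency checks; it never produces headline outputs.

#' Build a mass-action ODE model from a reaction network
#'
#' Propensities are `kf * x[r1] * x[r2] / bimol_divisor` for bimolecular
#' directions and `kr * x[complex]` for reverse directions. Choosing
#' `bimol_divisor = 0.602214076 * volume` gives count-based kinetics in a 3D
#' compartment, `bimol_divisor = area` count-based kinetics on a 2D membrane
#' with `kf` in um^2/s, and `bimol_divisor = 1` plain concentration units.
#'
#' @param network a [default_network()]-style data.frame.
#' @param bimol_divisor scaling divisor for bimolecular propensities.
#' @param species species ordering.
#' @return an `ode_model` list: `species`, stoichiometry `S`, `rates`
#'   function, `conservation` matrix.
#' @export
build_odes <- function(network, bimol_divisor = 1, species = momp_species()) {
  S <- stoichiometry_matrix(network, species)
  kf <- network$kf
  kr <- network$kr
  r1 <- match(network$r1, species)
  r2 <- match(network$r2, species)
  prod_i <- match(network$product, species)
  rev <- which(network$reversible)
  rates <- function(x) {
    fwd <- kf * x[r1] * x[r2] / bimol_divisor
    c(fwd, kr[rev] * x[prod_i[rev]])
  }
  cons <- if (all(species %in% momp_species())) {
    E <- equivalence_matrix(species)
    E[rowSums(abs(E %*% S)) < 1e-12, , drop = FALSE]
  } else {
    # generic left null space of the stoichiometry
    sv <- svd(S, nu = nrow(S))
    null_i <- which(c(sv$d, rep(0, nrow(S) - length(sv$d))) < 1e-10)
    t(sv$u[, null_i, drop = FALSE])
  }
  structure(list(species = species, S = S, rates = rates,
                 conservation = cons,
                 network = network, bimol_divisor = bimol_divisor),
            class = "ode_model")
}

#' Integrate an ODE model
#'
#' Stiff-capable implicit integration (`deSolve::lsoda`). The trajectory is
#' checked for non-negativity (within solver tolerance) and conservation of
#' the model's invariant combinations to relative tolerance `cons_tol`.
#'
#' @param model an `ode_model` from [build_odes()].
#' @param y0 named (or ordered) non-negative initial state.
#' @param times output time grid.
#' @param rtol,atol solver tolerances.
#' @param cons_tol relative conservation drift tolerated before erroring.
#' @return matrix of the trajectory (`time` column plus one per species).
#' @export
integrate_odes <- function(model, y0, times, rtol = 1e-8, atol = 1e-10,
                           cons_tol = 1e-6) {
  if (!is.null(names(y0))) {
    y <- setNames(numeric(length(model$species)), model$species)
    y[names(y0)] <- y0
  } else {
    stopifnot(length(y0) == length(model$species))
    y <- setNames(as.numeric(y0), model$species)
  }
  if (any(y < 0)) stop_ms("initial state must be non-negative")
  deriv <- function(t, x, p) list(drop(model$S %*% model$rates(x)))
  sol <- deSolve::lsoda(y, times, deriv, parms = NULL, rtol = rtol,
                        atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop_ms("ODE integration failed (istate %d)", attr(sol, "istate")[1])
  }
  traj <- as.matrix(sol)
  if (min(traj[, -1]) < -1e3 * atol) {
    stop_ms("ODE trajectory went negative (min %.3g)", min(traj[, -1]))
  }
  if (nrow(model$conservation) > 0) {
    q <- traj[, -1, drop = FALSE] %*% t(model$conservation)
    ref <- pmax(abs(q[1, ]), atol)
    drift <- apply(abs(sweep(q, 2, q[1, ])), 2, max) / ref
    if (any(drift > cons_tol)) {
      stop_ms("conserved quantity drifted by relative %.3g", max(drift))
    }
  }
  traj
}

#' Whole-cell vs summed single-mitochondrion kinetics under rate rescaling
#'
#' Demonstrates the volume-scaling consistency of the single-mitochondrion
#' stage: rescaling second-order rates by `V_m / V_c` (see [scale_rate()])
#' while referencing propensities to the local volume leaves the
#' per-particle-pair rate unchanged, so `m` equal mitochondria sharing the
#' cell's molecules evolve, in sum, exactly like the whole-cell ODE run at
#' per-mitochondrion amounts.
#'
#' @param network a network data.frame with whole-cell rates (nM^-1 s^-1).
#' @param counts named whole-cell molecule counts.
#' @param V_c cell volume (um^3).
#' @param m number of equal mitochondria partitioning volume and molecules.
#' @param times output time grid (s).
#' @return list with `whole_cell` and `summed_mito` trajectories and their
#'   maximum relative deviation `max_rel_dev`.
#' @export
eq1_consistency <- function(network, counts, V_c, m, times) {
  y0 <- setNames(numeric(length(momp_species())), momp_species())
  y0[names(counts)] <- counts
  # whole-cell count kinetics at per-mitochondrion amounts, times m
  mod_cell <- build_odes(network, bimol_divisor = AVOGADRO_PER_NM_UM3 * V_c)
  cell <- integrate_odes(mod_cell, y0 / m, times)
  whole <- cell
  whole[, -1] <- cell[, -1] * m
  # one mitochondrion of volume V_c / m with Eq.-scaled rates, summed over m
  V_m <- V_c / m
  net_m <- network
  net_m$kf <- scale_rate(network$kf, V_m, V_c)
  mod_mito <- build_odes(net_m, bimol_divisor = AVOGADRO_PER_NM_UM3 * V_m)
  mito <- integrate_odes(mod_mito, y0 / m, times)
  summed <- mito
  summed[, -1] <- mito[, -1] * m
  ref <- max(abs(whole[, -1]))
  dev <- max(abs(summed[, -1] - whole[, -1])) / ref
  list(whole_cell = whole, summed_mito = summed, max_rel_dev = dev)
}

#' Write an ODE trajectory to CSV
#' @param traj trajectory matrix from [integrate_odes()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
trajectory_to_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
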