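## Synthetic inputs: microscopy-like images of mitochondrial populations
## with known ground-truth sizes, scenario configuration generators with the
## study concentrations, and well-mixed calibration fixtures. Everything is
## seed-deterministic and carries its generating spec for provenance.

#' Specification for a synthetic mitochondrial image
#'
#' Objects are ellipses with log-normally distributed pixel areas
#' (right-skewed, as mitochondrial size distributions typically are),
#' rasterized on a dark background, optionally blurred with a Gaussian PSF
#' and corrupted with additive Gaussian noise.
#'
#' @param width,height image size in pixels.
#' @param pixel_size optional pixel edge length (um).
#' @param n_objects number of mitochondria.
#' @param median_px median object area in pixels.
#' @param sigma_log log-scale standard deviation of the area distribution.
#' @param subset_rule list: `type` is `"smallest_fraction"` or
#'   `"random_fraction"`, `fraction` in (0, 1]; selects the labeled subset
#'   (e.g. mitochondria undergoing or escaping MOMP).
#' @param subset_label population label of the subset.
#' @param blur_sigma Gaussian blur sigma in pixels (0 for none).
#' @param background,foreground intensities on the 8-bit scale.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(width = 512L, height = 512L,
                                 pixel_size = NULL, n_objects = 120L,
                                 median_px = 60, sigma_log = 0.45,
                                 subset_rule = list(type = "smallest_fraction",
                                                    fraction = 0.1),
                                 subset_label = "undergoing_MOMP",
                                 blur_sigma = 0, background = 30,
                                 foreground = 200, noise_sd = 0, seed = 1L) {
  stopifnot(n_objects >= 1, median_px > 0, sigma_log >= 0,
            subset_rule$fraction > 0, subset_rule$fraction <= 1,
            foreground > background)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_objects = as.integer(n_objects),
                 median_px = median_px, sigma_log = sigma_log,
                 subset_rule = subset_rule, subset_label = subset_label,
                 blur_sigma = blur_sigma, background = background,
                 foreground = foreground, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# separable Gaussian blur with reflected edges
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_filter <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    padded <- m[pmin(pmax(idx, 1), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_filter(t(pad_filter(image))))
}

#' Generate a synthetic mitochondrial image with ground truth
#'
#' Rasterizes non-overlapping ellipses, records pre-blur pixel areas as
#' ground truth, then applies blur and noise per the spec. Deterministic
#' under the spec's seed.
#'
#' @param spec a [synthetic_image_spec()].
#' @param max_attempts placement attempts per object before erroring.
#' @return list with `image` (numeric matrix, 0..255), `truth` (SizeTable
#'   data.frame with subset labels), and `spec`.
#' @export
make_image <- function(spec, max_attempts = 5000L) {
  with_seed(spec$seed, {
    n <- spec$n_objects
    areas <- rlnorm(n, meanlog = log(spec$median_px), sdlog = spec$sigma_log)
    aspect <- runif(n, 1.6, 3.2)
    angle <- runif(n, 0, pi)
    b_ax <- sqrt(areas / (pi * aspect))  # semi-minor
    a_ax <- aspect * b_ax                # semi-major
    margin <- 2 + 3 * spec$blur_sigma
    ctr <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- c(runif(1, a_ax[i] + margin, spec$height - a_ax[i] - margin),
               runif(1, a_ax[i] + margin, spec$width - a_ax[i] - margin))
        if (i == 1) { placed <- TRUE } else {
          prev <- ctr[seq_len(i - 1), , drop = FALSE]
          dmin <- sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2)
          placed <- all(dmin > a_ax[i] + a_ax[seq_len(i - 1)] + margin)
        }
        if (placed) { ctr[i, ] <- p; break }
      }
      if (!placed) {
        stop_ms("could not place object %d of %d without overlap; reduce n_objects or sizes",
                i, n)
      }
    }
    img <- matrix(spec$background, spec$height, spec$width)
    true_px <- integer(n)
    for (i in seq_len(n)) {
      rr <- floor(ctr[i, 1] - a_ax[i]):ceiling(ctr[i, 1] + a_ax[i])
      cc <- floor(ctr[i, 2] - a_ax[i]):ceiling(ctr[i, 2] + a_ax[i])
      rr <- rr[rr >= 1 & rr <= spec$height]
      cc <- cc[cc >= 1 & cc <= spec$width]
      dy <- outer(rr - ctr[i, 1], rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - ctr[i, 2])
      xr <- dx * cos(angle[i]) + dy * sin(angle[i])
      yr <- -dx * sin(angle[i]) + dy * cos(angle[i])
      inside <- (xr / a_ax[i])^2 + (yr / b_ax[i])^2 <= 1
      true_px[i] <- sum(inside)
      img[rr, cc][inside] <- spec$foreground
    }
    subset <- switch(spec$subset_rule$type,
      smallest_fraction = {
        k <- max(1L, as.integer(round_half_away(spec$subset_rule$fraction * n)))
        order(true_px)[seq_len(k)]
      },
      random_fraction = {
        k <- max(1L, as.integer(round_half_away(spec$subset_rule$fraction * n)))
        sample.int(n, k)
      },
      stop_ms("unknown subset rule '%s'", spec$subset_rule$type))
    img <- gaussian_blur(img, spec$blur_sigma)
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    }
    img <- pmin(pmax(img, 0), 255)
    truth <- data.frame(
      object_id = seq_len(n),
      pixel_area = true_px,
      physical_area = if (is.null(spec$pixel_size)) NA_real_ else
        true_px * spec$pixel_size^2,
      population = ifelse(seq_len(n) %in% subset, spec$subset_label, "all"))
    list(image = img, truth = truth, spec = spec)
  })
}

## ---------------------------------------------------------------------------
## Scenario configurations

# reference (unscaled) model cell: 2500 um^3 with 120 mitochondria of
# 1.5 x 0.5 x 0.5 um on a 6 x 4 x 5 lattice
REF_CELL_DIMS <- c(25, 10, 10)
REF_N_MITO <- 120L
REF_MITO_DIMS <- c(1.5, 0.5, 0.5)

# translocation defaults shared by all scenarios: exchange kinetics chosen so
# the membrane-bound steady state (~65% for MCL-1) is reached within a few
# seconds of simulated time at desk scale
default_translocation_params <- function() {
  list(D_cyto = 10, D_mem = 0.25, dt = 1.9e-4, duration = 1,
       record_interval = 0.15,
       MCL1 = list(p_bind = 0.008, k_off = 1.0),
       tBID = list(p_bind = 0.0373, k_off = 1.0),
       BAK = list(p_bind = 0.05, k_off = 0.01))
}

#' Build a full pipeline configuration for a study scenario
#'
#' Emits the configuration of one of the five simulation scenarios with the
#' study concentrations embedded: `fig1_sweep` (surface-area sweep at
#' conserved volume, 101 nM MCL-1), `fig2_arrangements` (regular vs random
#' vs polarized arrangements), `fig3_fragmentation` (10% fragmentation at
#' conserved volume, MCL-1 sweep 10/101/400 nM), `fig4_strong_tBID` (10 nM
#' tBID) and `fig5_weak_tBID` (2 nM tBID). Cell volume is scaled by
#' `scale_factor` (mitochondrial count and size unchanged) for desk-scale
#' particle numbers; three replicate seeds are derived per scenario.
#'
#' @param scenario scenario name.
#' @param scale_factor cell-volume scale factor in (0, 1].
#' @param seed master seed; replicate seeds derive from it.
#' @param n_mito mitochondrial count; defaults to 120 (the arrangement
#'   comparison uses a larger count at larger scale factors so the
#'   mitochondrial packing density of the reference desk-scale cell is
#'   preserved).
#' @return a config list consumed by [run_scenario()].
#' @export
make_experiment_config <- function(scenario = c("fig1_sweep",
                                                "fig2_arrangements",
                                                "fig3_fragmentation",
                                                "fig4_strong_tBID",
                                                "fig5_weak_tBID"),
                                   scale_factor = 1, seed = 1L,
                                   n_mito = NULL) {
  scenario <- match.arg(scenario)
  if (scale_factor <= 0 || scale_factor > 1) {
    stop_ms("scale_factor must lie in (0, 1]")
  }
  tp <- default_translocation_params()
  cell_dims <- REF_CELL_DIMS * scale_factor^(1 / 3)
  base <- list(scenario = scenario, scale_factor = scale_factor,
               seed = as.integer(seed),
               cell_dims = cell_dims, n_mito = n_mito %||% REF_N_MITO,
               mito_dims = REF_MITO_DIMS,
               translocation = tp,
               replicate_seeds = derive_seed(seed, 1:3 * 101L),
               n_replicates = 3L)
  extra <- switch(scenario,
    fig1_sweep = list(
      mcl1_nM = 101,
      area_factors = c(1, 8 / 7, 9 / 7, 11 / 7),
      # finer splitting makes thinner boxes; the step-size invariant then
      # requires a smaller dt
      dt = 7e-5),
    fig2_arrangements = list(
      mcl1_nM = 101,
      arrangements = c("regular", "random", "polarized_x", "polarized_y",
                       "polarized_z")),
    fig3_fragmentation = list(
      mcl1_nM = 101,
      concentrations_nM = c(10, 101, 400),
      fragment_fraction = 0.1,
      fragments_per_replacement = 3L),
    fig4_strong_tBID = list(
      mcl1_nM = 101, bak_nM = 50, tbid_nM = 10,
      fragment_fraction = 0.1, fragments_per_replacement = 3L,
      reaction = list(duration = 60, dt = 2e-3, record_interval = 4)),
    fig5_weak_tBID = list(
      mcl1_nM = 101, bak_nM = 50, tbid_nM = 2,
      fragment_fraction = 0.1, fragments_per_replacement = 3L,
      reaction = list(duration = 60, dt = 2e-3, record_interval = 4)))
  c(base, extra)
}

#' Well-mixed 2D calibration fixture
#'
#' Uniform random placements of two reactant populations on a periodic
#' patch, with the matching deterministic mass-action reference trajectory
#' attached (`A + B <-> C` with 2D rate constants).
#'
#' @param n_A,n_B initial particle counts.
#' @param k_f forward 2D rate constant (um^2/s).
#' @param k_r reverse rate (1/s).
#' @param patch_size patch edge length (um).
#' @param dt reaction time step (s).
#' @param duration reference trajectory duration (s).
#' @param seed integer seed.
#' @return list with `positions`, `species`, the generating parameters and
#'   the ODE `reference` trajectory (counts of A, B, C over time).
#' @export
make_wellmixed_fixture <- function(n_A, n_B, k_f, k_r, patch_size = 1,
                                   dt = 1e-3, duration = 10, seed = 1L) {
  stopifnot(n_A >= 0, n_B >= 0, k_f >= 0, k_r >= 0, patch_size > 0, dt > 0)
  n <- n_A + n_B
  pos <- with_seed(seed, matrix(runif(2 * n, 0, patch_size), ncol = 2))
  species <- c(rep("A", n_A), rep("B", n_B))
  net <- data.frame(id = "R1", r1 = "A", r2 = "B", product = "C",
                    catalytic = FALSE, kf = k_f, kr = k_r,
                    reversible = k_r > 0)
  S <- matrix(c(-1, -1, 1), ncol = 1, dimnames = list(c("A", "B", "C"), "f"))
  if (k_r > 0) S <- cbind(S, r = -S[, 1])
  model <- structure(list(species = c("A", "B", "C"), S = S,
                          rates = function(x) {
                            f <- k_f * x[1] * x[2] / patch_size^2
                            if (k_r > 0) c(f, k_r * x[3]) else f
                          },
                          conservation = rbind(A_eq = c(1, 0, 1),
                                               B_eq = c(0, 1, 1))),
                     class = "ode_model")
  times <- seq(0, duration, length.out = 50)
  ref <- integrate_odes(model, c(A = n_A, B = n_B, C = 0), times)
  list(positions = pos, species = species, n_A = n_A, n_B = n_B, k_f = k_f,
       k_r = k_r, patch_size = patch_size, dt = dt, seed = seed,
       network = net, reference = ref)
}
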