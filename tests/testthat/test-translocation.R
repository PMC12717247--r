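test_that("concentration/count conversions follow Avogadro scaling", {
  expect_equal(concentration_to_count(0, 100), 0L)
  # 101 nM in 2500 um^3: 101 * 0.602214076 * 2500
  expect_equal(concentration_to_count(101, 2500), 152059L)
  expect_error(concentration_to_count(-1, 10), ">= 0")
  # roundtrip within rounding
  n <- concentration_to_count(37.5, 800)
  expect_equal(concentration_to_count(count_to_concentration(n, 800), 800), n)
})

test_that("config validation enforces the step-size invariant and inputs", {
  g <- one_box_cell(half = c(0.1, 0.1, 0.1))
  st <- mcl1_species()
  expect_error(validate_sim_config(sim_config(st, dt = 1e-3, duration = 1), g),
               "RMS step")
  expect_silent(validate_sim_config(sim_config(st, dt = 1e-5, duration = 1), g))
  expect_error(sim_config(st[, -3], dt = 1e-4, duration = 1), "missing")
  expect_error(sim_config(st, dt = 0, duration = 1), "dt")
})

test_that("cytosolic steps are Gaussian with variance 2 D dt", {
  g <- cell_geometry(c(20, 20, 20))  # empty: pure diffusion
  st <- mcl1_species()
  cfg <- sim_config(st, dt = 2e-4, duration = 1, seed = 3)
  n <- 34000
  snap <- data.frame(species = "MCL1", compartment = "cytosol",
                     mito_id = NA_integer_, face_id = NA_integer_,
                     x = runif(n, -5, 5), y = runif(n, -5, 5),
                     z = runif(n, -5, 5), u = NA_real_, v = NA_real_)
  # D = 0: static
  cfg0 <- cfg
  cfg0$species$D_cyto <- 0
  s0 <- step_cytosol(snap, g, cfg0, seed = 5)
  expect_equal(s0$x, snap$x)
  # displacement variance ~ 2 D dt within 3 standard errors (1e5 samples)
  s1 <- step_cytosol(snap, g, cfg, seed = 6)
  d <- c(s1$x - snap$x, s1$y - snap$y, s1$z - snap$z)
  v_target <- 2 * 10 * 2e-4
  se <- v_target * sqrt(2 / (length(d) - 1))
  expect_lt(abs(var(d) - v_target), 3 * se)
})

test_that("periodic wrap returns particles on the opposite side", {
  g <- cell_geometry(c(4, 4, 4))
  st <- mcl1_species()
  cfg <- sim_config(st, dt = 1e-3, duration = 1, seed = 1)
  snap <- data.frame(species = "MCL1", compartment = "cytosol",
                     mito_id = NA_integer_, face_id = NA_integer_,
                     x = 1.999, y = 0, z = 0, u = NA_real_, v = NA_real_)
  out <- replicate(50, {
    s <- step_cytosol(snap, g, cfg, seed = sample.int(1e6, 1))
    s$x
  })
  expect_true(all(out >= -2 & out <= 2))
  expect_true(any(out < 0))  # wrapped to near -L/2
})

test_that("segment collisions hit the correct face and obey p_bind extremes", {
  g <- one_box_cell()
  hit <- collide_and_partition(c(1, 0, 0), c(0, 0, 0), g, p_bind = 1, seed = 2)
  expect_equal(hit$outcome, "bound")
  expect_equal(hit$mito_id, 1L)
  expect_equal(hit$face_id, 0L)  # +x face
  expect_equal(hit$u, 0.5)       # face center
  expect_equal(hit$v, 0.5)
  refl <- collide_and_partition(c(1, 0, 0), c(0, 0, 0), g, p_bind = 0, seed = 2)
  expect_equal(refl$outcome, "reflected")
  # specular: reflected back to the start (up to the re-detection nudge)
  expect_equal(refl$pos, c(1, 0, 0), tolerance = 1e-6)
  far <- collide_and_partition(c(3, 3, 3), c(3, 3, 2.5), g, 1, seed = 2)
  expect_equal(far$outcome, "no_hit")
})

test_that("binding frequency matches p_bind within the binomial 99% CI", {
  g <- one_box_cell()
  n_hit <- 10000
  bound <- vapply(seq_len(n_hit), function(i) {
    collide_and_partition(c(1, 0.1, -0.1), c(0, 0.1, -0.1), g, 0.3,
                          seed = i)$outcome == "bound"
  }, logical(1))
  ci <- qnorm(c(0.005, 0.995), 0.3, sqrt(0.3 * 0.7 / n_hit))
  expect_gt(mean(bound), ci[1])
  expect_lt(mean(bound), ci[2])
})

test_that("membrane diffusion is static at D = 0 and obeys the Einstein relation", {
  g <- one_box_cell(half = c(5, 5, 5), L = c(20, 20, 20))
  st <- species_params("MCL1", 1, 10, 0.25, 0.01, 0)
  n <- 4000
  snap <- data.frame(species = "MCL1", compartment = "membrane",
                     mito_id = 1L, face_id = 0L, x = NA_real_, y = NA_real_,
                     z = NA_real_, u = runif(n, 4, 6), v = runif(n, 4, 6))
  cfg0 <- sim_config(st, dt = 1e-3, duration = 1, seed = 1)
  cfg0$species$D_mem <- 0
  s0 <- step_membrane(snap, g, cfg0, seed = 2)
  expect_equal(s0$u, snap$u)
  # MSD over 50 steps of dt = 1e-3 on a large face: 4 D t
  cfg <- sim_config(st, dt = 1e-3, duration = 1, seed = 1)
  s <- snap
  for (i in 1:50) s <- step_membrane(s, g, cfg, seed = 100 + i)
  stay <- s$face_id == 0L  # restrict to particles that never left the face
  msd <- mean((s$u[stay] - snap$u[stay])^2 + (s$v[stay] - snap$v[stay])^2)
  target <- 4 * 0.25 * 50 * 1e-3
  expect_lt(abs(msd - target) / target, 0.1)
})

test_that("edge-crossing membrane steps land on the adjacent face", {
  out <- membrane_step_cpp(c(0, 0, 0), c(0.5, 0.5, 0.5), 0L, 0.9, 0.5, 0.3, 0)
  expect_equal(out$face, 2L)  # +x face across the +u edge lands on +y
  expect_equal(out$pos[2], 0.5)       # on the +y plane
  expect_equal(out$pos[1], 0.3)       # folded path continues down in x
  expect_equal(out$pos[3], 0)
  # path length is preserved across the fold
  d_on_old <- 0.1; d_on_new <- 0.2
  expect_equal(d_on_old + d_on_new, 0.3)
})

test_that("retrotranslocation releases with rate k_off", {
  expect_equal(kr_to_punbind(0, 0.1), 0)
  expect_equal(kr_to_punbind(log(2) / 0.1, 0.1), 0.5)
  g <- one_box_cell()
  st <- species_params("MCL1", 1, 10, 0.25, 0, 2)
  cfg <- sim_config(st, dt = 5e-3, duration = 1, seed = 1)
  n <- 10000
  snap <- data.frame(species = "MCL1", compartment = "membrane",
                     mito_id = 1L, face_id = 2L, x = NA_real_, y = NA_real_,
                     z = NA_real_, u = runif(n, 0, 1), v = runif(n, 0, 1))
  # k_off = 0: nothing released
  cfg0 <- cfg
  cfg0$species$k_off <- 0
  expect_true(all(retrotranslocate(snap, g, cfg0, 3)$compartment == "membrane"))
  # residence times follow an exponential with rate k_off
  s <- snap
  release_step <- rep(NA_integer_, n)
  for (step in 1:600) {
    s2 <- retrotranslocate(s, g, cfg, seed = 5000 + step)
    newly <- s$compartment == "membrane" & s2$compartment == "cytosol"
    release_step[newly] <- step
    # released particles sit 1 nm outside the face they left
    if (any(newly)) {
      expect_true(all(s2$y[newly] > 0.5))
    }
    s <- s2
    s[s$compartment == "cytosol", c("x", "y", "z")] <- NA  # park released
    if (!anyNA(release_step)) break
  }
  times <- release_step[!is.na(release_step)] * 5e-3
  expect_gt(length(times), 9000)
  ks <- suppressWarnings(ks.test(times, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("whole-cell runs conserve particles and keep cytosol out of boxes", {
  g <- small_cell()
  st <- mcl1_species(conc = 30, p_bind = 0.02, k_off = 2)
  cfg <- sim_config(st, dt = 1.5e-4, duration = 0.6, record_interval = 0.05,
                    seed = 11)
  run <- run_whole_cell(g, cfg)
  # exact conservation at every recorded time
  expect_true(all(run$series$n_cyto + run$series$n_mem ==
                    concentration_to_count(30, prod(g$cell_dims))))
  # no cytosolic particle inside any mitochondrion
  cyto <- run$snapshot[run$snapshot$compartment == "cytosol", ]
  b <- g$boxes
  inside <- rep(FALSE, nrow(cyto))
  for (i in seq_len(nrow(b))) {
    inside <- inside | (abs(cyto$x - b$cx[i]) < b$hx[i] &
                        abs(cyto$y - b$cy[i]) < b$hy[i] &
                        abs(cyto$z - b$cz[i]) < b$hz[i])
  }
  expect_equal(sum(inside), 0)
  # collision counters are non-negative and the per-mito table is complete
  expect_true(all(run$per_mito$collisions >= 0))
  expect_equal(sort(unique(run$per_mito$mito_id)), sort(b$id))
  # p_bind = 0 keeps the membrane empty
  cfg0 <- cfg
  cfg0$species$p_bind <- 0
  run0 <- run_whole_cell(g, cfg0)
  expect_true(all(run0$series$n_mem == 0))
})

test_that("identical seeds give bit-identical runs, different seeds differ", {
  g <- small_cell()
  st <- mcl1_species(conc = 10)
  cfg <- sim_config(st, dt = 1.5e-4, duration = 0.2, seed = 21)
  r1 <- run_whole_cell(g, cfg)
  r2 <- run_whole_cell(g, cfg)
  expect_identical(r1$snapshot, r2$snapshot)
  expect_identical(r1$series, r2$series)
  cfg$seed <- 22L
  r3 <- run_whole_cell(g, cfg)
  expect_false(identical(r1$snapshot, r3$snapshot))
})

test_that("steady-state flux balances collisions against release", {
  g <- small_cell()
  st <- mcl1_species(conc = 60, p_bind = 0.01, k_off = 3)
  cfg <- sim_config(st, dt = 1.5e-4, duration = 2, record_interval = 0.05,
                    seed = 31, collide_from = 1)
  run <- run_whole_cell(g, cfg)
  ser <- run$series[run$series$time >= 1, ]
  n_cyto <- mean(ser$n_cyto)
  n_mem <- mean(ser$n_mem)
  coll_rate <- sum(run$per_mito$collisions) / 1  # collisions/s in [1, 2] s
  bind_flux <- coll_rate * 0.01
  release_flux <- n_mem * 3
  # binding and release fluxes agree at steady state (few-percent tolerance,
  # MC noise plus the small per-step discretization of the release hazard)
  expect_lt(abs(bind_flux - release_flux) / release_flux, 0.1)
})

test_that("p_bind calibration is monotone and self-consistent", {
  g <- small_cell()
  st <- mcl1_species(conc = 25)
  cfg <- sim_config(st, dt = 1.5e-4, duration = 1.2, record_interval = 0.1,
                    seed = 41)
  expect_equal(calibrate_p_bind(0, 1, g, cfg), 0)
  p1 <- calibrate_p_bind(0.4, 2, g, cfg)
  p2 <- calibrate_p_bind(0.7, 2, g, cfg)
  expect_gt(p2, p1)
  cfg2 <- cfg
  cfg2$species$p_bind <- p1
  cfg2$species$k_off <- 2
  cfg2$seed <- 99L
  run <- run_whole_cell(g, cfg2)
  ser <- run$series[run$series$time >= 0.9, ]
  frac <- sum(ser$n_mem) / sum(ser$n_mem + ser$n_cyto)
  expect_lt(abs(frac - 0.4), 0.05)
})
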