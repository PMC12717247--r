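test_that("densities divide per-mito counts by volume and area", {
  g <- one_box_cell(half = c(0.75, 0.25, 0.25))
  snap <- data.frame(species = "MCL1",
                     compartment = c(rep("membrane", 10), "cytosol"),
                     mito_id = c(rep(1L, 10), NA), face_id = c(rep(0L, 10), NA),
                     x = 0, y = 0, z = 0, u = 0.1, v = 0.1)
  d <- densities(snap, g)
  expect_equal(d$count, 10)
  expect_equal(d$count_per_area, 10 / 3.5)
  expect_equal(d$count_per_volume, 10 / 0.375)
  expect_equal(d$count_per_area * d$area, d$count)
  # empty mitochondrion: zero densities
  snap0 <- snap[11, ]
  expect_equal(densities(snap0, g)$count_per_area, 0)
  snap_bad <- snap
  snap_bad$mito_id[1] <- 7L
  expect_error(densities(snap_bad, g), "unknown")
})

test_that("Mann-Whitney matches exact enumeration and is rank-invariant", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 0.1)  # 2 of 20 assignments are as extreme
  expect_equal(mw$p, enumerate_mw_p(c(1, 2, 3), c(4, 5, 6)))
  x <- c(0.3, 1.2, 2.5, 4.1)
  y <- c(0.9, 1.9, 3.3)
  expect_equal(mann_whitney(x, y)$p, enumerate_mw_p(x, y))
  # identical samples: U = n1 n2 / 2 and p near 1
  ident <- mann_whitney(1:6, 1:6)
  expect_equal(unname(ident$U), 18)
  expect_gt(ident$p, 0.9)
  # invariance under strictly monotone transforms
  expect_equal(mann_whitney(exp(x), exp(y))$p, mann_whitney(x, y)$p)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("Kruskal-Wallis with Dunn matches a hand-rank computation", {
  gs <- list(a = c(1, 5, 8, 11), b = c(2, 6, 9, 12), c = c(3, 7, 10, 13))
  kd <- kruskal_dunn(gs)
  # hand computation of tie-free H on the 3 x 4 toy table
  x <- unlist(gs)
  r <- rank(x)
  N <- 12
  Ri <- tapply(r, rep(names(gs), each = 4), sum)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / 4) - 3 * (N + 1)
  expect_equal(unname(kd$H), unname(H))
  # permuting group order leaves every p unchanged
  kd2 <- kruskal_dunn(gs[c(3, 1, 2)])
  expect_equal(kd$p, kd2$p)
  expect_equal(sort(kd$pairwise$p), sort(kd2$pairwise$p))
  # identical groups: H = 0, p = 1 (ties fully corrected)
  kd0 <- kruskal_dunn(list(a = 1:4, b = 1:4, c = 1:4))
  expect_equal(unname(kd0$H), 0)
  expect_equal(kd0$p, 1)
  expect_error(kruskal_dunn(list(1:3, 4:6)), "mann_whitney")
})

test_that("Levene and Brown-Forsythe match ANOVA on absolute deviations", {
  g1 <- c(1, 2, 3, 4)
  gs <- list(a = g1, b = g1)
  expect_equal(levene(gs)$W, 0)
  expect_equal(levene(gs)$p, 1)
  expect_equal(brown_forsythe(gs)$W, 0)
  # toy two-group case against a direct ANOVA on |x - center|
  a <- c(2, 4, 6, 9)
  b <- c(1, 1.5, 2, 2.4)
  for (center in c("mean", "median")) {
    fn <- if (center == "mean") levene else brown_forsythe
    dev_a <- abs(a - do.call(center, list(a)))
    dev_b <- abs(b - do.call(center, list(b)))
    fit <- anova(lm(d ~ g, data.frame(d = c(dev_a, dev_b),
                                      g = rep(c("a", "b"), each = 4))))
    res <- fn(list(a = a, b = b))
    expect_equal(res$W, fit[1, "F value"])
    expect_equal(res$p, fit[1, "Pr(>F)"])
  }
  expect_error(levene(list(a = 1:3)), ">= 2 groups")
  expect_error(levene(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("D'Agostino-Pearson calibrates under normality and detects heavy tails", {
  # frozen cross-check values computed with an independent reference
  # implementation of the K^2 omnibus test on fixed inputs
  x_ref <- c(-1.2, 0.4, 0.1, 2.3, -0.6, 1.1, -1.8, 0.9, 0.3, -0.2,
             1.7, -0.9, 0.5, -1.4, 2.0, 0.8, -0.1, 0.6, -2.2, 1.3)
  res <- dagostino_pearson(x_ref)
  expect_equal(res$K2, 0.4988263, tolerance = 1e-6)
  expect_equal(res$p, 0.7792580, tolerance = 1e-6)
  expect_equal(res$z_skew, -0.4786322, tolerance = 1e-6)
  expect_equal(res$z_kurt, -0.5193625, tolerance = 1e-6)
  # mirror symmetry: identical K^2 for x and -x
  expect_equal(dagostino_pearson(-x_ref)$K2, res$K2)
  expect_error(dagostino_pearson(rnorm(10)), "n >= 20")
  # size: non-rejection rate at alpha = 0.05 for normal samples
  set.seed(71)
  p_norm <- replicate(200, dagostino_pearson(rnorm(100))$p)
  expect_gt(mean(p_norm > 0.05), 0.95 - 3 * sqrt(0.05 * 0.95 / 200))
  # power: heavy-tailed t_2 samples rejected nearly always
  set.seed(72)
  p_t2 <- replicate(200, dagostino_pearson(rt(500, df = 2))$p)
  expect_gte(mean(p_t2 < 0.05), 0.95)
})

test_that("one-phase decay fits recover exact parameters and beat linear fits", {
  x <- seq(0, 10, length.out = 12)
  y <- (5 - 1) * exp(-0.3 * x) + 1
  fit <- one_phase_decay_fit(x, y)
  expect_false(fit$degenerate)
  expect_equal(fit$y0, 5, tolerance = 1e-6)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  # constant input flagged degenerate
  fit0 <- one_phase_decay_fit(x, rep(2, 12))
  expect_true(fit0$degenerate)
  expect_equal(fit0$plateau, 2)
  # saturating noisy data: decay residuals below a straight line's
  set.seed(5)
  y2 <- 4 * exp(-0.5 * x) + 0.8 + rnorm(12, 0, 0.02)
  fit2 <- one_phase_decay_fit(x, y2)
  lin <- lm(y2 ~ x)
  expect_lt(fit2$sse, sum(resid(lin)^2))
  expect_error(one_phase_decay_fit(x[1:3], y[1:3]), "4 points")
})

test_that("surface density maps conserve counts and detect uniform coverage", {
  g <- one_box_cell(half = c(0.75, 0.25, 0.25))
  n <- 6000
  pos <- with_seed(8, mompsim:::sample_surface_positions(c(0.75, 0.25, 0.25), n))
  snap <- data.frame(species = "MCL1", compartment = "membrane", mito_id = 1L,
                     face_id = pos$face, x = NA, y = NA, z = NA,
                     u = pos$u, v = pos$v)
  maps <- surface_density_map(snap, g, 1L, bins = 4)
  expect_equal(sum(unlist(maps)), n)
  # uniformity: chi-square on bin counts scaled by bin areas, per face
  areas <- c(0.25, 0.25, 0.75, 0.75, 0.75, 0.75)
  obs <- vapply(maps, sum, numeric(1))
  cs <- chisq.test(obs, p = areas / sum(areas))
  expect_gt(cs$p.value, 0.01)
  # empty mitochondrion: all-zero map
  maps0 <- surface_density_map(snap[0, ], g, 1L, bins = 4)
  expect_equal(sum(unlist(maps0)), 0)
  expect_error(surface_density_map(snap, g, 42L), "unknown")
})
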