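test_that("box surface area follows the closed form and rejects degenerate boxes", {
  expect_equal(box_surface_area(c(1, 1, 1)), 6)
  expect_equal(box_surface_area(c(2, 1, 0.5)), 7)
  expect_error(box_surface_area(c(1, 0, 1)), "edge lengths")
  expect_error(mito_box(1, c(0, 0, 0), c(0.5, 0, 0.5)), "half_extents")
})

test_that("regular arrangements sit on a symmetric lattice", {
  g <- build_regular(arrangement_spec("regular", 8, c(0.5, 0.5, 0.5)),
                     c(6, 6, 6))
  expect_equal(nrow(g$boxes), 8)
  ctr <- as.matrix(g$boxes[, c("cx", "cy", "cz")])
  d <- as.matrix(dist(ctr))
  nearest <- apply(d + diag(Inf, 8), 1, min)
  expect_true(all(abs(nearest - nearest[1]) < 1e-12))
  # deterministic: same call, identical geometry
  g2 <- build_regular(arrangement_spec("regular", 8, c(0.5, 0.5, 0.5)),
                      c(6, 6, 6))
  expect_identical(g$boxes, g2$boxes)
})

test_that("empty and infeasible regular arrangements behave per contract", {
  g0 <- build_regular(arrangement_spec("regular", 0), c(10, 5, 5))
  expect_equal(nrow(g0$boxes), 0)
  expect_error(build_regular(arrangement_spec("regular", 5000), c(10, 5, 5)),
               "lattice")
})

test_that("random arrangements are seed-deterministic and overlap-free", {
  spec <- arrangement_spec("random", 60, seed = 9)
  g1 <- build_random(spec, c(12, 5, 4.5))
  g2 <- build_random(spec, c(12, 5, 4.5))
  expect_identical(g1$boxes, g2$boxes)
  expect_equal(brute_overlap_count(g1$boxes), 0L)
  g3 <- build_random(arrangement_spec("random", 60, seed = 10), c(12, 5, 4.5))
  expect_false(isTRUE(all.equal(g1$boxes$cx, g3$boxes$cx)))
  # >50% volume fraction refused
  expect_error(
    build_random(arrangement_spec("random", 400, c(1.5, 0.5, 0.5)),
                 c(6, 5, 4)),
    "fraction")
})

test_that("polarized arrangements confine centers to the outer quarter slabs", {
  for (ax in c("x", "y", "z")) {
    spec <- arrangement_spec(paste0("polarized_", ax), 40, seed = 3)
    g <- build_polarized(spec, c(12, 6, 6))
    a <- match(ax, c("x", "y", "z"))
    cc <- g$boxes[[c("cx", "cy", "cz")[a]]]
    expect_true(all(abs(cc) >= c(12, 6, 6)[a] / 4 - 1e-9))
    expect_equal(brute_overlap_count(g$boxes), 0L)
  }
  g1 <- build_polarized(arrangement_spec("polarized_z", 1, seed = 1),
                        c(10, 10, 10))
  expect_equal(nrow(g1$boxes), 1)
  expect_true(abs(g1$boxes$cz) >= 2.5)
})

test_that("fragmentation conserves volume exactly and flags fragments", {
  g <- build_regular(arrangement_spec("regular", 20), c(12, 5, 4.5))
  expect_identical(apply_fragmentation(g, 0), g)

  gf <- apply_fragmentation(g, 0.1, 3L, seed = 4)
  s0 <- geometry_summary(g)
  s1 <- geometry_summary(gf)
  expect_equal(sum(s1$fragmented), 6)        # 2 replaced x 3 fragments
  expect_equal(nrow(gf$boxes), 18 + 6)
  expect_lt(abs(sum(s1$volume) - sum(s0$volume)) / sum(s0$volume), 1e-9)
  # single-box arithmetic: 1.5 x 0.5 x 0.5 into k = 3 cubes
  g1 <- cell_geometry(c(10, 10, 10), mito_box(1, c(0, 0, 0),
                                              c(0.75, 0.25, 0.25)))
  gf1 <- apply_fragmentation(g1, 1, 3L, seed = 1)
  s <- geometry_summary(gf1)
  expect_equal(nrow(s), 3)
  expect_equal(sum(s$volume), 0.375)
  expect_equal(sum(s$area), 4.5)
  expect_equal(box_surface_area(c(1.5, 0.5, 0.5)), 3.5)
  # fragments have strictly larger surface-to-volume ratio than the parent
  expect_true(all(s$area / s$volume > 3.5 / 0.375))
})

test_that("10% of 100 mitochondria are replaced under the rounding rule", {
  g <- build_regular(arrangement_spec("regular", 100, c(0.5, 0.5, 0.5)),
                     c(10, 10, 4))
  gf <- apply_fragmentation(g, 0.1, 3L, seed = 2)
  expect_equal(sum(!gf$boxes$fragmented), 90)
  expect_equal(sum(gf$boxes$fragmented), 30)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
})

test_that("surface-area variation hits requested factors at conserved volume", {
  spec <- arrangement_spec("regular", 12)
  dims <- c(9.8, 3.93, 3.93)
  ref <- build_regular(spec, dims)
  a0 <- sum(geometry_summary(ref)$area)
  v0 <- sum(geometry_summary(ref)$volume)
  expect_identical(vary_surface_area(spec, dims, 1), ref)
  for (f in c(8 / 7, 9 / 7, 11 / 7)) {
    g <- vary_surface_area(spec, dims, f)
    s <- geometry_summary(g)
    expect_lt(abs(sum(s$area) / a0 - f) / f, 0.05)
    expect_lt(abs(sum(s$volume) - v0) / v0, 1e-9)
    expect_equal(brute_overlap_count(g$boxes), 0L)
  }
  expect_error(vary_surface_area(spec, dims, 40), "unreachable")
  # scaling law: splitting one box into 8 half-scale boxes doubles area
  expect_equal(8 * box_surface_area(c(0.75, 0.25, 0.25)),
               2 * box_surface_area(c(1.5, 0.5, 0.5)))
})

test_that("geometry serialization round-trips byte-identically", {
  g <- build_random(arrangement_spec("random", 15, seed = 5), c(10, 6, 6))
  js1 <- geometry_to_json(g)
  js2 <- geometry_to_json(geometry_from_json(js1))
  expect_identical(as.character(js1), as.character(js2))
  csv <- tempfile(fileext = ".csv")
  geometry_to_csv(g, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$area, geometry_summary(g)$area)
})

test_that("geometry invariants are enforced at construction", {
  expect_error(cell_geometry(c(4, 4, 4),
                             rbind(mito_box(1, c(0, 0, 0), c(1, 1, 1)),
                                   mito_box(2, c(0.5, 0, 0), c(1, 1, 1)))),
               "overlap")
  expect_error(cell_geometry(c(2, 2, 2), mito_box(1, c(1, 0, 0), c(0.5, 0.5, 0.5))),
               "outside")
  expect_error(cell_geometry(c(10, 10, 10),
                             rbind(mito_box(1, c(-2, 0, 0), c(0.5, 0.5, 0.5)),
                                   mito_box(1, c(2, 0, 0), c(0.5, 0.5, 0.5)))),
               "unique")
})
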