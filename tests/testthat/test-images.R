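test_that("8-bit conversion scales linearly and preserves ordering", {
  expect_error(to_8bit(matrix(numeric(0), 0, 0)), "empty")
  expect_true(all(to_8bit(matrix(7, 5, 5)) == 0L))
  two <- to_8bit(matrix(c(0, 65535), 1, 2))
  expect_equal(as.integer(two), c(0L, 255L))
  set.seed(3)
  img <- matrix(runif(400, 0, 4096), 20, 20)
  img8 <- to_8bit(img)
  expect_true(all(diff(img8[order(img)]) >= 0))
  expect_equal(range(img8), c(0L, 255L))
})

test_that("the IsoData threshold lands between the modes of a bimodal image", {
  set.seed(4)
  img8 <- to_8bit(matrix(c(rnorm(600, 30, 4), rnorm(400, 200, 6)), 25, 40))
  # hand-iterated intermeans oracle on the same histogram
  h <- tabulate(as.integer(img8) + 1L, 256L)
  lev <- 0:255
  t_hand <- round(sum(h * lev) / sum(h))
  repeat {
    lo <- lev <= t_hand
    m1 <- sum(h[lo] * lev[lo]) / sum(h[lo])
    m2 <- sum(h[!lo] * lev[!lo]) / sum(h[!lo])
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t_hand) break
    t_hand <- t_new
  }
  thr <- isodata_threshold(img8)
  expect_equal(thr, t_hand)
  modes <- range(img8[img8 > 0])
  expect_gt(thr, 20)
  expect_lt(thr, 230)
  # already-binary image: same mask for any interior threshold
  bin <- matrix(c(0L, 255L), 8, 8)
  expect_equal(apply_threshold(bin, "isodata"), bin > 100)
  expect_equal(apply_threshold(bin, 1), apply_threshold(bin, 254))
  expect_true(all(!apply_threshold(bin, 255)))
})

test_that("particle measurement matches a flood-fill oracle at both connectivities", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:7, 3:7] <- TRUE
  t1 <- measure_particles(mask, min_size = 1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$pixel_area, 25)
  # corner-touching squares: one object at 8-connectivity, two at 4
  m2 <- matrix(FALSE, 10, 10)
  m2[2:4, 2:4] <- TRUE
  m2[5:7, 5:7] <- TRUE
  expect_equal(nrow(measure_particles(m2, connectivity = 8L, min_size = 1)), 1)
  expect_equal(nrow(measure_particles(m2, connectivity = 4L, min_size = 1)), 2)
  # random blob field against the recursive flood-fill oracle
  set.seed(9)
  m3 <- matrix(runif(900) < 0.35, 30, 30)
  for (conn in c(4L, 8L)) {
    got <- sort(measure_particles(m3, connectivity = conn, min_size = 1)$pixel_area)
    expect_equal(got, flood_fill_sizes(m3, conn))
  }
  # min_size filter and empty mask
  expect_true(all(measure_particles(m3, min_size = 3)$pixel_area >= 3))
  empty <- measure_particles(matrix(FALSE, 5, 5))
  expect_equal(nrow(empty), 0)
  # physical area conversion
  t2 <- measure_particles(mask, min_size = 1, pixel_size = 0.2)
  expect_equal(t2$physical_area, 25 * 0.04)
})

test_that("population comparisons report medians, sizes and Mann-Whitney p", {
  all_sz <- c(10, 20, 30, 40, 50, 60, 70, 80)
  res_same <- compare_populations(all_sz, all_sz)
  expect_gt(res_same$p, 0.9)
  sub <- c(10, 12, 14)
  res <- compare_populations(all_sz, sub)
  expect_lt(res$median_subset, res$median_all)
  expect_lt(res$p, 0.1)
  expect_equal(res$n_all, 8)
  expect_equal(res$n_subset, 3)
  expect_error(compare_populations(all_sz, numeric()), "non-empty")
})

test_that("image IO round-trips through TIFF and PNG", {
  set.seed(10)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  for (ext in c(".tif", ".png")) {
    f <- tempfile(fileext = ext)
    write_gray_image(img, f)
    back <- read_gray_image(f)
    expect_equal(round(back), img, ignore_attr = TRUE)
  }
})
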