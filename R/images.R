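## Retrospective mitochondrial-size quantification, mirroring the ImageJ
## workflow: 8-bit conversion, (auto)thresholding, connected-component
## particle sizing, and a population comparison of object sizes.

#' Convert a grayscale image to 8-bit
#'
#' Linear min-max scaling to `[0, 255]` with rounding; a constant image maps
#' to all zeros. Pixel ordering is preserved.
#'
#' @param image numeric matrix (any integer or real depth).
#' @return integer matrix with values in `0..255`.
#' @export
to_8bit <- function(image) {
  if (length(image) == 0) stop_ms("empty image")
  image <- as.matrix(image)
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) {
    out <- matrix(0L, nrow(image), ncol(image))
    return(out)
  }
  out <- round((image - rng[1]) / (rng[2] - rng[1]) * 255)
  storage.mode(out) <- "integer"
  out
}

#' IsoData (iterative intermeans) threshold of an 8-bit image
#'
#' The ImageJ-default automatic threshold: starting from the image mean, the
#' threshold is iterated to the midpoint of the mean below and the mean
#' above until stable. Foreground is `pixel > threshold`.
#'
#' @param image8 integer matrix in `0..255`.
#' @return the threshold value (integer).
#' @export
isodata_threshold <- function(image8) {
  h <- tabulate(as.integer(image8) + 1L, nbins = 256L)
  lev <- 0:255
  t_cur <- round(sum(h * lev) / sum(h))
  for (i in 1:256) {
    below <- lev <= t_cur
    s1 <- sum(h[below]); s2 <- sum(h[!below])
    m1 <- if (s1 > 0) sum(h[below] * lev[below]) / s1 else 0
    m2 <- if (s2 > 0) sum(h[!below] * lev[!below]) / s2 else 255
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  as.integer(t_cur)
}

#' Threshold an 8-bit image into a binary mask
#'
#' @param image8 integer matrix in `0..255`.
#' @param method_or_value `"isodata"` for the automatic iterative intermeans
#'   threshold, or a fixed numeric threshold.
#' @return logical matrix, `TRUE` where `pixel > threshold`.
#' @export
apply_threshold <- function(image8, method_or_value = "isodata") {
  thr <- if (is.character(method_or_value)) {
    if (!identical(method_or_value, "isodata")) {
      stop_ms("unknown threshold method '%s'", method_or_value)
    }
    isodata_threshold(image8)
  } else {
    as.numeric(method_or_value)
  }
  image8 > thr
}

#' Measure particle sizes from a binary mask
#'
#' Connected components are labeled (8-connectivity by default, as in
#' ImageJ's Analyze Particles), components smaller than `min_size` pixels
#' are dropped, and areas are converted to um^2 when `pixel_size` is given.
#' Objects touching the image border are kept.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @param min_size minimum object size in pixels.
#' @param pixel_size optional pixel edge length (um).
#' @param population population label stored with the rows.
#' @return a SizeTable data.frame: `object_id, pixel_area, physical_area,
#'   population`.
#' @export
measure_particles <- function(mask, connectivity = 8L, min_size = 2L,
                              pixel_size = NULL, population = "all") {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  data.frame(object_id = seq_along(keep),
             pixel_area = sizes[keep],
             physical_area = if (is.null(pixel_size)) {
               rep(NA_real_, length(keep))
             } else {
               sizes[keep] * pixel_size^2
             },
             population = rep(population, length.out = length(keep)))
}

#' Compare an object-size subset against the full population
#'
#' Mann-Whitney comparison (via [mann_whitney()]) with group medians and
#' sizes, as used to contrast mitochondria undergoing or escaping MOMP with
#' the full population.
#'
#' @param all_sizes numeric sizes of the full population.
#' @param subset_sizes numeric sizes of the subset.
#' @return list with `U`, `p`, `median_all`, `median_subset`, `n_all`,
#'   `n_subset`.
#' @export
compare_populations <- function(all_sizes, subset_sizes) {
  if (length(all_sizes) == 0 || length(subset_sizes) == 0) {
    stop_ms("both populations must be non-empty")
  }
  mw <- mann_whitney(all_sizes, subset_sizes)
  list(U = mw$U, p = mw$p, median_all = median(all_sizes),
       median_subset = median(subset_sizes), n_all = length(all_sizes),
       n_subset = length(subset_sizes))
}

#' Quantify mitochondrial sizes in a grayscale image
#'
#' Full ImageJ-like chain: 8-bit conversion, IsoData (or fixed) threshold,
#' connected-component sizing.
#'
#' @param image numeric matrix.
#' @param threshold `"isodata"` or a fixed value.
#' @inheritParams measure_particles
#' @return a SizeTable data.frame.
#' @export
quantify_image <- function(image, threshold = "isodata", connectivity = 8L,
                           min_size = 2L, pixel_size = NULL,
                           population = "all") {
  img8 <- to_8bit(image)
  mask <- apply_threshold(img8, threshold)
  measure_particles(mask, connectivity, min_size, pixel_size, population)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel; intensities are
#' returned on the file's native scale times 255 for unit-range readers.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = ,
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop_ms("unsupported image format '%s'", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img * 255
}

#' Write a grayscale image (TIFF or PNG)
#' @param image numeric matrix with values in `0..255`.
#' @param path output path (`.tif`, `.tiff` or `.png`).
#' @return `path` invisibly.
#' @export
write_gray_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
         tif = ,
         tiff = tiff::writeTIFF(scaled, path),
         png = png::writePNG(scaled, path),
         stop_ms("unsupported image format '%s'", ext))
  invisible(path)
}
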