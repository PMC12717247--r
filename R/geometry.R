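## Model-cell geometry: a periodic rectangular cell containing static,
## axis-aligned rectangular ("box") mitochondria. Boxes never move, rotate,
## or remodel during a simulation; fission is represented statically by
## replacing a fraction of boxes with smaller fragments of equal total volume.
## All lengths are in micrometres.

#' Construct a mitochondrion box
#'
#' @param id unique integer identifier.
#' @param center numeric 3-vector, box center (um).
#' @param half_extents numeric 3-vector of positive half edge lengths (um).
#' @param fragmented logical, whether this box is a fission fragment.
#' @return a one-row data.frame with columns `id, cx, cy, cz, hx, hy, hz,
#'   fragmented`.
#' @export
mito_box <- function(id, center, half_extents, fragmented = FALSE) {
  stopifnot(length(center) == 3L, length(half_extents) == 3L)
  if (any(!is.finite(half_extents)) || any(half_extents <= 0)) {
    stop_ms("half_extents must all be > 0 (got %s)",
            paste(signif(half_extents, 4), collapse = ", "))
  }
  data.frame(id = as.integer(id), cx = center[1], cy = center[2],
             cz = center[3], hx = half_extents[1], hy = half_extents[2],
             hz = half_extents[3], fragmented = isTRUE(fragmented))
}

#' Construct a cell geometry
#'
#' Validates the geometry invariants: every box lies fully inside the
#' periodic cell box, boxes do not overlap pairwise, ids are unique, and the
#' total mitochondrial volume does not exceed `max_volume_fraction` of the
#' cell volume.
#'
#' @param cell_dims numeric 3-vector of periodic cell edge lengths (um); the
#'   cell spans `[-L/2, L/2]` on each axis.
#' @param boxes data.frame of boxes as produced by [mito_box()] (rbind-ed).
#' @param max_volume_fraction maximum allowed mitochondrial volume fraction.
#' @return an object of class `cell_geometry`.
#' @export
cell_geometry <- function(cell_dims, boxes = empty_boxes(),
                          max_volume_fraction = 0.5) {
  stopifnot(length(cell_dims) == 3L, all(cell_dims > 0))
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) > 0) {
    if (anyDuplicated(boxes$id)) stop_ms("box ids must be unique")
    h <- as.matrix(boxes[, c("hx", "hy", "hz")])
    ctr <- as.matrix(boxes[, c("cx", "cy", "cz")])
    if (any(h <= 0)) stop_ms("all half_extents must be > 0")
    for (a in 1:3) {
      if (any(abs(ctr[, a]) + h[, a] > cell_dims[a] / 2 + 1e-12)) {
        stop_ms("box extends outside the cell along axis %d", a)
      }
    }
    ov <- find_overlaps(boxes)
    if (nrow(ov) > 0) {
      stop_ms("boxes overlap (e.g. ids %d and %d)", ov$id1[1], ov$id2[1])
    }
    vfrac <- sum(apply(2 * h, 1, prod)) / prod(cell_dims)
    if (vfrac > max_volume_fraction) {
      stop_ms("mitochondrial volume fraction %.3f exceeds limit %.3f",
              vfrac, max_volume_fraction)
    }
  }
  structure(list(cell_dims = as.numeric(cell_dims), boxes = boxes),
            class = "cell_geometry")
}

empty_boxes <- function() {
  data.frame(id = integer(), cx = numeric(), cy = numeric(), cz = numeric(),
             hx = numeric(), hy = numeric(), hz = numeric(),
             fragmented = logical())
}

#' @export
print.cell_geometry <- function(x, ...) {
  s <- geometry_summary(x)
  cat(sprintf("cell_geometry: %.4g x %.4g x %.4g um cell, %d mitochondria\n",
              x$cell_dims[1], x$cell_dims[2], x$cell_dims[3], nrow(x$boxes)))
  if (nrow(x$boxes) > 0) {
    cat(sprintf("  total volume %.4g um^3 (%.2f%% of cell), total area %.4g um^2, %d fragmented\n",
                sum(s$volume), 100 * sum(s$volume) / prod(x$cell_dims),
                sum(s$area), sum(s$fragmented)))
  }
  invisible(x)
}

# all pairwise axis-aligned overlaps (strict interior intersection beyond
# `margin`); quadratic scan, used for validation only
find_overlaps <- function(boxes, margin = 0) {
  n <- nrow(boxes)
  out <- data.frame(id1 = integer(), id2 = integer())
  if (n < 2) return(out)
  ctr <- as.matrix(boxes[, c("cx", "cy", "cz")])
  h <- as.matrix(boxes[, c("hx", "hy", "hz")])
  for (i in seq_len(n - 1)) {
    d <- abs(sweep(ctr[(i + 1):n, , drop = FALSE], 2, ctr[i, ]))
    s <- sweep(h[(i + 1):n, , drop = FALSE], 2, h[i, ], "+")
    hit <- which(rowSums(d < s + margin - 1e-12) == 3L)
    if (length(hit)) {
      out <- rbind(out, data.frame(id1 = boxes$id[i],
                                   id2 = boxes$id[i + hit]))
    }
  }
  out
}

#' Surface area of a rectangular box
#'
#' @param dims numeric 3-vector of full edge lengths (um).
#' @return surface area `2(ab + bc + ca)` in um^2.
#' @export
box_surface_area <- function(dims) {
  stopifnot(length(dims) == 3L)
  if (any(dims <= 0)) stop_ms("box edge lengths must be > 0")
  2 * (dims[1] * dims[2] + dims[2] * dims[3] + dims[3] * dims[1])
}

#' Per-mitochondrion geometry summary
#'
#' @param geometry a [cell_geometry()].
#' @return data.frame with `id, area, volume, fragmented` plus centers/dims.
#' @export
geometry_summary <- function(geometry) {
  b <- geometry$boxes
  dims <- as.matrix(2 * b[, c("hx", "hy", "hz")])
  data.frame(id = b$id, cx = b$cx, cy = b$cy, cz = b$cz,
             dx = dims[, 1], dy = dims[, 2], dz = dims[, 3],
             area = if (nrow(b)) apply(dims, 1, box_surface_area) else numeric(),
             volume = if (nrow(b)) apply(dims, 1, prod) else numeric(),
             fragmented = b$fragmented)
}

#' Arrangement specification
#'
#' @param mode one of `"regular"`, `"random"`, `"polarized_x"`,
#'   `"polarized_y"`, `"polarized_z"`, `"fragmented"`.
#' @param n_mito number of mitochondria before any fragmentation.
#' @param mito_dims full edge lengths of a non-fragmented mitochondrion (um).
#' @param fragment_fraction fraction of mitochondria replaced by fragments.
#' @param fragments_per_replacement number of fragments replacing each
#'   fragmented mitochondrion (>= 2).
#' @param seed integer seed for stochastic placements.
#' @return an `arrangement_spec` list.
#' @export
arrangement_spec <- function(mode = c("regular", "random", "polarized_x",
                                      "polarized_y", "polarized_z",
                                      "fragmented"),
                             n_mito, mito_dims = c(1.5, 0.5, 0.5),
                             fragment_fraction = 0,
                             fragments_per_replacement = 3L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_mito >= 0, length(mito_dims) == 3L, all(mito_dims > 0),
            fragment_fraction >= 0, fragment_fraction <= 1,
            fragments_per_replacement >= 2L)
  structure(list(mode = mode, n_mito = as.integer(n_mito),
                 mito_dims = as.numeric(mito_dims),
                 fragment_fraction = fragment_fraction,
                 fragments_per_replacement = as.integer(fragments_per_replacement),
                 seed = as.integer(seed)),
            class = "arrangement_spec")
}

# choose lattice split (nx, ny, nz) of n across cell_dims so that every
# spacing exceeds the box size by the largest possible margin; deterministic
lattice_dims <- function(n, cell_dims, mito_dims, min_gap = 0.05) {
  best <- NULL
  best_slack <- -Inf
  for (nx in 1:n) {
    if (n %% nx != 0) next
    rest <- n / nx
    for (ny in 1:rest) {
      if (rest %% ny != 0) next
      nz <- rest / ny
      sp <- cell_dims / c(nx, ny, nz)
      slack <- min(sp - mito_dims)
      if (slack > best_slack) {
        best_slack <- slack
        best <- c(nx, ny, nz)
      }
    }
  }
  if (is.null(best) || best_slack < min_gap) {
    stop_ms("cannot place %d mitochondria of size %s on a lattice in a %s cell (insufficient spacing)",
            n, paste(mito_dims, collapse = "x"),
            paste(signif(cell_dims, 4), collapse = "x"))
  }
  best
}

#' Regular symmetric arrangement
#'
#' Mitochondria centered on an even 3D lattice; fully deterministic.
#'
#' @param spec an [arrangement_spec()].
#' @param cell_dims periodic cell edge lengths (um).
#' @return a [cell_geometry()].
#' @export
build_regular <- function(spec, cell_dims) {
  n <- spec$n_mito
  if (n == 0) return(cell_geometry(cell_dims))
  nd <- lattice_dims(n, cell_dims, spec$mito_dims)
  ax <- lapply(1:3, function(a) {
    (seq_len(nd[a]) - 0.5) / nd[a] * cell_dims[a] - cell_dims[a] / 2
  })
  ctr <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
    mito_box(i, ctr[i, ], spec$mito_dims / 2)
  }))
  cell_geometry(cell_dims, boxes)
}

# rejection-sample non-overlapping box centers; `lim` gives per-axis center
# bounds (2 x 3 matrix), margin is the minimum face-to-face gap
sample_boxes <- function(n, half, lim, margin, max_attempts = 10000) {
  ctr <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- runif(3, lim[1, ], lim[2, ])
      if (i == 1) { ok <- TRUE } else {
        prev <- ctr[seq_len(i - 1), , drop = FALSE]
        d <- abs(sweep(prev, 2, p))
        ok <- !any(rowSums(d < 2 * rep(1, nrow(prev)) %o% half + margin) == 3L)
      }
      if (ok) { ctr[i, ] <- p; break }
    }
    if (!ok) {
      stop_ms("failed to place mitochondrion %d after %d attempts", i,
              max_attempts)
    }
  }
  ctr
}

#' Random non-overlapping arrangement
#'
#' Uniform rejection sampling of box centers inside the cell; identical seed
#' yields an identical layout.
#'
#' @inheritParams build_regular
#' @param margin minimum face-to-face gap between mitochondria (um).
#' @param max_attempts placement attempts per box before giving up.
#' @return a [cell_geometry()].
#' @export
build_random <- function(spec, cell_dims, margin = 0.05,
                         max_attempts = 10000) {
  n <- spec$n_mito
  half <- spec$mito_dims / 2
  vfrac <- n * prod(spec$mito_dims) / prod(cell_dims)
  if (vfrac > 0.5) {
    stop_ms("requested mitochondrial volume fraction %.2f exceeds 0.5", vfrac)
  }
  if (n == 0) return(cell_geometry(cell_dims))
  lim <- rbind(-(cell_dims / 2 - half), cell_dims / 2 - half)
  ctr <- with_seed(spec$seed,
                   sample_boxes(n, half, lim, margin, max_attempts))
  boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
    mito_box(i, ctr[i, ], half)
  }))
  cell_geometry(cell_dims, boxes)
}

#' Polarized arrangement
#'
#' Random non-overlapping placement confined to the two outer slabs (each a
#' quarter of the cell depth) along the chosen axis, emulating cells whose
#' mitochondria concentrate at opposite sides.
#'
#' @inheritParams build_random
#' @param axis `"x"`, `"y"` or `"z"`; taken from `spec$mode` when it is
#'   `polarized_*` and `axis` is missing.
#' @return a [cell_geometry()].
#' @export
build_polarized <- function(spec, cell_dims, axis = NULL, margin = 0.05,
                            max_attempts = 10000) {
  if (is.null(axis)) {
    axis <- sub("polarized_", "", spec$mode)
  }
  a <- match(axis, c("x", "y", "z"))
  if (is.na(a)) stop_ms("axis must be one of x, y, z")
  n <- spec$n_mito
  half <- spec$mito_dims / 2
  if (n == 0) return(cell_geometry(cell_dims))
  L <- cell_dims[a]
  if (L / 4 + half[a] > L / 2) stop_ms("box too thick for polarized slab")
  ctr <- with_seed(spec$seed, {
    lim <- rbind(-(cell_dims / 2 - half), cell_dims / 2 - half)
    out <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- runif(3, lim[1, ], lim[2, ])
        side <- if (runif(1) < 0.5) -1 else 1
        p[a] <- side * runif(1, L / 4, L / 2 - half[a])
        if (i == 1) { ok <- TRUE } else {
          prev <- out[seq_len(i - 1), , drop = FALSE]
          d <- abs(sweep(prev, 2, p))
          lim2 <- matrix(2 * half, nrow(prev), 3, byrow = TRUE) + margin
          ok <- !any(rowSums(d < lim2) == 3L)
        }
        if (ok) { out[i, ] <- p; break }
      }
      if (!ok) stop_ms("failed to place mitochondrion %d in polarized slab", i)
    }
    out
  })
  boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
    mito_box(i, ctr[i, ], half)
  }))
  cell_geometry(cell_dims, boxes)
}

#' Fragment a fraction of mitochondria at conserved volume
#'
#' Replaces `round(fraction * n)` randomly chosen mitochondria (rounding half
#' away from zero) by `k_fragments` boxes each: the longest axis is divided by
#' `k_fragments` and the cross-section preserved, so total mitochondrial
#' volume is conserved exactly while surface area increases. Fragments are
#' laid out in place of the parent, separated by `gap` along the split axis.
#'
#' @param geometry a [cell_geometry()].
#' @param fraction fraction of mitochondria to fragment, in `[0, 1]`.
#' @param k_fragments fragments per replaced mitochondrion (>= 2).
#' @param seed integer seed for choosing which mitochondria fragment.
#' @param gap spacing between sibling fragments (um); shrunk automatically if
#'   the fragment row would not fit inside the cell.
#' @return a new [cell_geometry()] with `fragmented` flags set.
#' @export
apply_fragmentation <- function(geometry, fraction, k_fragments = 3L,
                                seed = 1L, gap = 0.15) {
  stopifnot(fraction >= 0, fraction <= 1, k_fragments >= 2L)
  n <- nrow(geometry$boxes)
  n_rep <- as.integer(round_half_away(fraction * n))
  if (n_rep == 0) return(geometry)
  pick <- sort(with_seed(seed, sample.int(n, n_rep)))
  b <- geometry$boxes
  keep <- b[-pick, , drop = FALSE]
  next_id <- max(b$id) + 1L
  frags <- list()
  for (i in pick) {
    h <- as.numeric(b[i, c("hx", "hy", "hz")])
    ctr <- as.numeric(b[i, c("cx", "cy", "cz")])
    ax <- which.max(h)
    hf <- h
    hf[ax] <- h[ax] / k_fragments
    g <- gap
    span <- 2 * h[ax] + (k_fragments - 1) * g
    lim <- geometry$cell_dims[ax] / 2 - abs(ctr[ax])
    if (span / 2 > lim) {
      g <- max(0.01, (2 * (lim - h[ax])) / (k_fragments - 1))
      span <- 2 * h[ax] + (k_fragments - 1) * g
    }
    step <- 2 * hf[ax] + g
    start <- ctr[ax] - span / 2 + hf[ax]
    for (j in seq_len(k_fragments)) {
      c2 <- ctr
      c2[ax] <- start + (j - 1) * step
      frags[[length(frags) + 1L]] <- mito_box(next_id, c2, hf,
                                              fragmented = TRUE)
      next_id <- next_id + 1L
    }
  }
  out <- rbind(keep, do.call(rbind, frags))
  rownames(out) <- NULL
  geom2 <- cell_geometry(geometry$cell_dims, out)
  v1 <- sum(geometry_summary(geometry)$volume)
  v2 <- sum(geometry_summary(geom2)$volume)
  if (abs(v2 - v1) / v1 > 1e-9) {
    stop_ms("internal error: fragmentation changed total volume by %.3g", v2 - v1)
  }
  geom2
}

#' Build a geometry with scaled total surface area at conserved volume
#'
#' Produces a regular arrangement whose total mitochondrial surface area is
#' `area_factor` times that of the reference regular arrangement while the
#' total volume is conserved exactly. The scaling divides each mitochondrion
#' along its longest axis into `s` equal pieces (cross-section preserved),
#' with `s` chosen so the achieved factor is within `tol` of the request.
#'
#' @inheritParams build_regular
#' @param area_factor requested total-surface-area multiplier (> 0).
#' @param tol acceptable relative deviation from the requested factor.
#' @param max_split largest number of pieces per mitochondrion considered.
#' @return a [cell_geometry()].
#' @export
vary_surface_area <- function(spec, cell_dims, area_factor, tol = 0.05,
                              max_split = 12L) {
  stopifnot(area_factor > 0)
  d <- sort(spec$mito_dims, decreasing = TRUE)  # d[1] is the split axis
  base_area <- box_surface_area(spec$mito_dims)
  f_s <- vapply(seq_len(max_split), function(s) {
    2 * (d[1] * d[2] + s * d[2] * d[3] + d[3] * d[1]) / base_area
  }, numeric(1))
  s <- which.min(abs(f_s - area_factor))
  if (abs(f_s[s] - area_factor) / area_factor > tol) {
    stop_ms("area factor %.3g unreachable by length-splitting (nearest achievable %.3g)",
            area_factor, f_s[s])
  }
  geom <- build_regular(spec, cell_dims)
  if (s == 1) return(geom)
  apply_split_all(geom, s)
}

# split every box into s pieces along its longest axis (volume conserved)
apply_split_all <- function(geometry, s, gap = 0.1) {
  b <- geometry$boxes
  frags <- list()
  nid <- 1L
  for (i in seq_len(nrow(b))) {
    h <- as.numeric(b[i, c("hx", "hy", "hz")])
    ctr <- as.numeric(b[i, c("cx", "cy", "cz")])
    ax <- which.max(h)
    hf <- h
    hf[ax] <- h[ax] / s
    g <- gap
    span <- 2 * h[ax] + (s - 1) * g
    lim <- geometry$cell_dims[ax] / 2 - abs(ctr[ax])
    if (span / 2 > lim) {
      g <- max(0.01, (2 * (lim - h[ax])) / (s - 1))
      span <- 2 * h[ax] + (s - 1) * g
    }
    step <- 2 * hf[ax] + g
    start <- ctr[ax] - span / 2 + hf[ax]
    for (j in seq_len(s)) {
      c2 <- ctr
      c2[ax] <- start + (j - 1) * step
      frags[[nid]] <- mito_box(nid, c2, hf)
      nid <- nid + 1L
    }
  }
  cell_geometry(geometry$cell_dims, do.call(rbind, frags))
}

#' Build the geometry described by an arrangement spec
#'
#' Dispatch helper: regular, random and polarized arrangements are built
#' directly; `mode = "fragmented"` builds the regular arrangement and applies
#' [apply_fragmentation()] with the spec's fraction and fragment count.
#'
#' @inheritParams build_regular
#' @return a [cell_geometry()].
#' @export
build_arrangement <- function(spec, cell_dims) {
  switch(spec$mode,
         regular = build_regular(spec, cell_dims),
         random = build_random(spec, cell_dims),
         polarized_x = ,
         polarized_y = ,
         polarized_z = build_polarized(spec, cell_dims),
         fragmented = apply_fragmentation(
           build_regular(spec, cell_dims), spec$fragment_fraction,
           spec$fragments_per_replacement, seed = spec$seed),
         stop_ms("unknown arrangement mode '%s'", spec$mode))
}

#' Serialize a geometry to JSON
#'
#' @param geometry a [cell_geometry()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  obj <- list(units = "um",
              cell_dims = geometry$cell_dims,
              mitochondria = geometry$boxes)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a geometry from JSON written by [geometry_to_json()]
#' @param path input file path (or JSON string).
#' @return a [cell_geometry()].
#' @export
geometry_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cell_geometry(as.numeric(obj$cell_dims), as.data.frame(obj$mitochondria))
}

#' Export per-mitochondrion geometry table to CSV
#' @param geometry a [cell_geometry()].
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
geometry_to_csv <- function(geometry, path) {
  s <- geometry_summary(geometry)
  write.csv(s, path, row.names = FALSE)
  invisible(s)
}
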