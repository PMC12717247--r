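# Shared fixtures and independent oracles used across the suite.
# Heavy scenario runs are computed lazily once per session and cached so
# several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small reference cell: 12 boxes in a compact periodic cell
small_cell <- function() {
  build_regular(arrangement_spec("regular", 12), c(8, 4, 4))
}

one_box_cell <- function(half = c(0.5, 0.5, 0.5), L = c(10, 10, 10)) {
  cell_geometry(L, mito_box(1L, c(0, 0, 0), half))
}

# brute-force pairwise AABB overlap oracle (independent of find_overlaps)
brute_overlap_count <- function(boxes) {
  n <- nrow(boxes)
  cnt <- 0L
  if (n < 2) return(cnt)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(boxes$cx[i] - boxes$cx[j]) < boxes$hx[i] + boxes$hx[j] &&
          abs(boxes$cy[i] - boxes$cy[j]) < boxes$hy[i] + boxes$hy[j] &&
          abs(boxes$cz[i] - boxes$cz[j]) < boxes$hz[i] + boxes$hz[j]) {
        cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# naive recursive flood fill used as connected-component labeling oracle
flood_fill_sizes <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nb4 <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nb8 <- rbind(nb4, cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)))
  nb <- if (connectivity == 8L) nb8 else nb4
  sizes <- integer()
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- list(c(i, j)); seen[i, j] <- TRUE; sz <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        sz <- sz + 1L
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
      sizes <- c(sizes, sz)
    }
  }
  sort(sizes)
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (small samples, no ties)
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

mcl1_species <- function(conc = 50, p_bind = 0.01, k_off = 1) {
  species_params("MCL1", conc, 10, 0.25, p_bind, k_off)
}
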