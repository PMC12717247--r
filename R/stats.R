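## Per-mitochondrion density tables and the statistical toolkit used for the
## heterogeneity analyses: rank tests for medians, Levene/Brown-Forsythe for
## variances, D'Agostino-Pearson for normality, one-phase decay fits, and
## surface density maps.

#' Per-mitochondrion density table
#'
#' Tabulates membrane-bound particle counts of a run per mitochondrion and
#' species, divided by that mitochondrion's volume and surface area.
#'
#' @param run a `whole_cell_run` (or a list with `per_mito`), or a snapshot
#'   data.frame (then `geometry` is required).
#' @param geometry a [cell_geometry()]; only needed with a raw snapshot.
#' @param group optional group label for all rows (defaults to
#'   `"fragmented"` / `"non_fragmented"` from the geometry flags).
#' @param replicate replicate identifier stored with the rows.
#' @return data.frame with `mito_id, group, species, count, volume, area,
#'   count_per_volume, count_per_area, replicate`.
#' @export
densities <- function(run, geometry = NULL, group = NULL, replicate = 1L) {
  if (is.data.frame(run)) {
    if (is.null(geometry)) stop_ms("geometry required with a raw snapshot")
    snap <- run
    memb <- snap[snap$compartment == "membrane", , drop = FALSE]
    if (nrow(memb) && any(!memb$mito_id %in% geometry$boxes$id)) {
      stop_ms("snapshot references unknown mito_id")
    }
    gs <- geometry_summary(geometry)
    species <- unique(snap$species)
    pm <- do.call(rbind, lapply(species, function(sp) {
      cnt <- table(factor(memb$mito_id[memb$species == sp],
                          levels = gs$id))
      data.frame(mito_id = gs$id, species = sp, count = as.numeric(cnt),
                 volume = gs$volume, area = gs$area,
                 fragmented = gs$fragmented)
    }))
  } else {
    pm <- run$per_mito
  }
  grp <- if (is.null(group)) {
    ifelse(pm$fragmented, "fragmented", "non_fragmented")
  } else {
    group
  }
  data.frame(mito_id = pm$mito_id, group = grp, species = pm$species,
             count = pm$count, volume = pm$volume, area = pm$area,
             count_per_volume = pm$count / pm$volume,
             count_per_area = pm$count / pm$area,
             replicate = replicate)
}

#' Pool per-mitochondrion tables across replicate runs
#' @param tables list of [densities()] tables.
#' @return row-bound table with replicate ids preserved.
#' @export
pool_replicates <- function(tables) {
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p-value for small samples (`n1 * n2 <= 400` without ties), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, and sample sizes `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_ms("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected H statistic; pairwise Dunn z-tests on mean ranks with
#' optional multiplicity adjustment (default none, matching common "Dunn's
#' post-hoc" usage; `"bonferroni"`/`"holm"` available).
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param adjust p-value adjustment method for the pairwise comparisons.
#' @return list with `H`, `df`, `p`, and a `pairwise` data.frame.
#' @export
kruskal_dunn <- function(groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3) {
    stop_ms("need >= 3 groups; use mann_whitney() for two groups")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(seq_along(groups), 2)
  z <- apply(cmb, 2, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(s2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
  })
  praw <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(group1 = names(groups)[cmb[1, ]],
                         group2 = names(groups)[cmb[2, ]],
                         z = as.numeric(z), p = praw,
                         p_adj = p.adjust(praw, method = adjust))
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       pairwise = pairwise, adjust = adjust)
}

# shared engine for Levene-type tests: one-way ANOVA on absolute deviations
levene_engine <- function(groups, center) {
  if (length(groups) < 2) stop_ms("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop_ms("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  lt <- car::leveneTest(y, g, center = center)
  list(W = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
       p = lt[1, "Pr(>F)"])
}

#' Levene's test for variance homogeneity (deviations from group means)
#' @param groups named list of numeric vectors.
#' @return list with `W` (F statistic), `df1`, `df2`, `p`.
#' @export
levene <- function(groups) levene_engine(groups, mean)

#' Brown-Forsythe test for variance homogeneity (deviations from medians)
#' @param groups named list of numeric vectors.
#' @return list with `W` (F statistic), `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(groups) levene_engine(groups, median)

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn kurtosis
#' z-score into `K^2 = Z1^2 + Z2^2`, chi-squared with 2 df under normality.
#'
#' @param x numeric sample with `n >= 20`.
#' @return list with `K2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop_ms("D'Agostino-Pearson requires n >= 20 (got %d)", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / alpha)
  # kurtosis (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(K2 = K2, p = pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = Z1, z_kurt = Z2, n = n)
}

#' One-phase exponential decay fit
#'
#' Bounded nonlinear least squares of
#' `y = (y0 - plateau) * exp(-k x) + plateau` with `k >= 0`, using
#' `minpack.lm::nlsLM` from multiple starting points to avoid local minima.
#' A constant response is flagged degenerate (`plateau = y`, `k = 0`).
#'
#' @param x non-negative predictor values (>= 4 points).
#' @param y response values.
#' @param n_starts number of multi-start initializations.
#' @return list with `y0`, `plateau`, `k`, `sse`, `fitted`, `degenerate`.
#' @export
one_phase_decay_fit <- function(x, y, n_starts = 5L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop_ms("need at least 4 points")
  if (any(x < 0)) stop_ms("x must be >= 0")
  if (sd(y) < 1e-12 * (abs(mean(y)) + 1)) {
    return(list(y0 = y[1], plateau = y[1], k = 0, sse = 0, fitted = y,
                degenerate = TRUE))
  }
  xr <- diff(range(x))
  k_starts <- exp(seq(log(0.1), log(30), length.out = n_starts)) / max(xr, 1e-12)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (y0 - plateau) * exp(-k * x) + plateau,
                        start = list(y0 = y[which.min(x)],
                                     plateau = y[which.max(x)], k = k0),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- coef(fit)
      best <- list(y0 = unname(cf["y0"]), plateau = unname(cf["plateau"]),
                   k = unname(cf["k"]), sse = sse,
                   fitted = as.numeric(fitted(fit)), degenerate = FALSE)
    }
  }
  if (is.null(best)) {
    stop_ms("one-phase decay fit failed to converge from %d starts; residual scale %.3g",
            n_starts, sd(y))
  }
  best
}

#' Surface density map of a mitochondrion
#'
#' Bins the membrane particles of one mitochondrion into per-face 2D
#' histograms (particle counts projected onto the surface plane). Bin counts
#' sum to the mitochondrion's membrane particle count.
#'
#' @param snapshot particle snapshot data.frame.
#' @param geometry a [cell_geometry()].
#' @param mito_id mitochondrion id.
#' @param bins number of bins along each face axis (scalar).
#' @param species optional species filter.
#' @return list of six matrices (faces +x, -x, +y, -y, +z, -z).
#' @export
surface_density_map <- function(snapshot, geometry, mito_id, bins = 5L,
                                species = NULL) {
  i <- match(mito_id, geometry$boxes$id)
  if (is.na(i)) stop_ms("unknown mito_id %s", mito_id)
  half <- as.numeric(geometry$boxes[i, c("hx", "hy", "hz")])
  rows <- snapshot$compartment == "membrane" &
    !is.na(snapshot$mito_id) & snapshot$mito_id == mito_id
  if (!is.null(species)) rows <- rows & snapshot$species %in% species
  sub <- snapshot[rows, , drop = FALSE]
  maps <- vector("list", 6)
  names(maps) <- c("+x", "-x", "+y", "-y", "+z", "-z")
  for (f in 0:5) {
    a <- f %/% 2
    Lu <- 2 * half[(a + 1) %% 3 + 1]
    Lv <- 2 * half[(a + 2) %% 3 + 1]
    m <- matrix(0, bins, bins)
    on_f <- sub[sub$face_id == f, , drop = FALSE]
    if (nrow(on_f)) {
      bu <- pmin(pmax(ceiling(on_f$u / Lu * bins), 1L), bins)
      bv <- pmin(pmax(ceiling(on_f$v / Lv * bins), 1L), bins)
      for (j in seq_len(nrow(on_f))) m[bu[j], bv[j]] <- m[bu[j], bv[j]] + 1
    }
    maps[[f + 1]] <- m
  }
  maps
}

#' Medians-and-variances comparison report for a density table
#'
#' Applies the package's statistical conventions to the `count_per_area`
#' (or another) column of a [densities()] table: two groups are compared by
#' Mann-Whitney (medians) and Levene (variances); three or more groups by
#' Kruskal-Wallis with Dunn's post-hoc (medians) and Brown-Forsythe
#' (variances).
#'
#' @param table a [densities()]-style data.frame.
#' @param value column to compare.
#' @param group grouping column.
#' @return list with `medians`, `median_test`, `variance_test`, `n`.
#' @export
variance_report <- function(table, value = "count_per_area",
                            group = "group") {
  if (nrow(table) == 0) stop_ms("empty table")
  gs <- split(table[[value]], table[[group]])
  gs <- gs[lengths(gs) > 0]
  if (length(gs) < 2) stop_ms("need >= 2 groups (got %d)", length(gs))
  meds <- vapply(gs, median, numeric(1))
  if (length(gs) == 2) {
    med_test <- c(test = "mann_whitney",
                  mann_whitney(gs[[1]], gs[[2]])[c("U", "p")])
    var_test <- c(test = "levene", levene(gs)[c("W", "p")])
  } else {
    kd <- kruskal_dunn(gs)
    med_test <- list(test = "kruskal_dunn", H = kd$H, p = kd$p,
                     pairwise = kd$pairwise)
    var_test <- c(test = "brown_forsythe", brown_forsythe(gs)[c("W", "p")])
  }
  list(medians = as.list(meds), median_test = med_test,
       variance_test = var_test, n = as.list(lengths(gs)))
}

#' Write a stats report as JSON
#' @param report list of test results (e.g. from [variance_report()]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
stats_report_to_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
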