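## Scenario orchestration: build the geometry and species tables of a study
## scenario, run replicate translocation simulations, pool per-mitochondrion
## tables, run the single-mitochondrion reaction stage, and write outputs
## with a manifest that makes every stage reproducible.

scenario_species_table <- function(cfg, which = c("MCL1")) {
  tp <- cfg$translocation
  rows <- list(
    MCL1 = species_params("MCL1", cfg$mcl1_nM %||% 101, tp$D_cyto, tp$D_mem,
                          tp$MCL1$p_bind, tp$MCL1$k_off),
    tBID = species_params("tBID", cfg$tbid_nM %||% 10, tp$D_cyto, tp$D_mem,
                          tp$tBID$p_bind, tp$tBID$k_off),
    BAK = species_params("BAK", cfg$bak_nM %||% 50, tp$D_cyto, tp$D_mem,
                         tp$BAK$p_bind, tp$BAK$k_off))
  do.call(rbind, rows[which])
}

scenario_sim_config <- function(cfg, species_tab, seed, dt = NULL,
                                duration = NULL, collide_from = 0) {
  tp <- cfg$translocation
  sim_config(species_tab, dt %||% cfg$dt %||% tp$dt,
             duration %||% cfg$duration %||% tp$duration,
             record_interval = tp$record_interval, seed = seed,
             collide_from = collide_from)
}

scenario_fragmented_geometry <- function(cfg) {
  spec <- arrangement_spec("regular", cfg$n_mito, cfg$mito_dims)
  apply_fragmentation(build_regular(spec, cfg$cell_dims),
                      cfg$fragment_fraction,
                      cfg$fragments_per_replacement,
                      seed = derive_seed(cfg$seed, 7L))
}

# replicate translocation runs pooled into one density table
pooled_translocation <- function(geometry, cfg, species_tab,
                                 group = NULL, dt = NULL, duration = NULL) {
  runs <- lapply(seq_len(cfg$n_replicates), function(r) {
    sc <- scenario_sim_config(cfg, species_tab, cfg$replicate_seeds[r],
                              dt = dt, duration = duration)
    run_whole_cell(geometry, sc)
  })
  tab <- pool_replicates(lapply(seq_along(runs), function(r) {
    densities(runs[[r]], group = group, replicate = r)
  }))
  list(runs = runs, table = tab)
}

#' Run a study scenario end to end
#'
#' Executes the simulation pipeline of a [make_experiment_config()]
#' scenario: replicate whole-cell translocation runs, pooled
#' per-mitochondrion density tables and the scenario's statistical
#' comparisons; for the tBID scenarios optionally the single-mitochondrion
#' reaction stage with the pooled pore metric.
#'
#' @param config a [make_experiment_config()] list.
#' @param stages character subset of `c("translocation", "reactions")`.
#' @param species_filter optional subset of species names to simulate in the
#'   translocation stage (e.g. only `"tBID"` when only the tBID steady-state
#'   table is needed).
#' @return a list of scenario results (tables, stats, and per-scenario
#'   extras such as fits or pore tables).
#' @export
run_scenario <- function(config, stages = "translocation",
                         species_filter = NULL) {
  switch(config$scenario,
         fig1_sweep = scenario_fig1(config),
         fig2_arrangements = scenario_fig2(config),
         fig3_fragmentation = scenario_fig3(config),
         fig4_strong_tBID = ,
         fig5_weak_tBID = scenario_tbid(config, stages, species_filter),
         stop_ms("unknown scenario '%s'", config$scenario))
}

# surface-area sweep at conserved volume: collision proportionality
# (reflective runs) and cytosolic:membrane partitioning (translocation runs)
scenario_fig1 <- function(cfg) {
  spec <- arrangement_spec("regular", cfg$n_mito %||% 12L, cfg$mito_dims)
  species_tab <- scenario_species_table(cfg, "MCL1")
  geoms <- lapply(cfg$area_factors, function(f) {
    vary_surface_area(spec, cfg$cell_dims, f)
  })
  areas <- vapply(geoms, function(g) sum(geometry_summary(g)$area),
                  numeric(1))
  volumes <- vapply(geoms, function(g) sum(geometry_summary(g)$volume),
                    numeric(1))
  collisions <- numeric(length(geoms))
  ratio <- numeric(length(geoms))
  for (i in seq_along(geoms)) {
    # collision quantification: reflective interactions only
    st_refl <- species_tab
    st_refl$p_bind <- 0
    sc <- scenario_sim_config(cfg, st_refl, derive_seed(cfg$seed, 11L + i),
                              dt = cfg$dt, duration = 0.7)
    run_c <- run_whole_cell(geoms[[i]], sc)
    collisions[i] <- sum(run_c$per_mito$collisions)
    # partitioning: full (retro)translocation to steady state
    sc2 <- scenario_sim_config(cfg, species_tab,
                               derive_seed(cfg$seed, 31L + i),
                               dt = cfg$dt, duration = cfg$duration %||% 2)
    run_t <- run_whole_cell(geoms[[i]], sc2)
    ser <- run_t$series
    tl <- ser[ser$time >= 0.75 * max(ser$time), ]
    ratio[i] <- sum(tl$n_cyto) / sum(tl$n_mem)
  }
  sweep <- data.frame(area_factor = cfg$area_factors, total_area = areas,
                      total_volume = volumes, collisions = collisions,
                      cyto_mito_ratio = ratio)
  # through-origin proportionality of collision counts vs area
  fit0 <- lm(collisions ~ 0 + total_area, data = sweep)
  r2 <- 1 - sum(resid(fit0)^2) / sum(sweep$collisions^2)
  decay <- one_phase_decay_fit(sweep$total_area, sweep$cyto_mito_ratio)
  linfit <- lm(cyto_mito_ratio ~ total_area, data = sweep)
  list(scenario = cfg$scenario, sweep = sweep,
       collision_fit = list(slope = unname(coef(fit0)), r_squared = r2),
       decay_fit = decay, linear_sse = sum(resid(linfit)^2))
}

scenario_fig2 <- function(cfg) {
  species_tab <- scenario_species_table(cfg, "MCL1")
  tabs <- list()
  for (arr in (cfg$compare %||% cfg$arrangements)) {
    ai <- match(arr, cfg$arrangements)
    # stochastic arrangements are re-randomized per replicate, mirroring the
    # replicate protocol (new initial particle AND mitochondrion placements)
    rep_tabs <- lapply(seq_len(cfg$n_replicates), function(r) {
      spec <- arrangement_spec(arr, cfg$n_mito, cfg$mito_dims,
                               seed = derive_seed(cfg$seed, 50L + 10L * ai + r))
      geom <- build_arrangement(spec, cfg$cell_dims)
      sc <- scenario_sim_config(cfg, species_tab, cfg$replicate_seeds[r])
      densities(run_whole_cell(geom, sc), group = arr, replicate = r)
    })
    tabs[[arr]] <- pool_replicates(rep_tabs)
  }
  tab <- pool_replicates(tabs)
  out <- list(scenario = cfg$scenario, table = tab)
  if (all(c("regular", "random") %in% tab$group)) {
    two <- tab[tab$group %in% c("regular", "random"), ]
    out$regular_vs_random <- list(
      per_area = list(
        medians = mann_whitney(two$count_per_area[two$group == "regular"],
                               two$count_per_area[two$group == "random"]),
        variances = levene(split(two$count_per_area, two$group))),
      per_volume = list(
        medians = mann_whitney(two$count_per_volume[two$group == "regular"],
                               two$count_per_volume[two$group == "random"]),
        variances = levene(split(two$count_per_volume, two$group))))
  }
  pol <- tab[grepl("^polarized", tab$group), ]
  if (length(unique(pol$group)) >= 3) {
    out$polarized <- list(
      per_area = kruskal_dunn(split(pol$count_per_area, pol$group)),
      per_volume = kruskal_dunn(split(pol$count_per_volume, pol$group)))
  }
  out
}

scenario_fig3 <- function(cfg) {
  geom_frag <- scenario_fragmented_geometry(cfg)
  spec <- arrangement_spec("regular", cfg$n_mito, cfg$mito_dims)
  geom_ref <- build_regular(spec, cfg$cell_dims)
  species_tab <- scenario_species_table(cfg, "MCL1")
  tabs <- list()
  for (conc in cfg$concentrations_nM) {
    st <- species_tab
    st$conc_nM <- conc
    t1 <- pooled_translocation(geom_frag, cfg, st)$table
    t1$concentration_nM <- conc
    tabs[[as.character(conc)]] <- t1
  }
  # unfragmented reference cell at the reference concentration
  ref_conc <- cfg$mcl1_nM
  st <- species_tab
  st$conc_nM <- ref_conc
  ref_tab <- pooled_translocation(geom_ref, cfg, st,
                                  group = "reference_non_fragmented")$table
  ref_tab$concentration_nM <- ref_conc
  tab <- pool_replicates(tabs)
  per_conc <- lapply(split(tab, tab$concentration_nM), function(tt) {
    list(concentration_nM = tt$concentration_nM[1],
         brown_forsythe = brown_forsythe(split(tt$count_per_area, tt$group)),
         n = as.list(table(tt$group)))
  })
  # reference-concentration three-group comparison (reference cell
  # non-fragmented, fragmented-cell non-fragmented, fragmented)
  tt <- rbind(tab[tab$concentration_nM == ref_conc, ], ref_tab)
  groups3 <- split(tt$count_per_area, tt$group)
  ref_comparison <- list(
    kruskal = kruskal_dunn(groups3),
    brown_forsythe_all = brown_forsythe(groups3),
    brown_forsythe_frag = brown_forsythe(
      groups3[c("fragmented", "non_fragmented")]),
    per_volume_kruskal = kruskal_dunn(
      split(c(tt$count_per_volume), tt$group)))
  # pooled sweep comparison: densities normalized per concentration by the
  # concentration-wise overall median, then fragmented vs non-fragmented
  tabn <- do.call(rbind, lapply(split(tab, tab$concentration_nM), function(x) {
    x$norm_density <- x$count_per_area / median(x$count_per_area)
    x
  }))
  pooled_bf <- brown_forsythe(split(tabn$norm_density, tabn$group))
  list(scenario = cfg$scenario, table = tab, reference_table = ref_tab,
       per_concentration = per_conc, reference_comparison = ref_comparison,
       pooled_brown_forsythe = pooled_bf)
}

scenario_tbid <- function(cfg, stages, species_filter = NULL) {
  geom <- scenario_fragmented_geometry(cfg)
  which_sp <- species_filter %||% c("MCL1", "BAK", "tBID")
  species_tab <- scenario_species_table(cfg, which_sp)
  pt <- pooled_translocation(geom, cfg, species_tab)
  tab <- pt$table
  steady_stats <- lapply(setNames(which_sp, which_sp), function(sp) {
    ts <- tab[tab$species == sp, ]
    list(medians = mann_whitney(
           ts$count_per_area[ts$group == "non_fragmented"],
           ts$count_per_area[ts$group == "fragmented"]),
         variances = levene(split(ts$count_per_area, ts$group)))
  })
  out <- list(scenario = cfg$scenario, table = tab,
              steady_state = steady_stats, geometry = geom,
              runs = pt$runs)
  if ("reactions" %in% stages) {
    out$reactions <- run_reaction_stage(pt$runs[[1]], cfg)
  }
  out
}

#' Single-mitochondrion reaction stage over a whole cell
#'
#' Seeds every mitochondrion from the final whole-cell snapshot
#' ([seed_single_mito()]; retrotranslocation disabled), simulates the
#' reaction network on each, and pools the endpoint pore metrics
#' (aBAK4 + aBAK6, absolute and per membrane area).
#'
#' @param run a `whole_cell_run` providing the seeding snapshot.
#' @param cfg scenario config (provides reaction dt/duration and the seed).
#' @param network reaction network (default [default_network()]).
#' @param mito_ids subset of mitochondria to simulate (default all).
#' @return list with `pore_table` (per-mitochondrion endpoint metrics),
#'   `series` (pore counts over time per mitochondrion) and `stats`
#'   (fragmented vs non-fragmented comparison of pore densities).
#' @export
run_reaction_stage <- function(run, cfg, network = default_network(),
                               mito_ids = NULL) {
  rx <- cfg$reaction
  geom <- run$geometry
  gs <- geometry_summary(geom)
  ids <- mito_ids %||% gs$id
  V_c <- prod(geom$cell_dims)
  # one molecular parameter set for every mitochondrion: binding radii are
  # per-reaction molecular properties, derived once at the reference
  # (non-fragmented) mitochondrion area, so equal surface densities react at
  # equal per-molecule rates on every mitochondrion
  A_ref <- box_surface_area(cfg$mito_dims)
  meso <- build_meso_params(network, A_ref, V_c, rx$dt,
                            D_mem = cfg$translocation$D_mem,
                            seed = derive_seed(cfg$seed, 17L))
  pore_rows <- list()
  series_rows <- list()
  for (id in ids) {
    i <- match(id, gs$id)
    st <- seed_single_mito(run, id, seed = derive_seed(cfg$seed, 400L + id))
    res <- run_single_mito(st, network, meso, duration = rx$duration,
                           dt = rx$dt, record_interval = rx$record_interval,
                           seed = derive_seed(cfg$seed, 500L + id))
    ps <- res$pore_series
    ps$mito_id <- id
    series_rows[[length(series_rows) + 1L]] <- ps
    pore_rows[[length(pore_rows) + 1L]] <- data.frame(
      mito_id = id, fragmented = gs$fragmented[i], area = gs$area[i],
      pores = pore_metric(res$state),
      pores_per_area = pore_metric(res$state) / gs$area[i])
  }
  pore_table <- do.call(rbind, pore_rows)
  grp <- split(pore_table$pores_per_area,
               ifelse(pore_table$fragmented, "fragmented", "non_fragmented"))
  stats <- list(variances = levene(grp),
                medians = mann_whitney(grp$non_fragmented, grp$fragmented),
                max_non_fragmented = max(grp$non_fragmented),
                n_fragmented_above_nonfrag_max =
                  sum(grp$fragmented > max(grp$non_fragmented)))
  list(pore_table = pore_table, series = do.call(rbind, series_rows),
       stats = stats)
}

## ---------------------------------------------------------------------------
## Command layer and manifests

# round-trip a config through its manifest JSON representation so that a
# stage and its later re-run from the manifest compute from bit-identical
# inputs (JSON serialization of doubles is not exact at full precision)
canonicalize_config <- function(config) {
  cls <- class(config)
  out <- jsonlite::fromJSON(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                     force = TRUE),
    simplifyVector = TRUE)
  if (!is.null(out$replicate_seeds)) {
    out$replicate_seeds <- as.integer(out$replicate_seeds)
  }
  if (!is.null(out$subset_rule)) out$subset_rule <- as.list(out$subset_rule)
  if (length(out$pixel_size) == 0) out$pixel_size <- NULL
  class(out) <- cls
  out
}

write_manifest <- function(outdir, stage, config, outputs) {
  manifest <- list(stage = stage,
                   config = unclass(config),
                   outputs = lapply(outputs, function(f) {
                     list(file = f,
                          md5 = unname(tools::md5sum(file.path(outdir, f))))
                   }))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  path
}

#' Simulate a whole-cell scenario and write its outputs
#'
#' Runs the translocation stage of a scenario configuration with its
#' replicate seeds and writes: one snapshot CSV (+ JSON header) per
#' replicate of the scenario's primary geometry, the pooled
#' per-mitochondrion table, the scenario stats report, and a manifest.
#'
#' @param config a [make_experiment_config()] list.
#' @param outdir output directory (created if needed).
#' @return the scenario result list, invisibly; outputs on disk.
#' @export
cmd_simulate_cell <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- canonicalize_config(config)
  res <- run_scenario(config)
  outputs <- character()
  if (!is.null(res$table)) {
    write.csv(res$table, file.path(outdir, "per_mito.csv"),
              row.names = FALSE)
    outputs <- c(outputs, "per_mito.csv")
  }
  if (!is.null(res$runs)) {
    for (r in seq_along(res$runs)) {
      f <- sprintf("snapshot_rep%d.csv", r)
      write_snapshot(res$runs[[r]], file.path(outdir, f))
      outputs <- c(outputs, f, paste0(f, ".json"))
    }
  }
  if (!is.null(res$sweep)) {
    write.csv(res$sweep, file.path(outdir, "sweep.csv"), row.names = FALSE)
    outputs <- c(outputs, "sweep.csv")
  }
  stats <- res[setdiff(names(res), c("table", "runs", "geometry", "sweep",
                                     "reference_table"))]
  stats_report_to_json(stats, file.path(outdir, "stats_report.json"))
  outputs <- c(outputs, "stats_report.json")
  write_manifest(outdir, "simulate_cell", config, outputs)
  invisible(res)
}

#' Run the single-mitochondrion reaction stage and write its outputs
#'
#' @param config a tBID scenario config (`fig4_strong_tBID` or
#'   `fig5_weak_tBID`).
#' @param outdir output directory.
#' @return the scenario result list, invisibly.
#' @export
cmd_simulate_mito <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- canonicalize_config(config)
  res <- run_scenario(config, stages = c("translocation", "reactions"))
  write.csv(res$reactions$pore_table, file.path(outdir, "pore_table.csv"),
            row.names = FALSE)
  write.csv(res$reactions$series, file.path(outdir, "pore_series.csv"),
            row.names = FALSE)
  stats_report_to_json(res$reactions$stats,
                       file.path(outdir, "pore_stats.json"))
  write_manifest(outdir, "simulate_mito", config,
                 c("pore_table.csv", "pore_series.csv", "pore_stats.json"))
  invisible(res)
}

#' Statistical analysis of a per-mitochondrion table
#'
#' @param table a [densities()]-style data.frame or path to its CSV.
#' @param outdir output directory for the stats report JSON.
#' @param value,group columns compared (see [variance_report()]).
#' @return the report list, invisibly.
#' @export
cmd_analyze <- function(table, outdir, value = "count_per_area",
                        group = "group") {
  if (is.character(table)) table <- read.csv(table)
  if (nrow(table) == 0) stop_ms("empty table")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rep <- variance_report(table, value, group)
  stats_report_to_json(rep, file.path(outdir, "stats_report.json"))
  write_manifest(outdir, "analyze", list(value = value, group = group),
                 "stats_report.json")
  invisible(rep)
}

#' Quantify mitochondrial sizes in image files
#'
#' @param paths character vector of TIFF/PNG image paths.
#' @param outdir output directory.
#' @param ... passed to [quantify_image()].
#' @return combined SizeTable, invisibly.
#' @export
cmd_quantify_images <- function(paths, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- lapply(paths, function(p) {
    st <- quantify_image(read_gray_image(p), ...)
    st$source <- basename(p)
    st
  })
  tab <- do.call(rbind, tabs)
  write.csv(tab, file.path(outdir, "size_table.csv"), row.names = FALSE)
  write_manifest(outdir, "quantify_images", list(paths = basename(paths)),
                 "size_table.csv")
  invisible(tab)
}

#' Generate synthetic image fixtures
#'
#' @param spec a [synthetic_image_spec()].
#' @param outdir output directory; writes `synthetic.tif`, the ground-truth
#'   CSV and the spec YAML.
#' @return the [make_image()] result, invisibly.
#' @export
cmd_make_synthetic <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- canonicalize_config(spec)
  res <- make_image(spec)
  write_gray_image(res$image, file.path(outdir, "synthetic.tif"))
  write.csv(res$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(outdir, "spec.yaml"))
  write_manifest(outdir, "make_synthetic", spec,
                 c("synthetic.tif", "truth.csv", "spec.yaml"))
  invisible(res)
}

#' Re-run a pipeline stage from its manifest
#'
#' Reads a manifest written by one of the `cmd_*` stages and re-executes the
#' stage into a new directory; with unchanged package code this reproduces
#' byte-identical outputs.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param outdir output directory for the re-run.
#' @return the re-run manifest path, invisibly.
#' @export
rerun_from_manifest <- function(manifest_path, outdir) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  switch(man$stage,
         simulate_cell = cmd_simulate_cell(cfg, outdir),
         simulate_mito = cmd_simulate_mito(cfg, outdir),
         make_synthetic = cmd_make_synthetic(
           structure(cfg, class = "synthetic_image_spec"), outdir),
         stop_ms("cannot re-run stage '%s' from its manifest", man$stage))
  invisible(file.path(outdir, "manifest.json"))
}
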