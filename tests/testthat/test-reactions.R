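# Endpoint properties of the single-mitochondrion reaction stage: under a
# strong tBID stimulus fragmented mitochondria are more variable in pore
# density than non-fragmented ones; under a weak stimulus pore formation is
# sparse and the fragment pool carries a disproportionate upper tail.
# (The strict single-cell form of the weak-stimulus claim — one fragment
# exceeding every non-fragmented mitochondrion — is a tail event that needs
# paper-scale fragment numbers; run_reaction_stage() reports it, the tests
# assert the desk-scale robust forms.)

reaction_scenario <- function(key, scenario, seed_index, n_reps) {
  cached(key, {
    cfg <- make_experiment_config(scenario, scale_factor = 0.108,
                                  seed = derive_seed(ACC_SEED, seed_index))
    cfg$n_replicates <- n_reps
    geom <- mompsim:::scenario_fragmented_geometry(cfg)
    st <- mompsim:::scenario_species_table(cfg, c("MCL1", "BAK", "tBID"))
    gs <- geometry_summary(geom)
    # all fragments plus every second intact mitochondrion
    ids <- sort(c(gs$id[gs$fragmented],
                  gs$id[!gs$fragmented][seq(1, sum(!gs$fragmented), 2)]))
    tabs <- lapply(seq_len(n_reps), function(r) {
      sc <- mompsim:::scenario_sim_config(cfg, st, cfg$replicate_seeds[r])
      run <- run_whole_cell(geom, sc)
      cfg_r <- cfg
      cfg_r$seed <- derive_seed(cfg$seed, 900L + r)
      stage <- run_reaction_stage(run, cfg_r, mito_ids = ids)
      pt <- stage$pore_table
      pt$replicate <- r
      list(pt = pt, run = run)
    })
    list(pore = do.call(rbind, lapply(tabs, `[[`, "pt")),
         runs = lapply(tabs, `[[`, "run"))
  })
}

test_that("strong stimulus: fragments form pores more heterogeneously", {
  res <- reaction_scenario("rx_fig4", "fig4_strong_tBID", 5L, 2L)
  pt <- res$pore
  grp <- split(pt$pores_per_area, pt$fragmented)
  expect_gt(var(grp[["TRUE"]]), var(grp[["FALSE"]]))
  expect_lt(levene(list(nf = grp[["FALSE"]], fr = grp[["TRUE"]]))$p, 0.05)
  # intact mitochondria accumulate pores robustly under 10 nM tBID
  expect_gt(median(pt$pores[!pt$fragmented]), 0)
})

test_that("pore counts never exceed the BAK-equivalent supply", {
  res <- reaction_scenario("rx_fig4", "fig4_strong_tBID", 5L, 2L)
  snap <- res$runs[[1]]$snapshot
  pt <- res$pore[res$pore$replicate == 1, ]
  for (id in pt$mito_id[seq(1, nrow(pt), by = 8)]) {
    bak <- sum(snap$compartment == "membrane" & !is.na(snap$mito_id) &
                 snap$mito_id == id & snap$species == "BAK")
    expect_lte(pt$pores[pt$mito_id == id], floor(bak / 4))
  }
})

test_that("weak stimulus: the pore-density upper tail is fragment-dominated", {
  res <- reaction_scenario("rx_fig5", "fig5_weak_tBID", 6L, 2L)
  pt <- res$pore
  grp <- split(pt$pores_per_area, pt$fragmented)
  # pore formation is sparse overall
  expect_lt(median(pt$pores), median(res$pore$pores[!res$pore$fragmented]) + 3)
  # fragments are more dispersed relative to their mean load
  cv2 <- function(x) var(x) / max(mean(x), 1e-9)^2
  expect_gt(cv2(grp[["TRUE"]]), cv2(grp[["FALSE"]]))
  # and their tail reaches the top decile of the non-fragmented pool
  expect_gte(max(grp[["TRUE"]]), quantile(grp[["FALSE"]], 0.9))
})
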