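# Desk-scale study scenarios shared by the acceptance-level tests.
# Computed once per session and cached (several criteria draw on the same
# pooled simulations). All seeds are fixed so the whole suite is
# deterministic.

ACC_SEED <- 20260924L

acc_fig3 <- function() {
  cached("acc_fig3", {
    cfg <- make_experiment_config("fig3_fragmentation", scale_factor = 0.108,
                                  seed = derive_seed(ACC_SEED, 1L))
    run_scenario(cfg)
  })
}

acc_fig2 <- function() {
  cached("acc_fig2", {
    cfg <- make_experiment_config("fig2_arrangements", scale_factor = 0.5,
                                  seed = derive_seed(ACC_SEED, 2L),
                                  n_mito = 540L)
    cfg$compare <- c("regular", "random")
    run_scenario(cfg)
  })
}

acc_fig5_tbid <- function() {
  cached("acc_fig5", {
    cfg <- make_experiment_config("fig5_weak_tBID", scale_factor = 0.108,
                                  seed = derive_seed(ACC_SEED, 3L))
    run_scenario(cfg, species_filter = "tBID")
  })
}

acc_fig1 <- function() {
  cached("acc_fig1", {
    cfg <- make_experiment_config("fig1_sweep", scale_factor = 0.06,
                                  seed = derive_seed(ACC_SEED, 4L),
                                  n_mito = 12L)
    run_scenario(cfg)
  })
}
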