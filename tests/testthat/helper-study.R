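# The full default phantom study (500+500 train, 100+100 per validation
# split, tiny backbone at 128 px) is expensive, so it is trained once per
# test run, with a fixed seed committed here, and shared by every test that
# needs it.

STUDY_SEED <- 42L

full_study <- function() {
  memo("full_study", {
    cfg <- study_config()
    sim <- simulate_dataset(cfg$dataset, seed = STUDY_SEED)
    res <- run_study(cfg, seed = STUDY_SEED, sim = sim)
    res$sim <- sim
    res
  })
}
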