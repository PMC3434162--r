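# the reference synthetic study: 100-kb genome, 20 planted hairpins,
# 20 conserved decoy blocks; penalty selection over the full grid;
# scan and threshold sweep
run_synthetic_study <- function(seed) {
  bundle <- generate_genome(20, 100000L, seed = seed)
  cfg <- training_config(rng_seed = seed + 1L)
  model <- suppressWarnings(train_on_bundles(bundle, config = cfg))
  pred <- scan_genome(model, bundle$sequence, bundle$tracks,
                      window = 2000L, overlap = 400L, t_hairpin = 0.5)
  report <- evaluate_scan(pred$p_mi, pred$p_5end, bundle$truth,
                          thresholds = cfg$threshold_grid)
  list(bundle = bundle, model = model, pred = pred, report = report)
}
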