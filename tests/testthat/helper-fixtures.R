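# Shared fixtures, generated in code and cached for the session.

.fx <- new.env(parent = emptyenv())

# processed synthetic trial set; noise off by default for exactness checks
fx_trials <- function(seed = 11, noise = FALSE, n_cycles = 8) {
  key <- sprintf("trials_%d_%s_%d", seed, noise, n_cycles)
  if (is.null(.fx[[key]])) {
    cfg <- synthetic_config(
      seed = seed, n_cycles = n_cycles,
      semg_burst_sd = if (noise) 0.3 else 0,
      mt_drift_rate = if (noise) 0.05 else 0,
      moment_sd = if (noise) 2 else 0)
    .fx[[key]] <- prepare_trials(forward_generate(cfg))
  }
  .fx[[key]]
}

fx_true_params <- function() synthetic_config()$true_params

# ten-seed held-out accuracy benchmark shared by the acceptance checks
fx_benchmark <- function() {
  if (is.null(.fx$benchmark)) {
    .fx$benchmark <- hnm_benchmark(
      seeds = 1:10,
      variants = c("fused", "semg_only", "us_only", "random_signal"),
      single_speed = 0.50)
  }
  .fx$benchmark
}
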