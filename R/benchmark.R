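#' Held-out accuracy benchmark across variants, modes and seeds
#'
#' Repeats the whole study pipeline on freshly generated synthetic data for a
#' set of seeds: generate five-speed trials under the complementary-noise
#' model, calibrate the requested model variants (inter-speed mode, plus
#' optionally a single-speed mode), predict the held-out cycles at every
#' speed and compute accuracy metrics per speed. This is the engine behind
#' the fusion-advantage and inter-speed-robustness comparisons.
#'
#' @param seeds integer vector of seeds; each seed is an independent
#'   replicate (its own synthetic subject and cycle draw).
#' @param config a [synthetic_config()]; its `seed` field is replaced by each
#'   replicate seed in turn.
#' @param variants model variants to calibrate in inter-speed mode.
#' @param single_speed also calibrate the fused variant in single-speed mode
#'   at this speed (`NULL` to skip).
#' @param constants,control model constants and control settings.
#' @return A data frame with one row per seed, variant, mode and prediction
#'   speed: metric columns `rmse`, `n_rmse`, `bm_rmse`, `r2`.
#' @export
hnm_benchmark <- function(seeds = 1:10, config = synthetic_config(),
                          variants = c("fused", "semg_only", "us_only"),
                          single_speed = NULL,
                          constants = default_muscle_constants(),
                          control = hnm_control()) {
  rows <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    trials <- forward_generate(cfg, constants, control)
    ptrials <- prepare_trials(trials, constants, control)
    jobs <- lapply(variants, function(v) list(variant = v, mode = "inter",
                                              speed = NULL))
    if (!is.null(single_speed))
      jobs <- c(jobs, list(list(variant = "fused", mode = "single",
                                speed = single_speed)))
    for (job in jobs) {
      fit <- hnm_fit(ptrials, mode = job$mode, speed = job$speed,
                     variant = job$variant, constants = constants,
                     control = control, seed = s)
      met <- evaluate_fit(fit)
      met$seed <- s
      met$variant <- job$variant
      met$mode <- if (job$mode == "single")
        sprintf("single_%.2f", job$speed) else "inter"
      rows[[length(rows) + 1L]] <- met
    }
  }
  do.call(rbind, rows)
}
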