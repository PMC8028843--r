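# Small-scene configuration used throughout the unit tests: 3 lines (one per
# class) in triplicate, 40 bands, 10 px plots. Fast to simulate, same
# statistical structure as the default trial-scale scene.
small_config <- function(n_lines = 3, class_sizes = c(1, 1, 1), plot_px = 10,
                         ...) {
  sim_config(n_lines = n_lines, n_replicates = 3, n_bands = 40,
             plot_px = plot_px, gap_px = 2, class_sizes = class_sizes, ...)
}

small_sim <- function(seed = 1, ...) simulate_field(small_config(...), seed)

# single-row grid: skips the inner CV, keeps learner tests fast
fast_xgb_config <- function(seed = 1) {
  model_config("xgboost",
               grid = data.frame(max_depth = 4, eta = 0.3, nrounds = 40,
                                 gamma = 0, lambda = 1),
               seed = seed)
}
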