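# The full-scale simulation study (20 images x 10 observers at default
# behavioral parameters) is used by several end-to-end tests; it is computed
# once per session and cached.
.study_cache <- new.env(parent = emptyenv())

full_scale_study <- function() {
  if (!exists("res", .study_cache)) {
    ds <- simulate_dataset(n_images = 20, n_observers = 10, seed = 101)
    ev <- suppressMessages(evaluate_dataset(ds))
    assign("res", list(dataset = ds, eval = ev), .study_cache)
  }
  get("res", .study_cache)
}
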