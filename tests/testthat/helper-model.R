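# The full example model and its reference simulations are expensive to
# build and integrate, so they are computed once per test run and shared
# across test files.

.mitosim_cache <- new.env(parent = emptyenv())

cached_model <- function() {
  if (is.null(.mitosim_cache$model))
    .mitosim_cache$model <- build_cellcycle_model()
  .mitosim_cache$model
}

# calibrated model, mitogen + adhesion stepped on at 2e4 s, 10 days
cached_reference_run <- function() {
  if (is.null(.mitosim_cache$ref)) {
    m <- cached_model()
    sched <- stimulus_schedule(c(2e4, 2e4), c("mitogen", "adhesion"),
                               c(1, 1))
    .mitosim_cache$ref <- simulate_model(m, sched, t_end = 10 * 86400)
  }
  .mitosim_cache$ref
}

cached_reference_timeline <- function() {
  if (is.null(.mitosim_cache$tl))
    .mitosim_cache$tl <- detect_phases(cached_reference_run())
  .mitosim_cache$tl
}

# calibrated model with no mitogen: the quiescent (G0) run
cached_g0_run <- function(days = 10) {
  key <- paste0("g0_", days)
  if (is.null(.mitosim_cache[[key]]))
    .mitosim_cache[[key]] <- simulate_model(cached_model(),
                                            t_end = days * 86400)
  .mitosim_cache[[key]]
}
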