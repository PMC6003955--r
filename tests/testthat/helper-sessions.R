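# Shared synthetic fixtures, built once per test run and cached.
# The study population mirrors the default screening conditions: 20 position,
# 20 orientation and 20 untuned neurons at default gains, 30% of neurons
# reach-modulated (gain 2).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

small_population <- function() {
  fixture("small_pop",
          make_population(n_position = 2, n_orientation = 2, n_untuned = 2,
                          seed = 5))
}

small_session <- function() {
  fixture("small_session",
          simulate_session(small_population(), n_trials = 30, seed = 2))
}

study_population <- function() {
  fixture("study_pop",
          make_population(n_position = 20, n_orientation = 20,
                          n_untuned = 20, reach_fraction = 0.3,
                          reach_gain = 2, seed = 42))
}

study_session <- function() {
  fixture("study_session",
          simulate_session(study_population(), n_trials = 30, seed = 101))
}

# 100 untuned Poisson neurons with ~10 minutes of pre-docking data
untuned_session <- function() {
  fixture("untuned_session", {
    gt <- make_population(n_position = 0, n_orientation = 0,
                          n_untuned = 100, seed = 77)
    simulate_session(gt, n_trials = 34, seed = 78)
  })
}

small_assessment <- function() {
  fixture("small_assessment",
          assess_tuning(small_session(), keep_fits = TRUE))
}

# tuning assessment of the study session over the tuned neurons
study_assessment <- function() {
  fixture("study_assessment", {
    gt <- study_population()
    idx <- which(gt$class != "untuned")
    assess_tuning(study_session(), idx, keep_fits = TRUE)
  })
}
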