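# Shared fixtures, built lazily and memoized for the whole test run.
# Everything is generated in code; no stored data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# One reverberant capture condition of the default room (speech at 0 deg,
# noise source at +45 deg, 2 m).
default_condition <- function() {
  fixture("condition", function() {
    room <- room_spec()
    geo <- array_geometry()
    list(distance = 2, angle = 0,
         rir = simulate_rir(room, 2, 0, geo),
         noise_rir = simulate_rir(room, 2, 45, geo))
  })
}

test_noise_bank <- function() {
  fixture("bank", function() noise_bank(seed = 11))
}

# Small subject roster and scaled generator profile for synthesis tests.
test_profile <- function() generator_profile(duration_scale = 0.25)

test_subjects <- function() {
  fixture("subjects", function() generate_subjects(8, c(2, 2, 2, 2), seed = 5))
}

# The full default corpus metadata (100 subjects, 600 utterances at the
# calibrated durations); shared between composition and calibration
# checks.
default_corpus_meta <- function() {
  fixture("corpus_meta", function() {
    subjects <- generate_subjects(seed = 303)
    generate_corpus(subjects, generator_profile(), seed = 304)
  })
}

# Full end-to-end experiment under the documented reduced study size
# (32 subjects, 0.15 timing scale, 9 folds, 2 runs, 5 repeats).
e2e_experiment <- function() {
  fixture("e2e", function() {
    run_experiment(n_per_class = c(11, 7, 7, 7), duration_scale = 0.15,
                   folds = 9, runs = 2, repeats = 5, beamformer = "das",
                   seed = 1)
  })
}
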