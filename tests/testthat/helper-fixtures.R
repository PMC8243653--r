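# Shared fixtures, all generated in code. Expensive objects are built
# once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A clean (noise-free, wander-free, all-normal) record: degenerate
# morphology cases.
clean_normal_record <- function(n_beats = 100L, seed = 42L) {
  cached(sprintf("clean_%d_%d", n_beats, seed), {
    generate_record(
      synth_config(n_beats = n_beats, pac_rate = 0, pvc_rate = 0,
                   sd_rr = 0, resp_amp = 0, noise_sd = 0, wander_amp = 0,
                   seed = seed),
      patient_id = "clean01")
  })
}

# Default-world 300-beat record, preprocessed, with its features.
default_record_features <- function() {
  cached("default300", {
    g <- generate_record(synth_config(seed = 2024L), patient_id = "def01")
    pp <- preprocess_record(g$record, g$annotations)
    list(gen = g, pp = pp,
         features = assemble_features(pp$record, pp$annotations))
  })
}

# Small heterogeneous cohort feature table for model tests.
small_cohort_features <- function(n_patients = 8L, n_beats = 140L,
                                  seed = 5L) {
  cached(sprintf("cohort_%d_%d_%d", n_patients, n_beats, seed), {
    cohort <- generate_cohort(n_patients, seed = seed, n_beats = n_beats)
    do.call(rbind, lapply(cohort, function(g) {
      pp <- preprocess_record(g$record, g$annotations)
      assemble_features(pp$record, pp$annotations)
    }))
  })
}

# Sinusoid helper for filter tests.
sinusoid <- function(freq, fs, dur_s, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(round(dur_s * fs)) - 1) / fs)
}
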