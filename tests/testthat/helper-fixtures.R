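# Shared fixtures. Expensive ones are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Pure sine recording.
tone_rec <- function(freq = 200, dur = 1, amp = 0.5, fs = 44100) {
  tt <- (0:(round(dur * fs) - 1)) / fs
  audio_recording(amp * sin(2 * pi * freq * tt), fs)
}

# Tone bursts separated by silence, white noise everywhere, known
# active/silent power ratio. Returns the recording and the true ratio in dB.
snr_construction <- function(true_snr_db = 20, fs = 44100, seed = 9) {
  n <- 3 * fs
  tt <- (0:(fs - 1)) / fs
  sig <- numeric(n)
  sig[1:fs] <- 0.5 * sin(2 * pi * 200 * tt)
  sig[(2 * fs + 1):(3 * fs)] <- 0.5 * sin(2 * pi * 200 * tt)
  p_sig <- mean(sig[1:fs]^2)
  noise <- withr::with_seed(seed, rnorm(n, sd = sqrt(p_sig / 10^(true_snr_db / 10))))
  audio_recording(pmin(pmax(sig + noise, -1), 1), fs)
}

# Reduced sampler settings for unit tests that only need structure, not
# tight posterior summaries.
fast_model <- function(seed = 1, prior = "laplace", scale = 0.5) {
  model_config(prior = prior, scale = scale, chains = 2L, warmup = 300L,
               draws = 300L, seed = seed)
}

# Small separable feature cohort reused across classifier tests.
demo_cohort <- function() {
  cached("demo_cohort", {
    stratify_cohort(generate_cohort(
      cohort_config(effect_map = as.list(als_effect_map()), seed = 7)))
  })
}

# Standard clean voice fixture.
clean_voice <- function() {
  cached("clean_voice",
         synthesize_voice(voice_spec(f0_hz = 150, duration_s = 1, seed = 1)))
}
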