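# Shared fixtures, generated once per test run and cached.  Everything is
# seeded, so the suite is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, .fixture_cache)) assign(name, maker(), .fixture_cache)
  get(name, .fixture_cache)
}

# small training session: 6 trials/class, ~4 min of signal
small_session <- function() {
  fixture("small_session", function()
    generate_training_session(n_per_class = 6, seed = 42))
}

# mid-size session for decoder tests: 12 trials/class
mid_session <- function() {
  fixture("mid_session", function()
    generate_training_session(n_per_class = 12, seed = 7))
}

# a trained GvN decoder on the mid session
mid_gvn_model <- function() {
  fixture("mid_gvn_model", function() {
    s <- mid_session()
    train_decoder(s$recording, s$trials, "gvn", k = 6)
  })
}

# 40 s of pure pink-noise background on the default montage
noise_recording <- function(seconds = 40, seed = 5) {
  key <- paste0("noise_", seconds, "_", seed)
  fixture(key, function() with_seed(seed, {
    d <- matrix(0, 31, 500 * seconds)
    for (i in 1:31) d[i, ] <- pink_noise(500 * seconds, 500, 10)
    eeg_recording(d, default_montage()$channel_names, 500)
  }))
}

# controller input shorthands
cmd <- function(label) list(type = "CMD", label = label)
teb <- list(type = "TEB")

# an epoch of band-limited white noise on n channels
toy_epoch <- function(n_ch = 2, n_samp = 500, sds = rep(1, n_ch),
                      fs = 500, label = NA_character_) {
  list(data = matrix(stats::rnorm(n_ch * n_samp, sd = rep(sds, n_samp)),
                     n_ch, n_samp),
       fs = fs, label = label)
}
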