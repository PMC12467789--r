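# Shared fixtures: small simulated recordings, memoized per configuration
# so expensive generation is not repeated across tests.

.fix_env <- new.env(parent = emptyenv())

fixture_recording <- function(pattern = "normal", duration = 20,
                              noise_sd = 0.5, seed = 1L,
                              cycle_jitter_cv = NULL) {
  key <- paste(pattern, duration, noise_sd, seed,
               if (is.null(cycle_jitter_cv)) "def" else cycle_jitter_cv,
               sep = "|")
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- simulate_recording(sim_config(
      pattern = pattern, duration = duration, noise_sd = noise_sd,
      seed = seed, cycle_jitter_cv = cycle_jitter_cv))
  .fix_env[[key]]
}

# labeled phases for a recording, memoized alongside it
fixture_labels <- function(rec) {
  key <- paste0("lab|", rec$pattern, "|", length(rec$t), "|",
                signif(sum(rec$ankle), 12))
  if (is.null(.fix_env[[key]])) {
    sag <- sagittal_channels(rec)
    .fix_env[[key]] <- label_phases(sag$left, sag$right)
  }
  .fix_env[[key]]
}

# separable 4-cluster feature set for classifier sanity checks
fixture_clusters <- function(n = 400, seed = 42, noise = 0.5) {
  set.seed(seed)
  cls <- sample(rep(1:4, each = n / 4))
  centers <- matrix(0, 4, 6)
  centers[2, 1] <- 10; centers[3, 2] <- 10; centers[4, 3] <- 10
  x <- centers[cls, ] + matrix(rnorm(n * 6, 0, noise), n, 6)
  list(x = x, class = cls)
}
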