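# Shared fixtures: small configurations and hand-built timelines.

quiet_cfg <- function(b = 1.0, sigma = 0.3, n_taps = 36, seed = 1, ...) {
  p <- player_params(b = b, sigma = sigma)
  sim_config(params_p1 = p, params_p2 = p, n_taps = n_taps, seed = seed, ...)
}

uncoupled_cfg <- function(sigma = 0, n_taps = 36, seed = 1, ...) {
  p <- player_params(a = 0, b = 0, k = 0, sigma = sigma)
  sim_config(params_p1 = p, params_p2 = p, n_taps = n_taps, seed = seed, ...)
}

# deterministic toy timelines (times in seconds)
toy_timeline <- function() {
  pair_timeline(c(0, 0.48, 1.01), c(0.01, 0.49, 1.0))
}

# a tiny hand-assembled stimulus set of two timelines
toy_set <- function() {
  tls <- list(pair_timeline(c(0, 0.48, 1.01), c(0.01, 0.49, 1.0)),
              pair_timeline(c(0, 0.5, 1.0), c(0, 0.5, 1.0)))
  stim <- lapply(seq_along(tls), function(i)
    pairtap:::.stimulus(id = sprintf("toy-%02d", i), timeline = tls[[i]],
                        profile = NULL, distance = i - 1, rank = i,
                        seed = NULL))
  pairtap:::.stimulus_set("HUM", 1.0, stim, ensemble_mean = NULL,
                          config = NULL, reps = 2, base_seed = 0,
                          wdcc_args = list())
}
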