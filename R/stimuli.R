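# Stimulus-generation pipeline: HUM (humanized), RAN (asynchrony-shuffled
# surrogate) and ISO (near-isochronous) stimulus sets, selected from simulated
# ensembles by closeness of their WDCC profile to the ensemble mean.

#' Squared distance between two WDCC profiles
#'
#' Sum over lags of the squared coefficient difference.
#'
#' @param profile,reference `wdcc_profile` objects (or data.frames with
#'   `lag` and `coefficient`) on identical lag grids.
#' @return Non-negative scalar.
#' @export
wdcc_distance <- function(profile, reference) {
  if (!identical(as.integer(profile$lag), as.integer(reference$lag)))
    stop("profiles have mismatched lag grids")
  sum((profile$coefficient - reference$coefficient)^2)
}

.stimulus <- function(id, timeline, profile, distance, rank, seed,
                      shuffle = NULL, source_id = NULL) {
  list(id = id, timeline = timeline, profile = profile, distance = distance,
       rank = rank, seed = seed, shuffle = shuffle, source_id = source_id)
}

.stimulus_set <- function(label, b_level, stimuli, ensemble_mean, config,
                          reps, base_seed, wdcc_args) {
  structure(list(label = label, b_level = b_level, stimuli = stimuli,
                 ensemble_mean_profile = ensemble_mean, config = config,
                 reps = reps, base_seed = base_seed, wdcc_args = wdcc_args),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set %s (b = %g): %d stimuli selected from %d runs\n",
              x$label, x$b_level, length(x$stimuli), x$reps))
  invisible(x)
}

# Simulate `reps` pair timelines (seed = base_seed + run index), WDCC the ITI
# pair of each, and keep the `keep` runs closest (sum of squared coefficient
# differences) to the ensemble-mean profile. Degenerate runs are re-drawn
# with fresh seeds beyond the base range, up to `max_retries`.
.generate_selected_set <- function(config, reps, keep, label,
                                   max_lag, window_len, window_step,
                                   max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"), reps >= keep, keep >= 1)
  base_seed <- config$seed
  if (is.null(base_seed))
    stop("ensemble generation needs a base seed in the sim_config")
  timelines <- vector("list", reps)
  coefs <- NULL
  retries <- 0L
  for (i in seq_len(reps)) {
    repeat {
      seed_i <- if (retries == 0L) base_seed + i else base_seed + reps + retries
      cfg_i <- config
      cfg_i$seed <- seed_i
      tl <- tryCatch(simulate_pair(cfg_i), error = function(e) e)
      if (!inherits(tl, "error")) break
      retries <- retries + 1L
      message("run ", i, " degenerate (", conditionMessage(tl),
              "); re-drawing with seed ", base_seed + reps + retries)
      if (retries > max_retries)
        stop("exceeded ", max_retries, " degenerate-run retries")
    }
    timelines[[i]] <- tl
    pr <- wdcc(compute_iti(tl, 1), compute_iti(tl, 2),
               max_lag = max_lag, window_len = window_len,
               window_step = window_step)
    if (is.null(coefs)) coefs <- matrix(NA_real_, reps, nrow(pr))
    coefs[i, ] <- pr$coefficient
  }
  lags <- seq.int(-max_lag, max_lag)
  mean_coef <- colMeans(coefs)
  ensemble_mean <- structure(
    data.frame(lag = lags, coefficient = mean_coef, n_windows = NA_integer_),
    window_len = as.integer(window_len), window_step = as.integer(window_step),
    class = c("wdcc_profile", "data.frame"))
  dist <- rowSums(sweep(coefs, 2, mean_coef)^2)
  sel <- order(dist)[seq_len(keep)]
  stimuli <- lapply(seq_along(sel), function(r) {
    i <- sel[r]
    pr <- structure(
      data.frame(lag = lags, coefficient = coefs[i, ], n_windows = NA_integer_),
      window_len = as.integer(window_len), window_step = as.integer(window_step),
      class = c("wdcc_profile", "data.frame"))
    .stimulus(id = sprintf("%s-b%g-%02d", tolower(label),
                           config$params_p1$b, r),
              timeline = timelines[[i]], profile = pr,
              distance = dist[i], rank = r, seed = timelines[[i]]$seed)
  })
  .stimulus_set(label, config$params_p1$b, stimuli, ensemble_mean, config,
                reps, base_seed,
                list(max_lag = max_lag, window_len = window_len,
                     window_step = window_step))
}

#' Generate a humanized (HUM) stimulus set
#'
#' Simulates `reps` tapping pairs from the coupled-oscillator model, computes
#' the WDCC profile of each pair's ITI series, and selects the `keep` pairs
#' whose profiles are closest (squared distance, [wdcc_distance()]) to the
#' ensemble-mean profile. Run `i` uses seed `config$seed + i`.
#'
#' @param config a [sim_config()] with a non-`NULL` seed (the ensemble base
#'   seed).
#' @param reps ensemble size (default 1000).
#' @param keep number of stimuli selected (default 20).
#' @param max_lag,window_len,window_step WDCC settings (see [wdcc()]).
#' @return A `stimulus_set` with fields `label`, `b_level`, `stimuli` (each
#'   carrying its timeline, WDCC profile, distance and rank), and
#'   `ensemble_mean_profile`.
#' @export
#' @examples
#' \donttest{
#' hum <- generate_hum_set(sim_config(seed = 1), reps = 50, keep = 5)
#' summarize_set(hum)$group
#' }
generate_hum_set <- function(config, reps = 1000, keep = 20,
                             max_lag = 10, window_len = 15, window_step = 1) {
  .generate_selected_set(config, reps, keep, "HUM",
                         max_lag, window_len, window_step)
}

#' Generate an isochronous (ISO) stimulus set
#'
#' Identical machinery to [generate_hum_set()] but with the phase-noise
#' strength lowered to `sigma` (default 0.01) for both players, which keeps
#' ITI fluctuations below the perceptual threshold, and `keep = 10`.
#'
#' @param config a [sim_config()]; its players' `sigma` is overridden.
#' @param reps ensemble size (default 1000).
#' @param keep number of stimuli selected (default 10).
#' @param sigma noise strength used for both players (default 0.01).
#' @inheritParams generate_hum_set
#' @return A `stimulus_set` labelled `"ISO"`.
#' @export
generate_iso_set <- function(config, reps = 1000, keep = 10, sigma = 0.01,
                             max_lag = 10, window_len = 15, window_step = 1) {
  config$params_p1$sigma <- sigma
  config$params_p2$sigma <- sigma
  .generate_selected_set(config, reps, keep, "ISO",
                         max_lag, window_len, window_step)
}

#' Randomize one stimulus by asynchrony shuffling
#'
#' Builds the surrogate of a timeline that destroys the cross-correlation
#' structure while conserving the pair's mean timing and the multiset of
#' asynchronies: the halved asynchrony series `a/2` is permuted `shuffles`
#' times, each candidate reconstructed as `t(1) = m + d_rand`,
#' `t(2) = m - d_rand` (with `m` the mean-timing series), and the candidate
#' whose WDCC profile is closest to the mean profile of all candidates is
#' returned. Candidates with non-monotone tap times are discarded and
#' redrawn.
#'
#' The returned timeline's asynchrony series is exactly a permutation of the
#' source's, and its mean-timing series equals the source's; for timelines
#' produced by [simulate_pair()] (tap times on a dyadic 2^-20 s grid) both
#' invariants hold bit-exactly.
#'
#' @param hum a source `pair_timeline`.
#' @param shuffles number of candidate permutations (default 1000).
#' @param seed seed for the permutation draws (or `NULL`).
#' @param max_lag,window_len,window_step WDCC settings (see [wdcc()]).
#' @return List with `timeline` (the selected surrogate), `shuffle` (the
#'   permutation applied to the halved asynchronies), `profile`, `distance`
#'   and `n_discarded`.
#' @export
randomize_stimulus <- function(hum, shuffles = 1000, seed = NULL,
                               max_lag = 10, window_len = 15,
                               window_step = 1) {
  stopifnot(inherits(hum, "pair_timeline"), shuffles >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(hum$taps_p1)
  a <- hum$taps_p1 - hum$taps_p2            # exact for nearby tap times
  h <- 0.5 * a                              # halved asynchronies (s)
  m <- 0.5 * (hum$taps_p1 + hum$taps_p2)    # mean timing (s)

  perms <- vector("list", shuffles)
  cand <- vector("list", shuffles)
  coefs <- NULL
  discarded <- 0L
  for (s in seq_len(shuffles)) {
    repeat {
      perm <- sample.int(n)
      d <- h[perm]
      t1 <- m + d
      t2 <- m - d
      if (!is.unsorted(t1, strictly = TRUE) &&
          !is.unsorted(t2, strictly = TRUE)) break
      discarded <- discarded + 1L
      if (discarded > 100L * shuffles)
        stop("could not construct monotone surrogate timelines")
    }
    perms[[s]] <- perm
    tl <- pair_timeline(t1, t2, seed = seed, config = hum$config)
    cand[[s]] <- tl
    pr <- wdcc(compute_iti(tl, 1), compute_iti(tl, 2),
               max_lag = max_lag, window_len = window_len,
               window_step = window_step)
    if (is.null(coefs)) coefs <- matrix(NA_real_, shuffles, nrow(pr))
    coefs[s, ] <- pr$coefficient
  }
  mean_coef <- colMeans(coefs)
  dist <- rowSums(sweep(coefs, 2, mean_coef)^2)
  best <- which.min(dist)
  lags <- seq.int(-max_lag, max_lag)
  pr <- structure(
    data.frame(lag = lags, coefficient = coefs[best, ],
               n_windows = NA_integer_),
    window_len = as.integer(window_len), window_step = as.integer(window_step),
    class = c("wdcc_profile", "data.frame"))
  if (discarded > 0L)
    message(discarded, " non-monotone surrogate candidate(s) discarded")
  list(timeline = cand[[best]], shuffle = perms[[best]], profile = pr,
       distance = dist[best], n_discarded = discarded)
}

#' Generate the randomized (RAN) set from a HUM set
#'
#' Applies [randomize_stimulus()] to every stimulus of a HUM set (one RAN per
#' source HUM, `shuffles` candidate permutations each). Each RAN stimulus
#' inherits its source's rank, so example/practice selection by rank pairs
#' HUM and RAN stimuli. Group asynchrony statistics of the RAN set equal the
#' HUM set's exactly (permutation invariance).
#'
#' @param hum_set a `stimulus_set` from [generate_hum_set()].
#' @param shuffles candidate permutations per stimulus (default 1000).
#' @param seed base seed; stimulus `i` uses `seed + i`. Defaults to the HUM
#'   set's base seed shifted by 10^6.
#' @inheritParams generate_hum_set
#' @return A `stimulus_set` labelled `"RAN"`.
#' @export
generate_ran_set <- function(hum_set, shuffles = 1000, seed = NULL,
                             max_lag = 10, window_len = 15, window_step = 1) {
  stopifnot(inherits(hum_set, "stimulus_set"))
  if (is.null(seed)) seed <- hum_set$base_seed + 1000000L
  stimuli <- lapply(seq_along(hum_set$stimuli), function(i) {
    src <- hum_set$stimuli[[i]]
    r <- randomize_stimulus(src$timeline, shuffles = shuffles,
                            seed = seed + i, max_lag = max_lag,
                            window_len = window_len,
                            window_step = window_step)
    .stimulus(id = sub("^hum", "ran", src$id), timeline = r$timeline,
              profile = r$profile, distance = r$distance, rank = src$rank,
              seed = seed + i, shuffle = r$shuffle, source_id = src$id)
  })
  .stimulus_set("RAN", hum_set$b_level, stimuli,
                ensemble_mean = NULL, config = hum_set$config,
                reps = shuffles, base_seed = seed,
                wdcc_args = list(max_lag = max_lag, window_len = window_len,
                                 window_step = window_step))
}

#' Select the five example/practice stimuli of a 20-stimulus set
#'
#' Returns the stimuli at ranks 1, 5, 10, 15 and 20 when the 20 stimuli are
#' sorted by distance from the ensemble-mean WDCC profile, spanning the range
#' of cross-correlation structures in the set.
#'
#' @param set a 20-stimulus `stimulus_set`.
#' @return A `stimulus_set` containing the five selected stimuli (original
#'   ranks retained).
#' @export
select_examples <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  if (length(set$stimuli) != 20)
    stop("example selection is defined for 20-stimulus sets, got ",
         length(set$stimuli))
  ranks <- vapply(set$stimuli, function(s) s$rank, 0)
  pick <- match(c(1, 5, 10, 15, 20), ranks)
  out <- set
  out$stimuli <- set$stimuli[pick]
  out
}
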