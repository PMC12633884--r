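test_that("WDCC distance is a sum of squared coefficient differences", {
  set.seed(21)
  x <- rnorm(35); y <- rnorm(35)
  p <- wdcc(x, y)
  expect_equal(wdcc_distance(p, p), 0)
  q <- p
  q$coefficient <- q$coefficient + 0.1
  expect_equal(wdcc_distance(p, q), 21 * 0.01)
  # independently coded sum of squares
  r <- wdcc(rnorm(35), rnorm(35))
  expect_equal(wdcc_distance(p, r), sum((p$coefficient - r$coefficient)^2))
  r$lag <- r$lag + 1
  expect_error(wdcc_distance(p, r), "mismatched lag")
})

test_that("ensemble selection keeps the runs closest to the mean profile", {
  hum <- generate_hum_set(quiet_cfg(seed = 100), reps = 30, keep = 6)
  expect_s3_class(hum, "stimulus_set")
  expect_length(hum$stimuli, 6)
  d <- vapply(hum$stimuli, function(s) s$distance, 0)
  expect_equal(vapply(hum$stimuli, function(s) s$rank, 0), seq_len(6))
  expect_equal(d, sort(d)) # ranks ordered by ascending distance
  # selection optimality: re-simulate the full ensemble and check no
  # unselected run beats a selected one
  all_d <- vapply(seq_len(30), function(i) {
    cfg <- quiet_cfg(seed = 100)
    cfg$seed <- 100 + i
    tl <- simulate_pair(cfg)
    wdcc_distance(wdcc(compute_iti(tl, 1), compute_iti(tl, 2)),
                  hum$ensemble_mean_profile)
  }, 0)
  expect_equal(sort(all_d)[seq_len(6)], d)
  # every run has the full tap count
  expect_true(all(vapply(hum$stimuli,
                         function(s) length(s$timeline$taps_p1), 0L) == 36))
  # reps = keep keeps everything
  all_kept <- generate_hum_set(quiet_cfg(seed = 200, n_taps = 26),
                               reps = 5, keep = 5)
  expect_length(all_kept$stimuli, 5)
})

test_that("randomization conserves asynchronies and mean timing bit-exactly", {
  hum <- simulate_pair(quiet_cfg(seed = 33))
  r <- randomize_stimulus(hum, shuffles = 50, seed = 44)
  ran <- r$timeline
  expect_length(r$shuffle, 36)
  expect_setequal(r$shuffle, seq_len(36)) # a bijection on tap indices
  expect_identical(sort(compute_asynchrony(ran)), sort(compute_asynchrony(hum)))
  expect_identical(mean_timing(ran), mean_timing(hum))
  # asynchrony series is the permuted source series
  expect_identical(compute_asynchrony(ran), compute_asynchrony(hum)[r$shuffle])
  # per-stimulus mean and SD of asynchrony are exactly conserved
  expect_identical(mean(compute_asynchrony(ran)), mean(compute_asynchrony(hum)))
  expect_identical(sd(compute_asynchrony(ran)), sd(compute_asynchrony(hum)))
})

test_that("an identity permutation reconstructs the source timeline", {
  hum <- simulate_pair(quiet_cfg(seed = 35))
  m <- 0.5 * (hum$taps_p1 + hum$taps_p2)
  h <- 0.5 * (hum$taps_p1 - hum$taps_p2)
  expect_identical(m + h, hum$taps_p1)
  expect_identical(m - h, hum$taps_p2)
})

test_that("a single-shuffle ensemble degenerates to one random permutation", {
  hum <- simulate_pair(quiet_cfg(seed = 36))
  r <- randomize_stimulus(hum, shuffles = 1, seed = 9)
  expect_equal(r$distance, 0) # only candidate equals the ensemble mean
  expect_identical(sort(compute_asynchrony(r$timeline)),
                   sort(compute_asynchrony(hum)))
})

test_that("RAN sets inherit size, ranks and exact group asynchrony stats", {
  hum <- generate_hum_set(quiet_cfg(seed = 300), reps = 12, keep = 4)
  ran <- generate_ran_set(hum, shuffles = 20)
  expect_identical(ran$label, "RAN")
  expect_length(ran$stimuli, 4)
  expect_equal(vapply(ran$stimuli, function(s) s$rank, 0),
               vapply(hum$stimuli, function(s) s$rank, 0))
  gh <- summarize_set(hum)$group
  gr <- summarize_set(ran)$group
  expect_identical(gr$mean_async, gh$mean_async)
  expect_identical(gr$sd_async, gh$sd_async)
})

test_that("ISO generation lowers the noise and keeps 10 stimuli by default", {
  iso <- generate_iso_set(quiet_cfg(seed = 400), reps = 15, keep = 10)
  expect_identical(iso$label, "ISO")
  expect_length(iso$stimuli, 10)
  expect_equal(iso$config$params_p1$sigma, 0.01)
  g <- summarize_set(iso)$group
  expect_lt(g["mean", "sd_iti_p1"], 2)       # far below the HUM ~17-20 ms
  expect_lt(abs(g["mean", "mean_async"]), 1) # near-perfect synchrony
})

test_that("example selection returns the rank {1,5,10,15,20} stimuli", {
  hum <- generate_hum_set(quiet_cfg(seed = 500, n_taps = 26), reps = 20, keep = 20)
  ex <- select_examples(hum)
  expect_length(ex$stimuli, 5)
  ranks <- vapply(ex$stimuli, function(s) s$rank, 0)
  expect_equal(ranks, c(1, 5, 10, 15, 20))
  d <- vapply(hum$stimuli, function(s) s$distance, 0)
  dx <- vapply(ex$stimuli, function(s) s$distance, 0)
  expect_equal(min(dx), min(d)) # spans the set's distance range
  expect_equal(max(dx), max(d))
  expect_identical(vapply(select_examples(hum)$stimuli, function(s) s$id, ""),
                   vapply(ex$stimuli, function(s) s$id, ""))
  too_small <- hum
  too_small$stimuli <- hum$stimuli[1:7]
  expect_error(select_examples(too_small), "20-stimulus")
})

test_that("pipeline is reproducible at fixed seeds", {
  h1 <- generate_hum_set(quiet_cfg(seed = 600, n_taps = 26), reps = 8, keep = 3)
  h2 <- generate_hum_set(quiet_cfg(seed = 600, n_taps = 26), reps = 8, keep = 3)
  expect_identical(lapply(h1$stimuli, function(s) s$timeline$taps_p1),
                   lapply(h2$stimuli, function(s) s$timeline$taps_p1))
  r1 <- generate_ran_set(h1, shuffles = 10)
  r2 <- generate_ran_set(h2, shuffles = 10)
  expect_identical(lapply(r1$stimuli, function(s) s$shuffle),
                   lapply(r2$stimuli, function(s) s$shuffle))
})
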