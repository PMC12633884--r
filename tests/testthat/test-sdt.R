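test_that("trial schedules have the exact phase compositions", {
  sch <- make_trial_schedule(seed = 1)
  ex <- sch[sch$phase == "example", ]
  expect_equal(table(ex$stimulus_class)[c("HUM", "RAN", "ISO")],
               table(factor(c("HUM", "HUM", "RAN", "RAN", "ISO")))[c("HUM", "RAN", "ISO")])
  pr <- sch[sch$phase == "practice", ]
  expect_equal(nrow(pr), 9)
  expect_true(all(table(pr$stimulus_class) == 3))
  main <- sch[sch$phase == "main", ]
  expect_equal(nrow(main), 36)
  expect_equal(sum(main$stimulus_class == "ISO"), 6)
  expect_equal(sum(main$stimulus_class == "HUM"), 15)
  expect_equal(sum(main$stimulus_class == "RAN"), 15)
  for (b in 1:3) {
    blk <- main[main$block == b, ]
    expect_equal(nrow(blk), 12)
    expect_equal(sum(blk$stimulus_class == "ISO"), 2)
    expect_equal(sum(blk$stimulus_class == "HUM"), 5)
  }
  # HUM/RAN example and practice stimuli come from the rank-selection subset
  expect_true(all(sch$stimulus_rank[sch$phase != "main" &
                                      sch$stimulus_class != "ISO"] %in%
                    c(1, 5, 10, 15, 20)))
  # determinism
  expect_identical(make_trial_schedule(seed = 7), make_trial_schedule(seed = 7))
})

test_that("screening applies the two behavioral criteria at >= 2", {
  sch <- make_trial_schedule(seed = 2)
  ok <- simulate_listener(2, 0, sch, seed = 1, participant_id = "p-ok")
  # two timeouts in the main task
  to <- simulate_listener(2, 0, sch, seed = 2, participant_id = "p-to")
  idx <- which(to$phase == "main")[1:2]
  to$response[idx] <- "timeout"
  # judged ISO human-like twice in the main task
  iso <- simulate_listener(2, 0, sch, seed = 3, participant_id = "p-iso")
  ii <- which(iso$phase == "main" & iso$stimulus_class == "ISO")
  iso$response[ii] <- "not-human-like"
  iso$response[ii[1:2]] <- "human-like"
  # one ISO slip and one timeout: kept ("twice or more" thresholds)
  one <- simulate_listener(2, 0, sch, seed = 4, participant_id = "p-one")
  one$response[ii] <- "not-human-like"
  one$response[ii[1]] <- "human-like"
  one$response[which(one$phase == "main")[3]] <- "timeout"
  tab <- rbind(ok, to, iso, one)
  scr <- screen_participants(tab)
  expect_setequal(scr$kept, c("p-ok", "p-one"))
  expect_equal(scr$excluded$reason[scr$excluded$participant_id == "p-to"],
               "timeout>=2")
  expect_equal(scr$excluded$reason[scr$excluded$participant_id == "p-iso"],
               "iso_error>=2")
  # order-independence and idempotence over participants
  scr2 <- screen_participants(tab[sample(nrow(tab)), ])
  expect_setequal(scr2$kept, scr$kept)
  # practice-phase behavior never triggers exclusion
  pr_to <- simulate_listener(2, 0, sch, seed = 5, participant_id = "p-pr")
  pr_to$response[pr_to$phase == "practice"] <- "timeout"
  expect_equal(screen_participants(pr_to)$kept, "p-pr")
  # empty table, unknown class
  empty <- screen_participants(tab[0, ])
  expect_length(empty$kept, 0)
  bad <- ok
  bad$stimulus_class[1] <- "XYZ"
  expect_error(screen_participants(bad), "unknown stimulus_class")
})

test_that("response rates divide human-like counts by non-timeout counts", {
  sch <- make_trial_schedule(seed = 3)
  tab <- simulate_listener(1, 0, sch, seed = 6, participant_id = "p1")
  hum_idx <- which(tab$phase == "main" & tab$stimulus_class == "HUM")
  tab$response[hum_idx] <- "human-like"
  tab$response[hum_idx[1]] <- "timeout"
  tab$response[hum_idx[2:7]] <- "not-human-like"
  rr <- response_rates(tab, "p1")
  hum <- rr[rr$stimulus_class == "HUM", ]
  expect_equal(hum$n_valid, 14)
  expect_equal(hum$rate, 8 / 14)
  # all timeouts -> undefined, flagged not thrown
  tab$response[tab$phase == "main" & tab$stimulus_class == "RAN"] <- "timeout"
  rr <- response_rates(tab, "p1")
  expect_true(rr$undefined[rr$stimulus_class == "RAN"])
  expect_true(is.na(rr$rate[rr$stimulus_class == "RAN"]))
  # all human-like -> 1
  tab$response[tab$phase == "main" & tab$stimulus_class == "ISO"] <- "human-like"
  rr <- response_rates(tab, "p1")
  expect_equal(rr$rate[rr$stimulus_class == "ISO"], 1)
})

test_that("d-prime and criterion match their closed forms", {
  r <- compute_dprime_c(0.5, 0.5, 15, 15)
  expect_equal(r$d_prime, 0)
  expect_equal(r$criterion, 0)
  r <- compute_dprime_c(0.8413, 0.1587, 1000, 1000)
  expect_equal(r$d_prime, 2, tolerance = 1e-3)
  expect_equal(r$criterion, 0, tolerance = 1e-6)
  # equal high rates: no sensitivity, liberal ("human-like") bias positive
  r <- compute_dprime_c(0.9, 0.9, 1000, 1000)
  expect_equal(r$d_prime, 0)
  expect_equal(r$criterion, -qnorm(0.9), tolerance = 1e-12)
  expect_equal(r$criterion, -1.2816, tolerance = 1e-4)
  # antisymmetry: swapping H and F negates d', |C| unchanged
  a <- compute_dprime_c(0.8, 0.3, 15, 15)
  b <- compute_dprime_c(0.3, 0.8, 15, 15)
  expect_equal(a$d_prime, -b$d_prime)
  expect_equal(abs(a$criterion), abs(b$criterion))
  # extreme proportions get the 1/(2N) adjustment
  r <- compute_dprime_c(1, 0, 15, 15)
  expect_equal(r$h, 1 - 1 / 30)
  expect_equal(r$f, 1 / 30)
  expect_equal(r$d_prime, 2 * qnorm(1 - 1 / 30))
  expect_error(compute_dprime_c(0.5, 0.5, 0, 15), "positive")
})

test_that("synthetic listener parameters are recovered by scoring", {
  big <- data.frame(phase = "main", block = 1L, trial = 1:20000,
                    stimulus_class = rep(c("HUM", "RAN"), each = 10000),
                    stimulus_rank = 1L)
  tab <- simulate_listener(1.5, 0.4, big, seed = 10, participant_id = "sim")
  rr <- response_rates(tab, "sim")
  r <- compute_dprime_c(rr$rate[rr$stimulus_class == "HUM"],
                        rr$rate[rr$stimulus_class == "RAN"], 10000, 10000)
  expect_equal(r$d_prime, 1.5, tolerance = 0.07)
  expect_equal(r$criterion, 0.4, tolerance = 0.05)
  # d' = 0 observer recovers ~0
  tab0 <- simulate_listener(0, 0, big, seed = 11)
  rr0 <- response_rates(tab0, "synthetic-01")
  r0 <- compute_dprime_c(rr0$rate[rr0$stimulus_class == "HUM"],
                         rr0$rate[rr0$stimulus_class == "RAN"], 10000, 10000)
  expect_lt(abs(r0$d_prime), 0.1)
  # criterion shifts recovered C monotonically
  cs <- vapply(c(-0.5, 0, 0.5), function(ct) {
    tb <- simulate_listener(1, ct, big, seed = 12)
    rr <- response_rates(tb, "synthetic-01")
    compute_dprime_c(rr$rate[rr$stimulus_class == "HUM"],
                     rr$rate[rr$stimulus_class == "RAN"],
                     10000, 10000)$criterion
  }, 0)
  expect_true(all(diff(cs) > 0))
})

test_that("participant-level scoring table flags exclusions", {
  sch <- make_trial_schedule(seed = 4)
  good <- simulate_listener(2, 0.2, sch, seed = 20, participant_id = "a")
  bad <- simulate_listener(0, 0, sch, seed = 21, participant_id = "b")
  bad$response[which(bad$phase == "main")[1:3]] <- "timeout"
  out <- sdt_summary(rbind(good, bad))
  expect_equal(nrow(out), 2)
  expect_false(out$excluded[out$participant_id == "a"])
  expect_true(out$excluded[out$participant_id == "b"])
  expect_equal(out$reason[out$participant_id == "b"], "timeout>=2")
  expect_gt(out$d_prime[out$participant_id == "a"], 0)
})
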