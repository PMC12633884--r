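# Trial scheduling, participant screening, response rates, and
# signal-detection scoring (d', criterion C) for the HUM/RAN/ISO listening
# experiment, plus a synthetic equal-variance Gaussian listener for
# end-to-end testing.

#' Build the trial schedule of one experimental session
#'
#' Three phases: examples (HUM presented twice, RAN twice, ISO once),
#' practice (nine trials: HUM, RAN and ISO three times each, random order),
#' and the main task (three blocks of twelve trials; each block holds five
#' HUM, five RAN and two ISO trials in random order). HUM/RAN example and
#' practice stimuli are drawn from the rank-{1, 5, 10, 15, 20} subset (see
#' [select_examples()]); main-task trials cycle through ranks so every block
#' uses distinct stimuli.
#'
#' @param seed integer seed for the random orders.
#' @return A `trial_schedule`: data.frame with columns `phase`
#'   (`example`/`practice`/`main`), `block` (0 outside the main task),
#'   `trial` (within phase), `stimulus_class` (`HUM`/`RAN`/`ISO`) and
#'   `stimulus_rank` (rank of the stimulus within its class set).
#' @export
make_trial_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  example_ranks <- c(1, 5, 10, 15, 20)
  ex <- data.frame(phase = "example", block = 0L,
                   stimulus_class = c("HUM", "HUM", "RAN", "RAN", "ISO"),
                   stimulus_rank = c(sample(example_ranks, 2),
                                     sample(example_ranks, 2), sample(10, 1)))
  pr_class <- sample(rep(c("HUM", "RAN", "ISO"), each = 3))
  pr_rank <- integer(9)
  pr_rank[pr_class == "HUM"] <- sample(example_ranks, 3)
  pr_rank[pr_class == "RAN"] <- sample(example_ranks, 3)
  pr_rank[pr_class == "ISO"] <- sample(10, 3)
  pr <- data.frame(phase = "practice", block = 0L,
                   stimulus_class = pr_class, stimulus_rank = pr_rank)
  hum_ranks <- sample(20)  # each HUM/RAN stimulus appears at most once
  ran_ranks <- sample(20)
  iso_ranks <- sample(rep(sample(10), 2), 6)
  main <- do.call(rbind, lapply(1:3, function(b) {
    cls <- sample(c(rep("HUM", 5), rep("RAN", 5), rep("ISO", 2)))
    rk <- integer(12)
    rk[cls == "HUM"] <- hum_ranks[(b - 1) * 5 + 1:5]
    rk[cls == "RAN"] <- ran_ranks[(b - 1) * 5 + 1:5]
    rk[cls == "ISO"] <- iso_ranks[(b - 1) * 2 + 1:2]
    data.frame(phase = "main", block = b, stimulus_class = cls,
               stimulus_rank = rk)
  }))
  out <- rbind(ex, pr, main)
  out$trial <- stats::ave(seq_len(nrow(out)), out$phase, FUN = seq_along)
  out <- out[, c("phase", "block", "trial", "stimulus_class", "stimulus_rank")]
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", "data.frame")
  out
}

.check_classes <- function(x) {
  bad <- setdiff(unique(x), c("HUM", "RAN", "ISO"))
  if (length(bad)) stop("unknown stimulus_class: ", paste(bad, collapse = ", "))
}

#' Screen participants on behavioral criteria
#'
#' Excludes a participant if, in the main task, they (a) ran out of time on
#' two or more trials (`timeout>=2`) or (b) judged the isochronous control
#' stimulus "human-like" two or more times (`iso_error>=2`). Screening is
#' idempotent and independent of row/participant order.
#'
#' @param table a response table: data.frame with at least `participant_id`,
#'   `phase`, `stimulus_class` and `response`
#'   (`"human-like"`/`"not-human-like"`/`"timeout"`).
#' @return List with `kept` (character vector of participant ids),
#'   `excluded` (data.frame `participant_id`, `reason`; both reasons listed
#'   when both apply, separated by `";"`).
#' @export
screen_participants <- function(table) {
  if (nrow(table) == 0)
    return(list(kept = character(0),
                excluded = data.frame(participant_id = character(0),
                                      reason = character(0))))
  .check_classes(table$stimulus_class)
  main <- table[table$phase == "main", ]
  ids <- unique(as.character(table$participant_id))
  reasons <- vapply(ids, function(id) {
    rows <- main[as.character(main$participant_id) == id, ]
    r <- character(0)
    if (sum(rows$response == "timeout") >= 2) r <- c(r, "timeout>=2")
    if (sum(rows$stimulus_class == "ISO" &
            rows$response == "human-like") >= 2) r <- c(r, "iso_error>=2")
    paste(r, collapse = ";")
  }, "")
  list(kept = ids[reasons == ""],
       excluded = data.frame(participant_id = ids[reasons != ""],
                             reason = unname(reasons[reasons != ""])))
}

#' Per-class "human-like" response rates
#'
#' For each stimulus class, the number of "human-like" responses divided by
#' the number of responses that did not run out of time (main task only).
#'
#' @param table response table (see [screen_participants()]).
#' @param participant participant id.
#' @return data.frame with `stimulus_class`, `n_valid`, `n_humanlike`,
#'   `rate` (`NA` with `undefined = TRUE` when every trial timed out).
#' @export
response_rates <- function(table, participant) {
  rows <- table[table$phase == "main" &
                  as.character(table$participant_id) == as.character(participant), ]
  if (nrow(rows) == 0) stop("participant not present: ", participant)
  .check_classes(rows$stimulus_class)
  out <- do.call(rbind, lapply(c("HUM", "RAN", "ISO"), function(cl) {
    r <- rows[rows$stimulus_class == cl, ]
    nv <- sum(r$response != "timeout")
    nh <- sum(r$response == "human-like")
    data.frame(stimulus_class = cl, n_valid = nv, n_humanlike = nh,
               rate = if (nv > 0) nh / nv else NA_real_,
               undefined = nv == 0)
  }))
  out
}

#' Signal-detection sensitivity and bias
#'
#' Equal-variance Gaussian d' and criterion C from a hit rate `h` (proportion
#' of "human-like" responses to HUM) and false-alarm rate `f` (same for RAN):
#' `d' = z(h) - z(f)` and `C = -(z(h) + z(f)) / 2`, `z` the standard-normal
#' quantile. Proportions of exactly 0 or 1 are adjusted by the 1/(2N) rule
#' before the quantile transform.
#'
#' Sign convention for C: positive C means a bias towards responding
#' "human-like" (the negative of the convention in which a positive criterion
#' is conservative).
#'
#' @param h,f hit and false-alarm rates in `[0, 1]`.
#' @param n_hum,n_ran numbers of valid HUM and RAN trials behind `h` and `f`.
#' @return An `sdt_result`: list with `h`, `f` (after adjustment), `d_prime`,
#'   `criterion`, `n_hum`, `n_ran`.
#' @export
#' @examples
#' compute_dprime_c(0.8413, 0.1587, 15, 15) # d' ~ 2, C ~ 0
compute_dprime_c <- function(h, f, n_hum, n_ran) {
  stopifnot(h >= 0, h <= 1, f >= 0, f <= 1)
  if (n_hum <= 0 || n_ran <= 0) stop("trial counts must be positive")
  clamp <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  h <- clamp(h, n_hum)
  f <- clamp(f, n_ran)
  zh <- qnorm(h)
  zf <- qnorm(f)
  structure(list(h = h, f = f, d_prime = zh - zf,
                 criterion = -(zh + zf) / 2,
                 n_hum = n_hum, n_ran = n_ran),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("sdt_result: H=%.3f F=%.3f  d'=%.3f  C=%.3f  (n=%d/%d)\n",
              x$h, x$f, x$d_prime, x$criterion, x$n_hum, x$n_ran))
  invisible(x)
}

#' Score every participant of a response table
#'
#' Applies [screen_participants()] and [compute_dprime_c()] (HUM vs RAN,
#' main task, timeouts excluded; ISO trials never enter d'/C).
#'
#' @param table response table.
#' @return data.frame with one row per participant: `participant_id`, `h`,
#'   `f`, `d_prime`, `criterion`, `n_hum`, `n_ran`, `excluded`, `reason`.
#' @export
sdt_summary <- function(table) {
  scr <- screen_participants(table)
  ids <- unique(as.character(table$participant_id))
  do.call(rbind, lapply(ids, function(id) {
    rr <- response_rates(table, id)
    hum <- rr[rr$stimulus_class == "HUM", ]
    ran <- rr[rr$stimulus_class == "RAN", ]
    if (hum$n_valid == 0 || ran$n_valid == 0) {
      res <- list(h = NA_real_, f = NA_real_, d_prime = NA_real_,
                  criterion = NA_real_, n_hum = hum$n_valid,
                  n_ran = ran$n_valid)
    } else {
      res <- compute_dprime_c(hum$rate, ran$rate, hum$n_valid, ran$n_valid)
    }
    excl <- id %in% scr$excluded$participant_id
    data.frame(participant_id = id, h = res$h, f = res$f,
               d_prime = res$d_prime, criterion = res$criterion,
               n_hum = res$n_hum, n_ran = res$n_ran, excluded = excl,
               reason = if (excl)
                 scr$excluded$reason[scr$excluded$participant_id == id]
               else "")
  }))
}

#' Simulate a synthetic listener
#'
#' Equal-variance Gaussian observer: on each trial the evidence is drawn
#' from N(d'/2, 1) for HUM stimuli and N(-d'/2, 1) for RAN and ISO stimuli,
#' and the listener responds "human-like" iff the evidence exceeds the
#' criterion (so the generating `criterion` equals the C recovered by
#' [compute_dprime_c()] under this package's sign convention). Timeouts
#' occur independently with probability `timeout_rate`.
#'
#' @param d_prime_true generating sensitivity.
#' @param criterion_true generating criterion (evidence units).
#' @param schedule a [make_trial_schedule()] (or any data.frame with `phase`,
#'   `block`, `trial`, `stimulus_class`, `stimulus_rank`).
#' @param seed RNG seed.
#' @param participant_id id written into the table.
#' @param timeout_rate per-trial timeout probability (default 0).
#' @param iso_d_prime evidence offset separating ISO from HUM; defaults to
#'   `max(d_prime_true, 4)` so the near-isochronous control is easy to
#'   reject, as designed.
#' @return A response table (data.frame) with columns `participant_id`,
#'   `phase`, `block`, `trial`, `stimulus_class`, `stimulus_rank`,
#'   `response`, `rt_ms`.
#' @export
simulate_listener <- function(d_prime_true, criterion_true, schedule,
                              seed = NULL, participant_id = "synthetic-01",
                              timeout_rate = 0,
                              iso_d_prime = max(d_prime_true, 4)) {
  stopifnot(is.finite(d_prime_true), is.finite(criterion_true))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  mu <- ifelse(schedule$stimulus_class == "HUM", d_prime_true / 2,
               ifelse(schedule$stimulus_class == "RAN", -d_prime_true / 2,
                      -iso_d_prime / 2))
  evidence <- rnorm(n, mean = mu)
  resp <- ifelse(evidence > criterion_true, "human-like", "not-human-like")
  to <- stats::runif(n) < timeout_rate
  resp[to] <- "timeout"
  rt <- round(stats::runif(n, 600, 2400))
  rt[to] <- NA_integer_
  data.frame(participant_id = participant_id, phase = schedule$phase,
             block = schedule$block, trial = schedule$trial,
             stimulus_class = schedule$stimulus_class,
             stimulus_rank = schedule$stimulus_rank,
             response = resp, rt_ms = rt)
}
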