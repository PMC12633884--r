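# ITI / asynchrony series and windowed detrended cross-correlation (WDCC).
# Tap times are stored in seconds; every statistic here is reported in ms.

#' Inter-tap intervals of one player
#'
#' First-order differences of a player's tap times, in ms.
#'
#' @param timeline a [pair_timeline()].
#' @param player 1 or 2.
#' @return Numeric vector of length `n_taps - 1` (ms).
#' @export
#' @examples
#' tl <- pair_timeline(c(0, 0.48, 1.0), c(0, 0.5, 1.0))
#' compute_iti(tl, 1) # 480 520
compute_iti <- function(timeline, player = 1) {
  stopifnot(inherits(timeline, "pair_timeline"), player %in% c(1, 2))
  taps <- if (player == 1) timeline$taps_p1 else timeline$taps_p2
  if (length(taps) < 2) stop("need at least 2 taps")
  d <- diff(taps) * 1000
  if (any(d <= 0)) stop("non-monotone tap times")
  d
}

#' Tap-to-tap asynchrony series
#'
#' Signed timing difference a_n = t_n(1) - t_n(2) between paired taps,
#' player 1 minus player 2, in ms. Swapping the players flips the sign.
#'
#' @param timeline a [pair_timeline()].
#' @return Numeric vector of length `n_taps` (ms).
#' @export
compute_asynchrony <- function(timeline) {
  stopifnot(inherits(timeline, "pair_timeline"))
  (timeline$taps_p1 - timeline$taps_p2) * 1000
}

#' Mean tap timing of the pair
#'
#' m_n = 0.5 * (t_n(1) + t_n(2)), in ms. Together with the halved
#' asynchronies it reconstructs both timelines exactly:
#' t(1) = m + a/2, t(2) = m - a/2.
#'
#' @param timeline a [pair_timeline()].
#' @return Numeric vector of length `n_taps` (ms).
#' @export
mean_timing <- function(timeline) {
  stopifnot(inherits(timeline, "pair_timeline"))
  (timeline$taps_p1 + timeline$taps_p2) * 500
}

# Residual maker of the within-window linear detrend: projects a length-w
# segment onto the orthogonal complement of (1, 1:w). Cached per window size.
.detrend_mat <- local({
  cache <- list()
  function(w) {
    key <- as.character(w)
    if (is.null(cache[[key]])) {
      X <- cbind(1, seq_len(w))
      cache[[key]] <<- diag(w) - X %*% solve(crossprod(X), t(X))
    }
    cache[[key]]
  }
})

# All length-w windows of x at the given start indices, detrended:
# rows = windows. Returns the matrix and the residual L2 norms.
.detrended_windows <- function(x, starts, w) {
  seg <- matrix(x[outer(starts, 0:(w - 1), `+`)], nrow = length(starts))
  D <- seg %*% .detrend_mat(w)
  list(D = D, norm = sqrt(rowSums(D * D)))
}

#' Windowed detrended cross-correlation (WDCC)
#'
#' For each lag `l` in `-max_lag..max_lag`, slides a window of
#' `window_len` intervals along `x` (step `window_step`), pairs it with the
#' equally long window of `y` starting `l` intervals later, removes a
#' least-squares linear trend from each segment, and averages the Pearson
#' correlation of the residuals across windows.
#'
#' Lag-sign convention: at positive lag `l` the `y` window starts `l`
#' positions after the `x` window, i.e. positive lags mean `y` lags `x`.
#' `wdcc(x, y)` at lag `l` equals `wdcc(y, x)` at lag `-l`.
#'
#' Windows in which either detrended segment has (numerically) zero variance
#' are dropped from the average; `n_windows` records how many windows
#' contributed at each lag. If every window at some lag is dropped the
#' coefficient is undefined and an error is raised.
#'
#' @param x,y equal-length numeric series (typically the two players' ITI
#'   series, in ms).
#' @param max_lag largest lag, in intervals (default 10).
#' @param window_len window length, in intervals (default 15).
#' @param window_step distance between successive window starts (default 1,
#'   fully sliding).
#' @return A `wdcc_profile`: data.frame with columns `lag`, `coefficient`,
#'   `n_windows`, plus attributes `window_len` and `window_step`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(35); wdcc(x, x)$coefficient[11] # lag 0 -> 1
wdcc <- function(x, y, max_lag = 10, window_len = 15, window_step = 1) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (window_len + max_lag > n)
    stop("window_len + max_lag must not exceed the series length")
  if (window_len < 3) stop("window_len must be at least 3")
  w <- as.integer(window_len)
  lags <- seq.int(-max_lag, max_lag)
  all_starts <- seq.int(1L, n - w + 1L) # y windows are indexed from here
  x_starts <- seq.int(1L, n - w + 1L, by = window_step)
  dx <- .detrended_windows(x, x_starts, w)
  dy <- .detrended_windows(y, all_starts, w)
  eps <- 1e-12 * max(1, max(abs(x)), max(abs(y))) * sqrt(w)

  coef <- numeric(length(lags))
  nwin <- integer(length(lags))
  for (il in seq_along(lags)) {
    l <- lags[il]
    ys <- x_starts + l
    keep <- ys >= 1L & ys <= n - w + 1L
    xi <- which(keep)
    yi <- ys[keep]
    r <- rowSums(dx$D[xi, , drop = FALSE] * dy$D[yi, , drop = FALSE]) /
      (dx$norm[xi] * dy$norm[yi])
    ok <- dx$norm[xi] > eps & dy$norm[yi] > eps
    if (!any(ok))
      stop("WDCC coefficient undefined at lag ", l,
           ": all windows have zero detrended variance")
    coef[il] <- mean(r[ok])
    nwin[il] <- sum(ok)
  }
  structure(data.frame(lag = lags, coefficient = coef, n_windows = nwin),
            window_len = w, window_step = as.integer(window_step),
            class = c("wdcc_profile", "data.frame"))
}

#' Plot a WDCC lag profile
#'
#' @param x a `wdcc_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wdcc_profile <- function(x, ...) {
  graphics::plot(x$lag, x$coefficient, type = "b", pch = 16,
                 xlab = "lag (intervals)", ylab = "WDCC coefficient", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Per-stimulus timing summary
#'
#' Mean and SD of each player's ITI series and of the player-1 asynchrony
#' series, in ms.
#'
#' @param timeline a [pair_timeline()].
#' @return One-row data.frame: `mean_iti_p1`, `sd_iti_p1`, `mean_iti_p2`,
#'   `sd_iti_p2`, `mean_async`, `sd_async`.
#' @export
summarize_timeline <- function(timeline) {
  i1 <- compute_iti(timeline, 1)
  i2 <- compute_iti(timeline, 2)
  a <- compute_asynchrony(timeline)
  data.frame(mean_iti_p1 = mean(i1), sd_iti_p1 = sd(i1),
             mean_iti_p2 = mean(i2), sd_iti_p2 = sd(i2),
             mean_async = mean(a), sd_async = sd(a))
}

#' Group summary of a stimulus set
#'
#' Per-stimulus timing summaries and their group mean +/- SD across the set,
#' the form in which stimulus-class descriptive statistics are reported.
#'
#' @param set a `stimulus_set` (see [generate_hum_set()]).
#' @return List with `per_stimulus` (one row per stimulus) and `group`
#'   (two rows: mean and SD across stimuli).
#' @export
summarize_set <- function(set) {
  stopifnot(inherits(set, "stimulus_set"), length(set$stimuli) > 0)
  per <- do.call(rbind, lapply(set$stimuli, function(s) summarize_timeline(s$timeline)))
  per <- cbind(data.frame(stimulus = vapply(set$stimuli, function(s) s$id, "")), per)
  num <- per[, -1, drop = FALSE]
  group <- rbind(mean = colMeans(num), sd = apply(num, 2, sd))
  list(per_stimulus = per, group = as.data.frame(group))
}
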