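# Coupled phase-oscillator model of paired synchronized tapping.
#
# Each player i is a phase oscillator
#   d theta_i / dt = omega_i + sigma_i * xi_i(t),   d omega_i / dt = 0,
# with xi_i zero-mean unit-intensity Gaussian white noise. When player i's
# phase reaches 2*pi the player taps, theta_i is reset to 0, and the partner
# j receives discrete corrections
#   theta_j <- theta_j + a_j * Z_j(theta_j)                      (phase)
#   omega_j <- omega_j + b_j * Y_j(theta_j) - k_j * (omega_j - omega_j(0))
# where Z_j, Y_j are response functions, a_j and b_j the phase- and
# period-correction gains, and k_j a tempo rebound pulling omega back to its
# initial value.

#' Built-in response functions
#'
#' Response functions modulate the partner reset: `Z` scales the phase jump
#' and `Y` the angular-velocity change, both evaluated at the corrected
#' player's current phase. Built-ins are referenced by name:
#'
#' * `"neg_sin"`: Z(theta) = -sin(theta). The default. Has the fixed point
#'   Z(0) = Z(2*pi) = 0, so perfectly synchronous partners receive no
#'   correction; a player whose phase lags just below 2*pi when the partner
#'   taps is advanced, and one just past its own tap is retarded.
#' * `"zero"`: Z(theta) = 0, the uncoupled limit.
#'
#' Any R function of the phase (in radians) can be supplied instead.
#'
#' @name response-functions
#' @keywords internal
NULL

.resp_id <- function(f) {
  if (is.character(f)) {
    switch(match.arg(f, c("neg_sin", "zero")), neg_sin = 1L, zero = 2L)
  } else if (is.function(f)) 0L
  else stop("response function must be \"neg_sin\", \"zero\" or an R function")
}

.resp_fun <- function(f) if (is.function(f)) f else switch(f,
  neg_sin = function(theta) -sin(theta),
  zero    = function(theta) 0
)

#' Per-player model parameters
#'
#' @param a phase-correction gain (dimensionless).
#' @param b period-correction gain (dimensionless).
#' @param k tempo-rebound gain; defaults to `0.3 * b`.
#' @param sigma phase-noise strength (rad s^-1/2); `0.3` for humanized
#'   stimuli, `0.01` for isochronous ones.
#' @param omega0 initial angular velocity (rad/s); the default `2*pi / 0.5`
#'   corresponds to a 500 ms interbeat interval.
#' @param phase_response,period_response response function `Z` / `Y`: a
#'   built-in name (see [response-functions]) or a function of phase.
#'
#' @return An object of class `player_params`.
#' @export
#' @examples
#' player_params(b = 1.5)
player_params <- function(a = 0.3, b = 1.0, k = 0.3 * b, sigma = 0.3,
                          omega0 = 2 * pi / 0.5,
                          phase_response = "neg_sin",
                          period_response = "neg_sin") {
  stopifnot(sigma >= 0, omega0 > 0, a >= 0, k >= 0)
  structure(list(a = a, b = b, k = k, sigma = sigma, omega0 = omega0,
                 phase_response = phase_response,
                 period_response = period_response),
            class = "player_params")
}

#' @export
print.player_params <- function(x, ...) {
  cat(sprintf("player_params: a=%g b=%g k=%g sigma=%g omega0=%g rad/s (period %g ms)\n",
              x$a, x$b, x$k, x$sigma, x$omega0, 2 * pi / x$omega0 * 1000))
  invisible(x)
}

#' Simulation configuration for a tapping pair
#'
#' @param params_p1,params_p2 [player_params()] for each player; player 2
#'   defaults to a copy of player 1.
#' @param n_taps taps recorded per player (the simultaneous start at t = 0
#'   counts as tap 1 when `t0_is_tap = TRUE`, so a timeline has
#'   `n_taps - 1` inter-tap intervals).
#' @param dt Euler--Maruyama step (s). Must be far below the oscillation
#'   period; default 1 ms.
#' @param seed integer seed for the run, or `NULL` to use the current RNG
#'   state.
#' @param t0_is_tap whether the shared start event is recorded as tap 1.
#' @param tie_first which player's tap is processed first if both phases
#'   cross 2*pi at the same instant within a step (1 or 2).
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(params_p1 = player_params(b = 0.5), n_taps = 12, seed = 1)
sim_config <- function(params_p1 = player_params(), params_p2 = params_p1,
                       n_taps = 36L, dt = 1e-3, seed = NULL,
                       t0_is_tap = TRUE, tie_first = 1L) {
  stopifnot(inherits(params_p1, "player_params"),
            inherits(params_p2, "player_params"),
            n_taps >= 2, dt > 0, tie_first %in% c(1L, 2L))
  if (dt >= 0.1 * 2 * pi / max(params_p1$omega0, params_p2$omega0))
    stop("dt must be well below the oscillation period 2*pi/omega0")
  structure(list(params_p1 = params_p1, params_p2 = params_p2,
                 n_taps = as.integer(n_taps), dt = dt, seed = seed,
                 t0_is_tap = isTRUE(t0_is_tap),
                 tie_first = as.integer(tie_first)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n_taps=%d dt=%g s seed=%s t0_is_tap=%s\n",
              x$n_taps, x$dt,
              if (is.null(x$seed)) "<current RNG>" else format(x$seed),
              x$t0_is_tap))
  print(x$params_p1); print(x$params_p2)
  invisible(x)
}

#' Single Euler--Maruyama phase step
#'
#' Advances one oscillator state over `dt` with a supplied standard-normal
#' noise draw: `theta' = theta + omega * dt + sigma * sqrt(dt) * noise_draw`.
#' The angular velocity is unchanged between taps. Exposed mainly for
#' testing and didactic use; [simulate_pair()] integrates in compiled code.
#'
#' @param state list with elements `theta` (rad) and `omega` (rad/s).
#' @param params [player_params()] supplying `sigma`.
#' @param dt step length (s), >= 0.
#' @param noise_draw a standard-normal deviate.
#' @return The advanced state (phase not wrapped).
#' @export
#' @examples
#' step_phase(osc_state(0, 4 * pi), player_params(sigma = 0), dt = 0.5,
#'            noise_draw = 0)$theta # one full period
step_phase <- function(state, params, dt, noise_draw) {
  stopifnot(dt >= 0)
  if (!is.finite(noise_draw)) stop("non-finite noise draw")
  state$theta <- state$theta + state$omega * dt +
    params$sigma * sqrt(dt) * noise_draw
  state
}

#' Oscillator state
#'
#' @param theta phase (rad), in `[0, 2*pi)`.
#' @param omega angular velocity (rad/s), > 0.
#' @return A list with class `osc_state`.
#' @export
osc_state <- function(theta, omega) {
  stopifnot(theta >= 0, theta < 2 * pi, omega > 0)
  structure(list(theta = theta, omega = omega), class = "osc_state")
}

#' Partner reset at a tap event
#'
#' Applies the discrete correction received by player j at the instant the
#' other player taps: a phase jump `a * Z(theta)` and an angular-velocity
#' update `b * Y(theta) - k * (omega - omega0)`. If the phase jump carries
#' the phase across 2*pi it wraps, and the wrap counts as a tap of j (the
#' returned state carries `tapped = TRUE`).
#'
#' @param state the corrected player's state ([osc_state()]).
#' @param params the corrected player's [player_params()].
#' @return The updated state, with attribute-like element `tapped`.
#' @export
#' @examples
#' apply_partner_reset(osc_state(0, 4 * pi), player_params()) # fixed point
apply_partner_reset <- function(state, params) {
  z <- .resp_fun(params$phase_response)(state$theta)
  y <- .resp_fun(params$period_response)(state$theta)
  state$theta <- state$theta + params$a * z
  state$omega <- state$omega + params$b * y -
    params$k * (state$omega - params$omega0)
  if (state$omega <= 0)
    stop("degenerate run: partner reset drove angular velocity to ",
         format(state$omega), " <= 0")
  state$tapped <- FALSE
  if (state$theta >= 2 * pi) {
    state$theta <- state$theta - 2 * pi
    state$tapped <- TRUE
  }
  state
}

#' Simulate one tapping pair
#'
#' Integrates the coupled two-oscillator model with fixed-step
#' Euler--Maruyama (phase noise only) and event-driven tap handling: a 2*pi
#' crossing inside a step is located by linear interpolation, the tapper's
#' phase is set to exactly 0 at that instant, the partner reset is applied,
#' and the remainder of the step is integrated. Both players start at
#' `theta = 0`, `omega = omega0`; by default t = 0 is recorded as tap 1 of
#' both players.
#'
#' @param config a [sim_config()].
#' @return A `pair_timeline`: list with `taps_p1`, `taps_p2` (tap times in
#'   seconds, strictly increasing, length `n_taps` each), `seed`, and the
#'   generating `config`.
#' @export
#' @examples
#' tl <- simulate_pair(sim_config(n_taps = 12, seed = 1))
#' diff(tl$taps_p1) * 1000 # inter-tap intervals, ms
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- list(config$params_p1, config$params_p2)
  if (!is.null(config$seed)) set.seed(config$seed)
  # generous cap: 4x the nominal duration of the sequence
  max_time <- 4 * config$n_taps * 2 * pi / min(p[[1]]$omega0, p[[2]]$omega0)
  res <- simulate_pair_cpp(
    n_taps = config$n_taps, dt = config$dt,
    a = c(p[[1]]$a, p[[2]]$a), b = c(p[[1]]$b, p[[2]]$b),
    k = c(p[[1]]$k, p[[2]]$k), sigma = c(p[[1]]$sigma, p[[2]]$sigma),
    omega0 = c(p[[1]]$omega0, p[[2]]$omega0),
    z_id = c(.resp_id(p[[1]]$phase_response), .resp_id(p[[2]]$phase_response)),
    y_id = c(.resp_id(p[[1]]$period_response), .resp_id(p[[2]]$period_response)),
    z1 = .resp_fun(p[[1]]$phase_response), y1 = .resp_fun(p[[1]]$period_response),
    z2 = .resp_fun(p[[2]]$phase_response), y2 = .resp_fun(p[[2]]$period_response),
    t0_is_tap = config$t0_is_tap, tie_first = config$tie_first,
    max_time = max_time)
  # Tap times are quantized to a dyadic grid of 2^-20 s (~0.95 us), far below
  # the interpolation accuracy of the event scheme and audio sample spacing.
  # On this grid the m +/- a/2 reconstruction used by the asynchrony-shuffling
  # surrogate is exact in double precision, so shuffled surrogates conserve
  # the asynchrony multiset and mean-timing series bit-exactly.
  pair_timeline(round(res$taps_p1 * 2^20) / 2^20,
                round(res$taps_p2 * 2^20) / 2^20,
                seed = config$seed, config = config)
}

#' Construct a pair timeline
#'
#' @param taps_p1,taps_p2 tap times in seconds, strictly increasing, equal
#'   length.
#' @param seed seed that produced the timeline (or `NULL`).
#' @param config generating [sim_config()] (or `NULL` for hand-built data).
#' @return An object of class `pair_timeline`.
#' @export
pair_timeline <- function(taps_p1, taps_p2, seed = NULL, config = NULL) {
  if (length(taps_p1) != length(taps_p2))
    stop("players must have equal tap counts (got ", length(taps_p1),
         " and ", length(taps_p2), ")")
  if (is.unsorted(taps_p1, strictly = TRUE) ||
      is.unsorted(taps_p2, strictly = TRUE))
    stop("tap times must be strictly increasing within each player")
  structure(list(taps_p1 = as.numeric(taps_p1),
                 taps_p2 = as.numeric(taps_p2),
                 seed = seed, config = config),
            class = "pair_timeline")
}

#' @export
print.pair_timeline <- function(x, ...) {
  n <- length(x$taps_p1)
  cat(sprintf("pair_timeline: %d taps/player over %.3f s%s\n", n,
              max(x$taps_p1[n], x$taps_p2[n]),
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  invisible(x)
}
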