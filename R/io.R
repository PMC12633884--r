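# Plain-text export of timelines, WDCC profiles and stimulus sets.

#' Write / read a pair timeline as CSV
#'
#' Long format: columns `player` (1|2), `tap_index` (1-based), `time_ms`.
#'
#' @param timeline a [pair_timeline()].
#' @param path output CSV path.
#' @return `path` invisibly; `read_timeline_csv()` returns a
#'   `pair_timeline`.
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "pair_timeline"))
  n <- length(timeline$taps_p1)
  df <- data.frame(player = rep(1:2, each = n), tap_index = rep(seq_len(n), 2),
                   time_ms = c(timeline$taps_p1, timeline$taps_p2) * 1000)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeline_csv
#' @export
read_timeline_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("player", "tap_index", "time_ms") %in% names(df)))
  df <- df[order(df$player, df$tap_index), ]
  pair_timeline(df$time_ms[df$player == 1] / 1000,
                df$time_ms[df$player == 2] / 1000)
}

#' Write a WDCC profile as CSV
#'
#' Columns `lag`, `coefficient`, `n_windows`.
#'
#' @param profile a `wdcc_profile` (see [wdcc()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wdcc_csv <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("lag", "coefficient", "n_windows")],
            path, row.names = FALSE)
  invisible(path)
}

#' Export a stimulus set to a directory
#'
#' Writes one timeline CSV and one WDCC-profile CSV per stimulus plus a
#' `manifest.json` recording the label, b level, seeds, WDCC settings,
#' per-stimulus ids/ranks/distances and the generating configuration.
#'
#' @param set a `stimulus_set`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in set$stimuli) {
    write_timeline_csv(s$timeline, file.path(dir, paste0(s$id, "_timeline.csv")))
    write_wdcc_csv(s$profile, file.path(dir, paste0(s$id, "_wdcc.csv")))
  }
  cfg <- set$config
  manifest <- list(
    label = set$label, b_level = set$b_level, reps = set$reps,
    base_seed = set$base_seed, wdcc = set$wdcc_args,
    config = if (is.null(cfg)) NULL else list(
      n_taps = cfg$n_taps, dt = cfg$dt, t0_is_tap = cfg$t0_is_tap,
      params_p1 = cfg$params_p1[c("a", "b", "k", "sigma", "omega0")],
      params_p2 = cfg$params_p2[c("a", "b", "k", "sigma", "omega0")]),
    stimuli = lapply(set$stimuli, function(s)
      list(id = s$id, rank = s$rank, distance = s$distance, seed = s$seed,
           source_id = s$source_id)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
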