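#' Cleaning rule parameters
#'
#' The two exclusion rules applied to raw tracks: fixes implying a travel
#' speed above `speed_threshold` are removed (community dogs cannot sustain
#' such speeds over a full logging interval, so these are positioning
#' errors), and dogs with less than `min_recording` hours between first and
#' last fix are excluded from the cohort.
#'
#' @param speed_threshold km/h; default 20.
#' @param min_recording hours; default 24.
#' @return a `cleaning_params` list.
#' @export
cleaning_params <- function(speed_threshold = 20, min_recording = 24) {
  stopifnot(speed_threshold > 0, min_recording > 0)
  structure(list(speed_threshold = speed_threshold,
                 min_recording = min_recording),
            class = "cleaning_params")
}

#' Per-step travel speeds of a track
#'
#' Average speed between every two consecutive fixes: planar distance over
#' elapsed time, in km/h. Steps with zero elapsed time are flagged invalid
#' (`NA` speed) rather than reported as infinite.
#'
#' @param track a projected [sampled_track] with at least 2 fixes.
#' @return data.frame with one row per step: `from`, `to` (fix indices),
#'   `distance_m`, `duration_s`, `speed_kmh` (`NA` where `duration_s == 0`).
#' @export
compute_speeds <- function(track) {
  if (n_fixes(track) < 2) stop("need at least 2 fixes to compute speeds")
  st <- .track_steps(track)
  speed <- ifelse(st$duration_s > 0,
                  (st$length_m / 1000) / (st$duration_s / 3600),
                  NA_real_)
  data.frame(from = seq_len(nrow(st)), to = seq_len(nrow(st)) + 1L,
             distance_m = st$length_m, duration_s = st$duration_s,
             speed_kmh = speed)
}

#' Remove fixes implying implausible speeds
#'
#' Iteratively removes the later fix of the first step whose speed exceeds
#' the threshold, then recomputes speeds, until no step exceeds it. Treating
#' the later fix as the erroneous one is deterministic and removes a single
#' spurious jump with a single deletion. The procedure terminates because
#' every pass removes one fix.
#'
#' @param track a projected [sampled_track].
#' @param params a [cleaning_params].
#' @return list with `track` (filtered) and `n_removed`.
#' @export
filter_by_speed <- function(track, params = cleaning_params()) {
  n_removed <- 0L
  if (n_fixes(track) < 2) {
    return(list(track = track, n_removed = 0L))
  }
  repeat {
    if (n_fixes(track) < 2) {
      warning("speed filter reduced track ", track$dog_id,
              " below 2 fixes; keeping as-is")
      break
    }
    sp <- compute_speeds(track)
    bad <- which(!is.na(sp$speed_kmh) & sp$speed_kmh > params$speed_threshold)
    if (length(bad) == 0) break
    drop_row <- sp$to[bad[1]]
    track$fixes <- track$fixes[-drop_row, , drop = FALSE]
    rownames(track$fixes) <- NULL
    n_removed <- n_removed + 1L
  }
  list(track = track, n_removed = n_removed)
}

#' Exclude dogs with short recording periods
#'
#' Dogs whose elapsed recording span (first to last fix) is strictly less
#' than `min_recording` hours are listed as excluded; all others are kept
#' unchanged. A span of exactly the threshold is kept.
#'
#' @param tracks list of [sampled_track]s.
#' @param params a [cleaning_params].
#' @return list with `kept` (list of tracks) and `excluded_ids` (character).
#' @export
exclude_short_recordings <- function(tracks, params = cleaning_params()) {
  hours <- vapply(tracks, recording_hours, 0)
  short <- hours < params$min_recording
  list(kept = tracks[!short],
       excluded_ids = vapply(tracks[short], function(t) t$dog_id, ""))
}

#' Sampling summary of a cleaned track
#'
#' @param track a cleaned [sampled_track].
#' @param n_fixes_raw fix count before cleaning (defaults to the current
#'   count if the raw track is not available).
#' @return a `sampling_summary`: `recording_hours` (span between first and
#'   last fix), `fixes_per_hour` (post-cleaning fixes over that span; `NA`
#'   and flagged for a single-fix track), `n_fixes_raw`, `n_fixes_clean`.
#' @export
summarize_sampling <- function(track, n_fixes_raw = n_fixes(track)) {
  n <- n_fixes(track)
  hours <- recording_hours(track)
  structure(list(
    dog_id = track$dog_id,
    recording_hours = hours,
    fixes_per_hour = if (hours > 0) n / hours else NA_real_,
    n_fixes_raw = n_fixes_raw,
    n_fixes_clean = n,
    degenerate = hours <= 0
  ), class = "sampling_summary")
}

#' Clean one raw track end to end
#'
#' Convenience wrapper: speed-filters a projected track and attaches its
#' [summarize_sampling()] record.
#'
#' @param track projected [sampled_track].
#' @param params a [cleaning_params].
#' @return list with `track`, `n_removed`, `sampling`.
#' @export
clean_track <- function(track, params = cleaning_params()) {
  raw_n <- n_fixes(track)
  flt <- filter_by_speed(track, params)
  list(track = flt$track, n_removed = flt$n_removed,
       sampling = summarize_sampling(flt$track, n_fixes_raw = raw_n))
}
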