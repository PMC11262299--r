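#' Swimming speed of one lane segment
#'
#' Trials are filmed from above at a fixed frame rate over a lane marked
#' at fixed intervals; the analyst records how many frames the snake took
#' to cross each segment. Speed is segment length over elapsed time.
#'
#' @param frames Integer frame count for the segment (> 0).
#' @param frame_rate Camera frame rate in frames/s (default 60).
#' @param segment_length Segment length in cm (default 30).
#' @return Speed in cm/s.
#' @examples
#' segment_speed(60)   # one second per 30 cm -> 30 cm/s
#' @export
segment_speed <- function(frames, frame_rate = 60, segment_length = 30) {
  stopifnot(frame_rate > 0, segment_length > 0)
  if (any(frames != round(frames)))
    stop("segment_speed(): frame counts must be whole numbers")
  if (any(frames <= 0))
    stop("segment_speed(): frame counts must be positive")
  segment_length / (frames / frame_rate)
}

#' Construct a swim trial record
#'
#' @param individual_id Identifier of the animal.
#' @param treatment_temp Trial water temperature (deg C).
#' @param segment_frames Integer vector of per-segment frame counts.
#' @param frame_rate Frames/s (default 60).
#' @param segment_length Segment length in cm (default 30).
#' @param duration_cap Maximum trial duration in s (default 120).
#' @param species,sex,body_mass Optional covariates carried through.
#' @return A `swim_trial` object.
#' @export
swim_trial <- function(individual_id, treatment_temp, segment_frames,
                       frame_rate = 60, segment_length = 30,
                       duration_cap = 120, species = NA_character_,
                       sex = NA_character_, body_mass = NA_real_) {
  stopifnot(length(segment_frames) >= 1, frame_rate > 0,
            segment_length > 0)
  if (any(segment_frames != round(segment_frames)) ||
      any(segment_frames <= 0))
    stop("swim_trial(): segment_frames must be positive whole numbers")
  total_s <- sum(segment_frames) / frame_rate
  if (total_s > duration_cap)
    stop("swim_trial(): implied trial time (", round(total_s, 1),
         " s) exceeds the duration cap of ", duration_cap, " s")
  structure(list(individual_id = individual_id, species = species,
                 sex = sex, body_mass = body_mass,
                 treatment_temp = treatment_temp,
                 segment_frames = as.integer(segment_frames),
                 frame_rate = frame_rate,
                 segment_length = segment_length,
                 duration_cap = duration_cap),
            class = "swim_trial")
}

#' Maximum swimming speed of a trial
#'
#' Converts every segment's frame count to a speed and takes the highest
#' as the trial's maximum swimming speed at that temperature. Trials that
#' cover fewer than `min_segments` marks warn (the protocol targets at
#' least five 30 cm segments) but are not excluded.
#'
#' @param trial A [swim_trial()].
#' @param min_segments Segment count below which a warning is issued.
#' @return One-row data frame (a `SpeedObservation`): `individual_id`,
#'   `species`, `sex`, `body_mass_g`, `treatment_c`, `max_speed_cm_s`.
#' @export
trial_max_speed <- function(trial, min_segments = 5) {
  stopifnot(inherits(trial, "swim_trial"))
  if (length(trial$segment_frames) < min_segments)
    warning("trial_max_speed(): only ", length(trial$segment_frames),
            " segment(s); protocol targets >= ", min_segments)
  speeds <- segment_speed(trial$segment_frames, trial$frame_rate,
                          trial$segment_length)
  data.frame(individual_id = trial$individual_id,
             species = trial$species, sex = trial$sex,
             body_mass_g = trial$body_mass,
             treatment_c = trial$treatment_temp,
             max_speed_cm_s = max(speeds),
             stringsAsFactors = FALSE)
}

#' Reduce a table of swim trials to speed observations
#'
#' Accepts either the long dialect (one row per segment, with a
#' `segment_index` and `frames` column) or the wide dialect (one row per
#' trial with `seg1`, `seg2`, ... frame-count columns).
#'
#' @param trials Data frame with columns `individual_id`, `species`,
#'   `treatment_c`, optionally `sex`, `body_mass_g`, `frame_rate`,
#'   `segment_length_cm`, and frame counts in one of the two dialects.
#' @return Data frame of speed observations, one row per trial.
#' @export
speeds_from_trials <- function(trials) {
  need <- c("individual_id", "species", "treatment_c")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("speeds_from_trials(): missing columns: ",
         paste(miss, collapse = ", "))
  long <- all(c("segment_index", "frames") %in% names(trials))
  segcols <- grep("^seg[0-9]+$", names(trials), value = TRUE)
  if (!long && !length(segcols))
    stop("speeds_from_trials(): need either long columns ",
         "(segment_index, frames) or wide columns seg1, seg2, ...")
  col_or <- function(d, nm, default) if (nm %in% names(d)) d[[nm]] else default
  key <- interaction(trials$individual_id, trials$treatment_c, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    frames <- if (long) d$frames[order(d$segment_index)] else
      stats::na.omit(as.numeric(unlist(d[1, segcols, drop = FALSE])))
    tr <- swim_trial(
      individual_id = d$individual_id[1],
      treatment_temp = d$treatment_c[1],
      segment_frames = frames,
      frame_rate = col_or(d, "frame_rate", 60)[1],
      segment_length = col_or(d, "segment_length_cm", 30)[1],
      species = d$species[1],
      sex = as.character(col_or(d, "sex", NA_character_)[1]),
      body_mass = col_or(d, "body_mass_g", NA_real_)[1])
    trial_max_speed(tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
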