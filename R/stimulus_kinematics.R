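#' Pin-array geometry
#'
#' Geometry and timing of the lateral pin-array display used to render tactile
#' apparent motion. Rows of pins are oscillated in sequence so that a single
#' virtual ridge sweeps across the fingertip; the spatial period of the ridge
#' pattern is the first-to-last row distance plus the wrap gap.
#'
#' @param n_rows number of pin rows (>= 2).
#' @param row_pitch distance between adjacent rows, mm.
#' @param wrap_gap extra distance between the last and (wrapped) first row, mm.
#' @param refresh_period display refresh period, s.
#' @param osc_freq within-row oscillation frequency, Hz (metadata only).
#' @param osc_amplitude pin oscillation amplitude, mm (metadata; mapped to
#'   tactile noise by the synthetic-experiment generator).
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(n_rows = 8, row_pitch = 1.6, wrap_gap = 1.6,
                           refresh_period = 0.0015, osc_freq = 20,
                           osc_amplitude = 0.1) {
  if (n_rows < 2 || n_rows != round(n_rows)) stop("n_rows must be an integer >= 2")
  if (row_pitch <= 0 || wrap_gap <= 0) stop("row_pitch and wrap_gap must be > 0")
  if (refresh_period <= 0) stop("refresh_period must be > 0")
  if (osc_amplitude <= 0) stop("osc_amplitude must be > 0")
  structure(list(n_rows = as.integer(n_rows), row_pitch = row_pitch,
                 wrap_gap = wrap_gap, refresh_period = refresh_period,
                 osc_freq = osc_freq, osc_amplitude = osc_amplitude),
            class = "array_geometry")
}

#' Spatial period of the simulated ridge pattern
#'
#' `(n_rows - 1) * row_pitch + wrap_gap`; 12.8 mm with the default 8-row,
#' 1.6 mm-pitch geometry, guaranteeing that only one ridge is felt at a time.
#'
#' @param geometry an [array_geometry()] object.
#' @return Period in mm.
#' @export
ridge_spatial_period <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  (geometry$n_rows - 1) * geometry$row_pitch + geometry$wrap_gap
}

#' Simulate the row-actuation timeline of the moving virtual ridge
#'
#' The virtual ridge position advances by `v_tact * refresh_period` every
#' refresh; the active row is the one whose spatial segment the (wrapped)
#' ridge currently overlaps, rows being actuated in sequence in the direction
#' of `sign(v_tact)` with immediate hand-off and no cross-fading. With
#' `v_tact = 0` a single row stays active for the whole duration.
#'
#' @param geometry an [array_geometry()] object.
#' @param v_tact commanded apparent ridge velocity, mm/s (sign = direction).
#' @param duration simulated time, s (> 0).
#' @return An object of class `stimulus_timeline`: a data.frame of activation
#'   events (`time` s, `row` 1-based index, `ridge_position` unwrapped mm) with
#'   the geometry, `v_tact` and `duration` stored as attributes. Exactly one
#'   row is active between consecutive events.
#' @export
#' @examples
#' tl <- build_row_timeline(array_geometry(), v_tact = 10, duration = 3)
#' measured_ridge_period(tl)  # 12.8 mm
build_row_timeline <- function(geometry, v_tact, duration) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(v_tact)) stop("v_tact must be finite")
  period <- ridge_spatial_period(geometry)
  times <- seq(0, duration, by = geometry$refresh_period)
  pos <- v_tact * times
  wrapped <- pos %% period
  row <- pmin(floor(wrapped / geometry$row_pitch) + 1L, geometry$n_rows)
  keep <- c(TRUE, row[-1L] != row[-length(row)])
  events <- data.frame(time = times[keep], row = row[keep],
                       ridge_position = pos[keep])
  structure(events, class = c("stimulus_timeline", "data.frame"),
            geometry = geometry, v_tact = v_tact, duration = duration)
}

#' Ridge travel between successive activations of the same row
#'
#' Measures the emergent spatial period directly from a timeline: the mean
#' absolute ridge displacement between consecutive activations of the row that
#' is active first. Equals [ridge_spatial_period()] of the generating geometry.
#'
#' @param timeline a [build_row_timeline()] result spanning at least two
#'   activations of the same row.
#' @return Displacement in mm.
#' @export
measured_ridge_period <- function(timeline) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  # drop the t = 0 event: the ridge starts exactly on a segment edge, so its
  # first interval is not a full period
  ev <- timeline[-1L, , drop = FALSE]
  reps <- table(ev$row)
  rows <- names(reps)[reps >= 2]
  if (nrow(ev) == 0L || length(rows) == 0L) {
    stop("timeline too short: no row was re-activated")
  }
  idx <- which(ev$row == as.integer(rows[1L]))
  mean(abs(diff(ev$ridge_position[idx])))
}

#' Write a stimulus timeline to CSV
#'
#' @param timeline a `stimulus_timeline`.
#' @param path output CSV path (columns time, row, ridge_position).
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  utils::write.csv(as.data.frame(timeline), path, row.names = FALSE)
  invisible(path)
}

#' Finger-pursuit trace of one trial
#'
#' Two-phase pursuit kinematics: the ridge (and finger) move at a fixed speed
#' for the first part of the displacement, then the surface velocity changes
#' suddenly while the finger keeps moving (main task) or stops (control task).
#'
#' @param phase1_speed tracking speed in phase 1, mm/s.
#' @param phase1_distance finger displacement covered in phase 1, mm.
#' @param total_distance total finger displacement of a trial, mm.
#' @param v_prop_phase2 mean finger velocity during phase 2, mm/s (the measured
#'   mean rather than the instructed speed).
#' @return An object of class `pursuit_trace`.
#' @export
pursuit_trace <- function(phase1_speed = 10, phase1_distance = 50,
                          total_distance = 100, v_prop_phase2 = 10.8) {
  if (phase1_distance <= 0 || total_distance <= phase1_distance) {
    stop("need 0 < phase1_distance < total_distance")
  }
  if (phase1_speed <= 0) stop("phase1_speed must be > 0")
  structure(list(phase1_speed = phase1_speed,
                 phase1_distance = phase1_distance,
                 total_distance = total_distance,
                 v_prop_phase2 = v_prop_phase2),
            class = "pursuit_trace")
}

#' Phase-2 channel velocities of a trial
#'
#' Maps the world-frame surface velocity onto the two sensory channels in the
#' second (judged) phase of a trial. In the main task the finger keeps moving,
#' so the tactile slip is `v_surf - v_prop`; in the control task the finger is
#' stationary and the slip equals the surface velocity.
#'
#' @param trace a [pursuit_trace()].
#' @param v_surf world-frame surface velocity, mm/s.
#' @param condition `"main"` or `"control"`.
#' @return Named list with `v_prop` and `v_tact` (mm/s).
#' @export
#' @examples
#' trial_kinematics(pursuit_trace(), v_surf = 0, condition = "main")
trial_kinematics <- function(trace, v_surf, condition = c("main", "control")) {
  stopifnot(inherits(trace, "pursuit_trace"))
  condition <- match.arg(condition)
  if (condition == "main") {
    list(v_prop = trace$v_prop_phase2, v_tact = v_surf - trace$v_prop_phase2)
  } else {
    list(v_prop = 0, v_tact = v_surf)
  }
}
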