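#' Optokinetic response: saccade detection and OKR index
#'
#' Saccades are detected as eye-angle velocity threshold crossings with a
#' refractory period; the OKR index is the count of saccades in the
#' stimulus-expected direction minus the count in the opposite direction
#' within a stimulation window, averaged over both eyes.
#'
#' @name okr
NULL

#' Detect saccades in an eye-angle trace
#'
#' An event is recorded where |d angle / dt| crosses the velocity threshold;
#' its direction is the sign of the velocity at the crossing, and subsequent
#' crossings within the refractory window (per eye) are suppressed.
#'
#' @param trace an `eye_trace` (uniform sampling required).
#' @param velocity_threshold saccade velocity criterion (deg/s).
#' @param refractory suppression window after an event (s).
#' @return data.frame (time, eye, direction), time-sorted.
#' @export
detect_saccades <- function(trace, velocity_threshold = 100,
                            refractory = 0.5) {
  stopifnot(velocity_threshold > 0)
  dt <- diff(trace$time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("non-uniform sampling")
  dt <- mean(dt)
  one_eye <- function(angle, eye) {
    v <- diff(angle) / dt
    hits <- which(abs(v) >= velocity_threshold)
    times <- numeric(0); dirs <- numeric(0)
    last <- -Inf
    for (i in hits) {
      tc <- trace$time[i + 1]
      if (tc - last < refractory) next
      times <- c(times, tc)
      dirs <- c(dirs, sign(v[i]))
      last <- tc
    }
    data.frame(time = times, eye = rep(eye, length(times)),
               direction = dirs)
  }
  ev <- rbind(one_eye(trace$angle_left, "left"),
              one_eye(trace$angle_right, "right"))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' OKR index from detected saccades
#'
#' Per eye, the number of saccades in the expected direction minus the number
#' in the opposite direction within the window; the combined index is the
#' mean of the two eyes.
#'
#' @param events data.frame from [detect_saccades()].
#' @param expected_direction +1 or -1.
#' @param window `c(start, end)` in seconds (inclusive).
#' @return list with `index_left`, `index_right`, `combined`,
#'   `n_expected`/`n_opposite` per eye, and the window used.
#' @export
okr_index <- function(events, expected_direction, window) {
  stopifnot(expected_direction %in% c(-1, 1), length(window) == 2)
  if (window[2] <= window[1]) stop("empty stimulation window")
  per_eye <- function(eye) {
    ev <- events[events$eye == eye & events$time >= window[1] &
                   events$time <= window[2], , drop = FALSE]
    n_exp <- sum(ev$direction == expected_direction)
    n_opp <- sum(ev$direction == -expected_direction)
    c(n_expected = n_exp, n_opposite = n_opp, index = n_exp - n_opp)
  }
  l <- per_eye("left"); r <- per_eye("right")
  list(index_left = unname(l["index"]), index_right = unname(r["index"]),
       combined = unname((l["index"] + r["index"]) / 2),
       n_expected = c(left = unname(l["n_expected"]),
                      right = unname(r["n_expected"])),
       n_opposite = c(left = unname(l["n_opposite"]),
                      right = unname(r["n_opposite"])),
       window = window)
}
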