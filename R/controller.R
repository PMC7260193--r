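#' Closed-loop controller configuration
#'
#' Settings of the proportional acoustic power controller used during
#' microbubble sonications.  The power starts at `p_start`, is modulated
#' between `t_control_start` and `t_control_end` so that the harmonic
#' emission level `H` falls in the goal band `[goal_lo, goal_hi]` dB above
#' the noise floor, and is never allowed to exceed `p_max`.  A subharmonic
#' or wideband detection reduces the power by `trigger_reduction` and locks
#' it for the remainder of the sonication.
#'
#' @param p_gain Proportional gain, sqrt(W) per dB.
#' @param goal_lo,goal_hi Goal band for the harmonic level, dB.
#' @param p_start Starting acoustic power, W.
#' @param p_max Maximum allowed acoustic power, W.
#' @param p_min Lower power bound, W (a floor preventing degenerate
#'   zero-power states after repeated safety triggers).
#' @param t_control_start,t_control_end Control window, seconds after
#'   sonication start.
#' @param trigger_reduction Fractional power reduction on a safety trigger.
#' @param burst_ms Burst length, ms.
#' @param interval_ms Interval between consecutive bursts (across targets), ms.
#' @param n_targets Targets per volumetric sonication.
#' @param dur_no_mb,dur_mb Sonication durations without / with microbubbles, s.
#' @param k_sub,k_wide Detection thresholds in floor standard deviations.
#'
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(p_gain = 0.0167, goal_lo = 6, goal_hi = 7.5,
                              p_start = 0.16, p_max = 0.39, p_min = 0.01,
                              t_control_start = 8, t_control_end = 25,
                              trigger_reduction = 0.40,
                              burst_ms = 5, interval_ms = 101.6,
                              n_targets = 9L, dur_no_mb = 30, dur_mb = 55,
                              k_sub = 3.3, k_wide = 4) {
  stopifnot(p_gain > 0, goal_lo < goal_hi,
            0 < p_min, p_min < p_start, p_start <= p_max,
            t_control_start < t_control_end, t_control_end < dur_mb,
            trigger_reduction > 0, trigger_reduction < 1,
            burst_ms > 0, interval_ms >= burst_ms, n_targets >= 1)
  structure(
    list(p_gain = p_gain, goal_lo = goal_lo, goal_hi = goal_hi,
         p_start = p_start, p_max = p_max, p_min = p_min,
         t_control_start = t_control_start, t_control_end = t_control_end,
         trigger_reduction = trigger_reduction,
         burst_ms = burst_ms, interval_ms = interval_ms,
         n_targets = as.integer(n_targets),
         dur_no_mb = dur_no_mb, dur_mb = dur_mb,
         k_sub = k_sub, k_wide = k_wide),
    class = "controller_config")
}

#' Per-target controller state
#'
#' @param cfg A [controller_config()].
#' @return An object of class `controller_state` with elements `phase`
#'   (`"baseline"`, `"controlling"`, `"fixed"` or `"locked"`), `power` (W),
#'   `goal_hits` (powers of bursts whose `H` fell in the goal band) and
#'   `trigger_time` (s, `NA` if no safety trigger fired).
#' @export
controller_state <- function(cfg = controller_config()) {
  structure(
    list(phase = "baseline", power = cfg$p_start,
         goal_hits = numeric(0), trigger_time = NA_real_),
    class = "controller_state")
}

clamp_power <- function(p, cfg) min(max(p, cfg$p_min), cfg$p_max)

#' Proportional power update
#'
#' Given the harmonic emission level `H` (dB above the noise floor) of the
#' current burst, computes the power for the next burst:
#' `P_new = (sqrt(P_current) - p_gain * (H - H_goal))^2`, where `H_goal` is
#' the nearest edge of the goal band.  If `H` already lies inside the band
#' the power is unchanged (and recorded as a goal hit by [step_controller()]).
#' The result is clamped to `[p_min, p_max]`.
#'
#' @param state A [controller_state()] in phase `"controlling"`.
#' @param H Harmonic emission level, dB.
#' @param cfg A [controller_config()].
#'
#' @return New power in watts.
#' @export
power_update <- function(state, H, cfg = controller_config()) {
  if (!is.finite(H)) return(state$power)  # burst skipped
  if (H >= cfg$goal_lo && H <= cfg$goal_hi) return(state$power)
  h_goal <- if (H > cfg$goal_hi) cfg$goal_hi else cfg$goal_lo
  clamp_power((sqrt(state$power) - cfg$p_gain * (H - h_goal))^2, cfg)
}

#' Safety trigger: 40% power reduction and lock
#'
#' Applied when subharmonic or wideband emission is detected: the power is
#' reduced by `trigger_reduction` (then clamped to at least `p_min`) and
#' fixed for the remainder of the sonication.  Idempotent on an already
#' locked state.
#'
#' @param state A [controller_state()].
#' @param t Time of the triggering burst, s.
#' @inheritParams power_update
#' @return Updated `controller_state` with `phase = "locked"`.
#' @export
apply_safety_trigger <- function(state, cfg = controller_config(), t = NA_real_) {
  if (identical(state$phase, "locked")) return(state)
  state$power <- clamp_power(state$power * (1 - cfg$trigger_reduction), cfg)
  state$phase <- "locked"
  state$trigger_time <- t
  state
}

#' Commit the post-control-window power
#'
#' At the end of the control window the power is fixed to the mean of the
#' powers of all bursts whose `H` fell inside the goal band; if no burst
#' achieved the goal the last power is held.  A locked state is left
#' untouched.
#'
#' @inheritParams apply_safety_trigger
#' @return Updated `controller_state` with `phase = "fixed"` (unless locked).
#' @export
finalize_power <- function(state, cfg = controller_config()) {
  if (identical(state$phase, "locked")) return(state)
  if (length(state$goal_hits) > 0L)
    state$power <- clamp_power(mean(state$goal_hits), cfg)
  state$phase <- "fixed"
  state
}

#' Advance the controller by one burst
#'
#' Implements the burst-to-burst control logic for one target:
#' \itemize{
#'   \item `t < t_control_start`: baseline phase, power held at `p_start`
#'     (the early noise floor is still being measured, so detection flags
#'     are not yet defined);
#'   \item `t_control_start <= t`: a safety trigger (subharmonic or wideband
#'     flag) takes precedence over everything and locks the power at 60% of
#'     its current value;
#'   \item otherwise, within the control window the proportional update is
#'     applied and in-band bursts are recorded as goal hits;
#'   \item past `t_control_end` the power is committed once (mean of the
#'     goal-hit powers) and never increased again; trigger checks remain
#'     active.
#' }
#'
#' @param state A [controller_state()].
#' @param features An [extract_features()] result (or any list with `H`,
#'   `sub_flag`, `wide_flag`).
#' @param t Burst time, seconds since sonication start.
#' @param cfg A [controller_config()].
#'
#' @return Updated `controller_state` holding the power for the next burst.
#' @export
step_controller <- function(state, features, t, cfg = controller_config()) {
  if (identical(state$phase, "locked")) return(state)
  if (t < cfg$t_control_start) {
    state$power <- cfg$p_start
    return(state)
  }
  flag <- isTRUE(features$sub_flag) || isTRUE(features$wide_flag)
  if (flag) return(apply_safety_trigger(state, cfg, t = t))
  if (t <= cfg$t_control_end) {
    if (identical(state$phase, "baseline")) state$phase <- "controlling"
    H <- features$H
    if (is.finite(H) && H >= cfg$goal_lo && H <= cfg$goal_hi)
      state$goal_hits <- c(state$goal_hits, state$power)
    state$power <- power_update(state, H, cfg)
  } else if (identical(state$phase, "controlling") ||
             identical(state$phase, "baseline")) {
    state <- finalize_power(state, cfg)
  }
  state
}

#' Round-robin burst schedule
#'
#' Bursts are applied sequentially to the `n_targets` targets of a
#' volumetric sonication at a fixed inter-burst interval, so each target is
#' revisited every `n_targets * interval_ms` (9 targets at 101.6 ms give a
#' per-target pulse repetition frequency of 1.1 Hz).
#'
#' @param cfg A [controller_config()].
#' @param duration Sonication duration in seconds (default `cfg$dur_mb`).
#'
#' @return A data frame with columns `burst_idx`, `t` (s) and `target_id`
#'   (0-based), with attributes `prf_hz` (per-target PRF) and
#'   `bursts_per_target`.
#' @export
burst_schedule <- function(cfg = controller_config(), duration = cfg$dur_mb) {
  interval <- cfg$interval_ms / 1000
  period <- cfg$n_targets * interval
  n_bursts <- floor(duration / interval)
  bursts_per_target <- floor(duration / period)
  if (bursts_per_target < 1L)
    warning("duration shorter than one round-robin period: ",
            "empty per-target schedule")
  idx <- seq_len(n_bursts) - 1L
  out <- data.frame(burst_idx = idx + 1L, t = idx * interval,
                    target_id = idx %% cfg$n_targets)
  attr(out, "prf_hz") <- 1 / period
  attr(out, "bursts_per_target") <- bursts_per_target
  out
}

#' Power-to-pressure calibration
#'
#' Two calibration points tie acoustic power to peak negative pressure in
#' water: 0.16 W at 68 kPa and 0.39 W at 165 kPa.  Interpolation is linear
#' in sqrt(power), consistent with pressure scaling with the square root of
#' power (neither a pure `p ~ sqrt(W)` law nor linearity in W passes through
#' both printed points).
#'
#' @param points Two-column matrix or data frame of (power W, pressure kPa)
#'   calibration points, pressures increasing with power.
#' @return An object of class `power_calibration`.
#' @export
power_calibration <- function(points = cbind(power_w = c(0.16, 0.39),
                                             pressure_kpa = c(68, 165))) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 2L,
            all(points > 0), !is.unsorted(points[, 1L], strictly = TRUE),
            !is.unsorted(points[, 2L], strictly = TRUE))
  structure(list(points = points), class = "power_calibration")
}

#' Convert acoustic power to peak negative pressure
#'
#' @param power Acoustic power in watts (vectorised).
#' @param cal A [power_calibration()].
#' @return Peak negative pressure in kPa.
#' @export
power_to_pressure <- function(power, cal = power_calibration()) {
  if (any(power <= 0)) stop("power must be positive", call. = FALSE)
  s <- sqrt(cal$points[, 1L])
  p <- cal$points[, 2L]
  n <- length(s)
  rng <- range(cal$points[, 1L])
  if (any(power < rng[1] - 1e-12 | power > rng[2] + 1e-12))
    warning("power outside the calibrated range [",
            rng[1], ", ", rng[2], "] W; extrapolating")
  x <- sqrt(power)
  out <- stats::approx(s, p, xout = pmin(pmax(x, s[1L]), s[n]))$y
  lo <- x < s[1L]
  hi <- x > s[n]
  out[lo] <- p[1L] + (x[lo] - s[1L]) * (p[2L] - p[1L]) / (s[2L] - s[1L])
  out[hi] <- p[n] + (x[hi] - s[n]) * (p[n] - p[n - 1L]) / (s[n] - s[n - 1L])
  out
}
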