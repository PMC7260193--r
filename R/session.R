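#' Run a simulated closed-loop sonication session
#'
#' Orchestrates the full per-session protocol: for each volumetric
#' sonication group, a fixed-power pass without microbubbles followed by a
#' controlled pass with microbubbles.  For every pass, baseline bursts
#' (3.5 s worth) are first generated to estimate the pre-sonication noise
#' floor; during the microbubble pass a second floor is accumulated from
#' the fixed-power bursts of the first 8 s and used for the subharmonic /
#' wideband detection thresholds.  Each of the 9 targets carries an
#' independent [controller_state()] advanced by [step_controller()];
#' there is no cross-target coupling.
#'
#' @param emitter An [synthetic_emitter()] (or any list with `freq` and
#'   `mags(power, t, mb)`).
#' @param cfg A [controller_config()].
#' @param bands A [band_set()].
#' @param seed Optional integer seed making the whole session reproducible.
#' @param groups Group ids to sonicate (default `0:3`).
#' @param passes Which passes to run: subset of `c("no_mb", "mb")`.  The
#'   no-microbubble pass runs at the fixed starting power; the controller is
#'   only active with microbubbles.
#' @param n_baseline Baseline bursts per pass used for the pre-sonication
#'   floor; default is 3.5 s at the burst interval.
#'
#' @return A `burst_log` data frame with one row per burst and columns
#'   `burst_idx`, `t_s`, `pass`, `group_id`, `target_id`, `power_w`,
#'   `h2_db`, `h3_db`, `H_db`, `sub_db`, `wide_db`, `sub_flag`, `wide_flag`,
#'   `phase`.  Final per-target controller states are attached as the
#'   `final_states` attribute.
#' @export
run_session <- function(emitter = synthetic_emitter(),
                        cfg = controller_config(),
                        bands = band_set(), seed = NULL,
                        groups = 0:3, passes = c("no_mb", "mb"),
                        n_baseline = NULL) {
  passes <- match.arg(passes, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  interval <- cfg$interval_ms / 1000
  if (is.null(n_baseline)) n_baseline <- max(2L, floor(3.5 / interval))
  idx <- lapply(stats::setNames(nm = names(bands)), function(nm)
    band_indices(emitter$freq, bands, nm))
  for (nm in names(idx))
    if (length(idx[[nm]]) == 0L)
      stop("band ", nm, " not resolvable on the emitter grid", call. = FALSE)
  band_means <- function(m)
    vapply(idx, function(i) mean(m[i]), numeric(1))

  chunks <- list()
  final_states <- list()
  for (g in groups) {
    for (pass in passes) {
      mb <- pass == "mb"
      duration <- if (mb) cfg$dur_mb else cfg$dur_no_mb
      # pre-sonication noise floor from baseline bursts (no bubbles)
      base <- matrix(0, n_baseline, 4L)
      for (b in seq_len(n_baseline))
        base[b, ] <- band_means(emitter$mags(cfg$p_start, -3.5, FALSE))
      floor_pre <- colMeans(base)
      sched <- burst_schedule(cfg, duration)
      nb <- nrow(sched)
      states <- replicate(cfg$n_targets, controller_state(cfg),
                          simplify = FALSE)
      pw <- h2 <- h3 <- sub <- wide <- numeric(nb)
      sflag <- wflag <- rep(NA, nb)
      phase <- character(nb)
      early <- matrix(NA_real_, nb, 2L)  # sub/wide in-band means, first 8 s
      n_early <- 0L
      early_ref <- NULL  # list(mean, sd_db) per sub/wide once window closes
      for (b in seq_len(nb)) {
        tid <- sched$target_id[b] + 1L
        t <- sched$t[b]
        st <- states[[tid]]
        p_burst <- if (mb) st$power else cfg$p_start
        m <- band_means(emitter$mags(p_burst, t, mb))
        lev <- 20 * log10(m / floor_pre)
        if (t < cfg$t_control_start) {
          n_early <- n_early + 1L
          early[n_early, ] <- m[3:4]
        } else if (is.null(early_ref) && n_early >= 2L) {
          em <- early[seq_len(n_early), , drop = FALSE]
          mu <- colMeans(em)
          early_ref <- list(
            mean = mu,
            sd_db = c(stats::sd(20 * log10(em[, 1L] / mu[1L])),
                      stats::sd(20 * log10(em[, 2L] / mu[2L]))))
        }
        feat <- list(H = (lev[1L] + lev[2L]) / 2,
                     sub_flag = NA, wide_flag = NA)
        if (!is.null(early_ref) && t >= cfg$t_control_start) {
          feat$sub_flag <- 20 * log10(m[3L] / early_ref$mean[1L]) >
            cfg$k_sub * early_ref$sd_db[1L]
          feat$wide_flag <- 20 * log10(m[4L] / early_ref$mean[2L]) >
            cfg$k_wide * early_ref$sd_db[2L]
        }
        pw[b] <- p_burst
        h2[b] <- lev[1L]; h3[b] <- lev[2L]
        sub[b] <- lev[3L]; wide[b] <- lev[4L]
        sflag[b] <- feat$sub_flag; wflag[b] <- feat$wide_flag
        phase[b] <- st$phase
        if (mb) states[[tid]] <- step_controller(st, feat, t, cfg)
      }
      chunks[[length(chunks) + 1L]] <- data.frame(
        t_s = sched$t, pass = pass, group_id = g,
        target_id = sched$target_id, power_w = pw,
        h2_db = h2, h3_db = h3, H_db = (h2 + h3) / 2,
        sub_db = sub, wide_db = wide,
        sub_flag = sflag, wide_flag = wflag, phase = phase)
      if (mb) final_states[[as.character(g)]] <- states
    }
  }
  log <- do.call(rbind, chunks)
  log <- cbind(burst_idx = seq_len(nrow(log)), log)
  attr(log, "final_states") <- final_states
  attr(log, "cfg") <- cfg
  class(log) <- c("burst_log", "data.frame")
  log
}

pct <- function(num, den) if (den == 0) 0 else 100 * num / den

#' Session summary of controller performance
#'
#' Aggregates a burst log into the session-level metrics reported for
#' closed-loop BBB-opening sessions: per pass (with / without microbubbles)
#' and per volumetric-sonication group, the fraction of locations whose
#' harmonic emission reached the controller goal band at least once, the
#' burst- and location-level rates of subharmonic and wideband detections,
#' and the fraction of bursts delivered at the maximum allowed power.
#'
#' @param log A `burst_log` from [run_session()] (or a data frame with the
#'   same columns).
#' @param cfg A [controller_config()]; defaults to the one attached to the
#'   log.
#'
#' @return An object of class `session_summary`: a list with data frames
#'   `overall` (one row per pass) and `by_group` (one row per pass x group).
#' @export
summarize_session <- function(log, cfg = attr(log, "cfg")) {
  if (nrow(log) == 0L) stop("empty burst log", call. = FALSE)
  if (is.null(cfg)) cfg <- controller_config()
  summarise_rows <- function(d) {
    loc <- interaction(d$group_id, d$target_id, drop = TRUE)
    in_band <- d$H_db >= cfg$goal_lo & d$H_db <= cfg$goal_hi
    sflag <- !is.na(d$sub_flag) & d$sub_flag
    wflag <- !is.na(d$wide_flag) & d$wide_flag
    n_loc <- nlevels(loc)
    goal_loc <- sum(tapply(in_band, loc, any))
    data.frame(
      n_locations = n_loc,
      n_goal_achieved = goal_loc,
      pct_locations_goal = pct(goal_loc, n_loc),
      pct_bursts_sub = pct(sum(sflag), nrow(d)),
      pct_bursts_wide = pct(sum(wflag), nrow(d)),
      pct_locations_sub = pct(sum(tapply(sflag, loc, any)), n_loc),
      pct_locations_wide = pct(sum(tapply(wflag, loc, any)), n_loc),
      pct_bursts_at_pmax = pct(sum(d$power_w >= cfg$p_max - 1e-9), nrow(d)))
  }
  overall <- do.call(rbind, lapply(split(log, log$pass), summarise_rows))
  overall <- cbind(pass = rownames(overall), overall, row.names = NULL)
  key <- interaction(log$pass, log$group_id, drop = TRUE)
  by_group <- do.call(rbind, lapply(split(log, key), summarise_rows))
  meta <- do.call(rbind, strsplit(rownames(by_group), ".", fixed = TRUE))
  by_group <- cbind(pass = meta[, 1L],
                    group_id = as.integer(meta[, 2L]),
                    by_group, row.names = NULL)
  structure(list(overall = overall, by_group = by_group),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>\n\nOverall:\n")
  print(x$overall, digits = 3)
  cat("\nBy group:\n")
  print(x$by_group, digits = 3)
  invisible(x)
}

#' Planned sonication-location counts across a study
#'
#' Bookkeeping for a multi-session design: each session delivers
#' `n_groups` volumetric sonications of `n_targets` locations, once without
#' and once with microbubbles.  Whole volumetric sonications can be
#' excluded from each arm (e.g. lost recordings), removing `n_targets`
#' locations apiece.  With 30 sessions of 4 x 9 targets, four excluded
#' no-microbubble and one excluded microbubble sonications, this yields
#' 1044 and 1071 analysable locations respectively.
#'
#' @param n_sessions Number of sessions.
#' @param n_groups Volumetric sonications per session.
#' @param n_targets Targets per volumetric sonication.
#' @param excluded_no_mb,excluded_mb Number of excluded volumetric
#'   sonications in the no-microbubble / microbubble arm.
#'
#' @return A list with elements `no_mb` and `mb`: analysable location
#'   counts per arm.
#' @export
planned_location_counts <- function(n_sessions = 30, n_groups = 4,
                                    n_targets = 9,
                                    excluded_no_mb = 4, excluded_mb = 1) {
  total <- n_sessions * n_groups
  stopifnot(excluded_no_mb <= total, excluded_mb <= total)
  list(no_mb = (total - excluded_no_mb) * n_targets,
       mb = (total - excluded_mb) * n_targets)
}

#' Write / read a burst log as CSV
#'
#' @param log A `burst_log` data frame.
#' @param path File path.
#' @return `write_burst_log` returns `path` invisibly; `read_burst_log`
#'   returns a `burst_log` data frame.
#' @export
write_burst_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_burst_log
#' @export
read_burst_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(log) <- c("burst_log", "data.frame")
  log
}
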