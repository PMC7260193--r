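#' Per-burst spectrum record
#'
#' Container for the magnitude spectrum recorded by a passive cavitation
#' detector during one ultrasound burst, together with the target it was
#' aimed at and the acoustic power that produced it.
#'
#' @param freq Numeric vector of frequencies in Hz, strictly increasing.
#' @param mag Nonnegative magnitudes, one per frequency bin.
#' @param target_id Integer 0-8: position within the 9-target volumetric
#'   sonication.
#' @param group_id Integer 0-3: which of the four volumetric sonications.
#' @param t Seconds since the start of the sonication.
#' @param power Applied acoustic power in watts.
#'
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(freq, mag, target_id = 0L, group_id = 0L,
                            t = 0, power = NA_real_) {
  freq <- as.numeric(freq)
  mag <- as.numeric(mag)
  if (length(freq) != length(mag))
    stop("`freq` and `mag` must have the same length", call. = FALSE)
  if (any(diff(freq) <= 0))
    stop("`freq` must be strictly increasing", call. = FALSE)
  if (any(mag < 0))
    stop("`mag` must be nonnegative", call. = FALSE)
  structure(
    list(target_id = as.integer(target_id), group_id = as.integer(group_id),
         t = as.numeric(t), power = as.numeric(power),
         freq = freq, mag = mag),
    class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf(
    "<spectrum_record> target %d group %d, t = %.2f s, power = %.3f W, %d bins (%.0f-%.0f kHz)\n",
    x$target_id, x$group_id, x$t, x$power, length(x$freq),
    min(x$freq) / 1e3, max(x$freq) / 1e3))
  invisible(x)
}

#' Emission analysis bands
#'
#' Frequency bands used to quantify microbubble acoustic emissions for a
#' transcranial device driven at a 230 kHz fundamental: second and third
#' harmonic bands (+/- 10 kHz around 460 and 690 kHz), the subharmonic band
#' (115 +/- 10 kHz, monitored by a low-frequency hydrophone) and a wideband
#' window (660 +/- 40 kHz) whose elevation signals inertial cavitation.
#'
#' @param fundamental_hz Drive frequency in Hz.
#' @param harmonic_halfwidth_hz Half-width of the harmonic bands, Hz.
#' @param subharmonic_halfwidth_hz Half-width of the subharmonic band, Hz.
#' @param broadband_halfwidth_hz Half-width of the wideband window, Hz.
#' @param broadband_center_hz Center of the wideband window (the resonance
#'   of the broadband hydrophone, not a harmonic), Hz.
#'
#' @return An object of class `band_set`: a named list of `c(lo, hi)`
#'   intervals in Hz with elements `harmonic2`, `harmonic3`, `subharmonic`
#'   and `broadband`, plus the fundamental as an attribute.
#' @export
band_set <- function(fundamental_hz = 230e3,
                     harmonic_halfwidth_hz = 10e3,
                     subharmonic_halfwidth_hz = 10e3,
                     broadband_halfwidth_hz = 40e3,
                     broadband_center_hz = 660e3) {
  stopifnot(fundamental_hz > 0, harmonic_halfwidth_hz > 0,
            subharmonic_halfwidth_hz > 0, broadband_halfwidth_hz > 0,
            broadband_center_hz > 0)
  ctr <- function(f, hw) c(f - hw, f + hw)
  structure(
    list(harmonic2 = ctr(2 * fundamental_hz, harmonic_halfwidth_hz),
         harmonic3 = ctr(3 * fundamental_hz, harmonic_halfwidth_hz),
         subharmonic = ctr(fundamental_hz / 2, subharmonic_halfwidth_hz),
         broadband = ctr(broadband_center_hz, broadband_halfwidth_hz)),
    fundamental_hz = fundamental_hz,
    class = "band_set")
}

band_names <- c("harmonic2", "harmonic3", "subharmonic", "broadband")

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set> fundamental", attr(x, "fundamental_hz") / 1e3, "kHz\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %6.0f - %6.0f kHz\n", nm, x[[nm]][1] / 1e3,
                x[[nm]][2] / 1e3))
  invisible(x)
}

#' Frequency-bin indices of an analysis band
#'
#' For the `"broadband"` band the bins falling inside the harmonic
#' measurement bands are excluded: the wideband statistic quantifies
#' emission between the spectral lines, and must not rise simply because
#' the controller drives the (fully contained) third harmonic to its goal.
#'
#' @param freq Frequency grid, Hz.
#' @param bands A [band_set()].
#' @param name Band name.
#' @return Integer vector of bin indices.
#' @export
band_indices <- function(freq, bands, name) {
  b <- bands[[name]]
  if (is.null(b)) stop("unknown band name: ", name, call. = FALSE)
  idx <- which(freq >= b[1] & freq <= b[2])
  if (name == "broadband") {
    for (h in c("harmonic2", "harmonic3")) {
      hb <- bands[[h]]
      idx <- setdiff(idx, which(freq >= hb[1] & freq <= hb[2]))
    }
  }
  idx
}

in_band_mean <- function(spectrum, band) {
  idx <- which(spectrum$freq >= band[1] & spectrum$freq <= band[2])
  if (length(idx) == 0L)
    stop(sprintf("band [%g, %g] Hz contains no frequency bins",
                 band[1], band[2]), call. = FALSE)
  mean(spectrum$mag[idx])
}

named_band_mean <- function(spectrum, bands, name) {
  idx <- band_indices(spectrum$freq, bands, name)
  if (length(idx) == 0L)
    stop("band ", name, " contains no frequency bins", call. = FALSE)
  mean(spectrum$mag[idx])
}

check_band_coverage <- function(spectrum, bands) {
  lo <- min(vapply(bands, `[`, numeric(1), 1L))
  hi <- max(vapply(bands, `[`, numeric(1), 2L))
  if (min(spectrum$freq) > lo || max(spectrum$freq) < hi)
    stop("spectrum grid does not span all analysis bands", call. = FALSE)
  invisible(TRUE)
}

#' Estimate per-band noise floors from baseline bursts
#'
#' The noise floor for each analysis band is the mean (over baseline bursts)
#' of the in-band mean magnitude; its spread is the sample standard
#' deviation, across bursts, of the per-burst level in dB relative to that
#' mean.  Two floors are used in practice: one measured for 3.5 s before the
#' sonication starts (`source = "pre_sonication"`, the dB reference for all
#' reported levels), and one from the bursts applied at the fixed starting
#' power during the first 8 s of the microbubble sonication
#' (`source = "early_fixed_power"`, the reference for the subharmonic and
#' wideband detection thresholds).
#'
#' @param baseline_spectra List of [spectrum_record()] objects sharing one
#'   frequency grid; at least two.
#' @param bands A [band_set()].
#' @param source Provenance tag, `"pre_sonication"` or `"early_fixed_power"`.
#'
#' @return An object of class `noise_floor`: per band, `mean_level` (linear
#'   magnitude), `sd_db` (dB spread across bursts) and `n_bursts`.
#' @export
estimate_noise_floor <- function(baseline_spectra, bands = band_set(),
                                 source = c("pre_sonication",
                                            "early_fixed_power")) {
  source <- match.arg(source)
  n <- length(baseline_spectra)
  if (n < 2L)
    stop("at least 2 baseline bursts are required to estimate a noise floor",
         call. = FALSE)
  f0 <- baseline_spectra[[1L]]$freq
  for (s in baseline_spectra)
    if (length(s$freq) != length(f0) || any(s$freq != f0))
      stop("all baseline spectra must share the same frequency grid",
           call. = FALSE)
  check_band_coverage(baseline_spectra[[1L]], bands)
  per_band <- lapply(stats::setNames(nm = names(bands)), function(nm) {
    m <- vapply(baseline_spectra, named_band_mean, numeric(1),
                bands = bands, name = nm)
    mean_level <- mean(m)
    if (mean_level <= 0)
      stop("baseline in-band magnitude is zero; noise floor undefined",
           call. = FALSE)
    list(mean_level = mean_level,
         sd_db = stats::sd(20 * log10(m / mean_level)),
         n_bursts = n)
  })
  structure(c(per_band, list(source = source)), class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat("<noise_floor> source:", x$source, "\n")
  for (nm in band_names)
    cat(sprintf("  %-12s mean %.4g, sd %.3f dB (n = %d)\n", nm,
                x[[nm]]$mean_level, x[[nm]]$sd_db, x[[nm]]$n_bursts))
  invisible(x)
}

resolve_band <- function(band, bands) {
  if (is.character(band)) {
    if (!band %in% names(bands))
      stop("unknown band name: ", band, call. = FALSE)
    bands[[band]]
  } else {
    stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
    band
  }
}

#' In-band emission level in dB relative to a noise floor
#'
#' Spectra are treated as amplitude-like, so levels are `20 log10` ratios of
#' the in-band mean magnitude to the floor's mean level.
#'
#' @param spectrum A [spectrum_record()].
#' @param band Band name (looked up in `floor`) or a `c(lo, hi)` interval in
#'   Hz; a named band is required when `floor` is a `noise_floor`.
#' @param floor A `noise_floor` (band looked up by name) or a single positive
#'   number used directly as the reference mean level.
#' @param bands A [band_set()] used to resolve `band` when it is a name.
#'
#' @return Level in dB.
#' @export
band_level_db <- function(spectrum, band, floor, bands = band_set()) {
  ref <- if (inherits(floor, "noise_floor")) {
    if (!is.character(band))
      stop("a named band is required to look up a noise_floor", call. = FALSE)
    floor[[band]]$mean_level
  } else {
    as.numeric(floor)
  }
  if (!is.finite(ref) || ref <= 0)
    stop("noise-floor mean level must be positive", call. = FALSE)
  level <- if (is.character(band)) {
    named_band_mean(spectrum, bands, band)
  } else {
    in_band_mean(spectrum, resolve_band(band, bands))
  }
  20 * log10(level / ref)
}

#' Extract emission features from one burst
#'
#' Computes second/third-harmonic, subharmonic and wideband levels in dB
#' relative to the pre-sonication noise floor, the controller input
#' `H` (dB-domain mean of the two harmonic levels), and detection flags for
#' subharmonic and wideband emission.  A flag is raised when the band level,
#' measured relative to the early fixed-power floor, exceeds `k` standard
#' deviations of that floor (k = 3.3 for subharmonic, 4 for wideband).
#'
#' @param spectrum A [spectrum_record()].
#' @param bands A [band_set()].
#' @param floor_pre Pre-sonication noise floor (dB reference for levels).
#' @param floor_early Early fixed-power noise floor (threshold reference);
#'   `NULL` leaves both flags `NA`.
#' @param k_sub,k_wide Detection thresholds in floor standard deviations.
#'
#' @return An object of class `emission_features` with elements `h2_db`,
#'   `h3_db`, `H` (dB), `sub_db`, `wide_db`, `sub_flag`, `wide_flag`.
#' @export
extract_features <- function(spectrum, bands = band_set(), floor_pre,
                             floor_early = NULL, k_sub = 3.3, k_wide = 4) {
  stopifnot(inherits(floor_pre, "noise_floor"))
  h2 <- band_level_db(spectrum, "harmonic2", floor_pre, bands)
  h3 <- band_level_db(spectrum, "harmonic3", floor_pre, bands)
  sub <- band_level_db(spectrum, "subharmonic", floor_pre, bands)
  wide <- band_level_db(spectrum, "broadband", floor_pre, bands)
  if (is.null(floor_early)) {
    sub_flag <- NA
    wide_flag <- NA
  } else {
    stopifnot(inherits(floor_early, "noise_floor"))
    sub_early <- band_level_db(spectrum, "subharmonic", floor_early, bands)
    wide_early <- band_level_db(spectrum, "broadband", floor_early, bands)
    sub_flag <- sub_early > k_sub * floor_early$subharmonic$sd_db
    wide_flag <- wide_early > k_wide * floor_early$broadband$sd_db
  }
  structure(
    list(h2_db = h2, h3_db = h3, H = (h2 + h3) / 2,
         sub_db = sub, wide_db = wide,
         sub_flag = sub_flag, wide_flag = wide_flag),
    class = "emission_features")
}

#' @export
print.emission_features <- function(x, ...) {
  cat(sprintf(
    "<emission_features> H = %.2f dB (h2 %.2f, h3 %.2f); sub %.2f dB [%s]; wide %.2f dB [%s]\n",
    x$H, x$h2_db, x$h3_db, x$sub_db,
    ifelse(is.na(x$sub_flag), "NA", ifelse(x$sub_flag, "FLAG", "ok")),
    x$wide_db,
    ifelse(is.na(x$wide_flag), "NA", ifelse(x$wide_flag, "FLAG", "ok"))))
  invisible(x)
}
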