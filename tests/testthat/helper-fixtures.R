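# Shared fixtures: small deterministic spectra and hand-built noise floors.

test_freq <- seq(50e3, 750e3, by = 1e3)

# Flat spectrum of constant magnitude on a grid spanning all bands.
flat_spectrum <- function(mag = 1, ...) {
  spectrum_record(freq = test_freq, mag = rep(mag, length(test_freq)), ...)
}

# Spectrum with prescribed dB levels (re a unit floor) in each measurement
# band; levels apply to exactly the bins the feature extractor averages.
leveled_spectrum <- function(h2_db = 0, h3_db = 0, sub_db = 0, wide_db = 0,
                             floor_level = 1, bands = band_set(), ...) {
  mag <- rep(floor_level, length(test_freq))
  lv <- c(harmonic2 = h2_db, harmonic3 = h3_db,
          subharmonic = sub_db, broadband = wide_db)
  for (nm in names(lv))
    mag[band_indices(test_freq, bands, nm)] <-
      floor_level * 10^(lv[[nm]] / 20)
  spectrum_record(freq = test_freq, mag = mag, ...)
}

# Hand-built noise floor with chosen mean level and dB spread in each band.
manual_floor <- function(mean_level = 1, sd_db = 0, n_bursts = 10L,
                         source = "pre_sonication") {
  per <- list(mean_level = mean_level, sd_db = sd_db, n_bursts = n_bursts)
  structure(list(harmonic2 = per, harmonic3 = per, subharmonic = per,
                 broadband = per, source = source),
            class = "noise_floor")
}

# Emitter on a reduced synthesis grid (2048 samples -> ~977 Hz bins): all
# bands stay resolvable while sessions run quickly.
fast_params <- function(...) emission_model_params(n_samples = 2048, ...)

# Deterministic emitter producing a fixed harmonic level H whenever
# microbubbles are present, on the reduced grid.
constant_h_emitter <- function(H = 7, bands = band_set()) {
  em <- synthetic_emitter(fast_params(gain_h = 0, jitter_db = 0,
                                      bin_sd_db = 0))
  f <- 10^(H / 20)
  i2 <- band_indices(em$freq, bands, "harmonic2")
  i3 <- band_indices(em$freq, bands, "harmonic3")
  em$mags <- function(power, t, mb = TRUE) {
    m <- rep(1, length(em$freq))
    if (mb && t >= 0) {
      m[i2] <- f
      m[i3] <- f
    }
    m
  }
  em
}
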