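test_that("noise floor of identical flat baselines has zero spread", {
  spectra <- replicate(10, flat_spectrum(1), simplify = FALSE)
  nf <- estimate_noise_floor(spectra, source = "pre_sonication")
  for (nm in c("harmonic2", "harmonic3", "subharmonic", "broadband")) {
    expect_equal(nf[[nm]]$mean_level, 1)
    expect_equal(nf[[nm]]$sd_db, 0)
    expect_equal(nf[[nm]]$n_bursts, 10L)
  }
})

test_that("noise floor mean and dB spread match hand arithmetic", {
  nf <- estimate_noise_floor(list(flat_spectrum(1), flat_spectrum(10)),
                             source = "early_fixed_power")
  # in-band means 1 and 10: mean 5.5; sd of {20log10(1/5.5), 20log10(10/5.5)}
  expect_equal(nf$harmonic2$mean_level, 5.5)
  expect_equal(nf$harmonic2$sd_db, 14.1421356237, tolerance = 1e-9)
  expect_equal(nf$source, "early_fixed_power")
})

test_that("noise floor estimation validates its inputs", {
  expect_error(estimate_noise_floor(list(flat_spectrum(1))),
               "at least 2")
  other_grid <- spectrum_record(freq = seq(60e3, 760e3, by = 1e3),
                                mag = rep(1, 701))
  expect_error(estimate_noise_floor(list(flat_spectrum(1), other_grid)),
               "same frequency grid")
})

test_that("band levels follow the 20 log10 amplitude convention", {
  nf <- estimate_noise_floor(replicate(3, flat_spectrum(1),
                                       simplify = FALSE))
  expect_equal(band_level_db(flat_spectrum(1), "harmonic2", nf), 0)
  expect_equal(band_level_db(flat_spectrum(10), "harmonic2", nf), 20)
  expect_equal(band_level_db(flat_spectrum(2), "harmonic3", nf),
               6.02059991328, tolerance = 1e-9)
  expect_error(band_level_db(flat_spectrum(1), "harmonic2", 0),
               "positive")
})

test_that("band level is scale-equivariant in the spectrum magnitudes", {
  set.seed(11)
  for (rep in 1:5) {
    mag <- exp(rnorm(length(test_freq), 0, 0.3))
    s1 <- spectrum_record(test_freq, mag)
    cc <- exp(runif(1, -2, 2))
    s2 <- spectrum_record(test_freq, cc * mag)
    for (band in c("harmonic2", "subharmonic", "broadband"))
      expect_equal(band_level_db(s2, band, 1) - band_level_db(s1, band, 1),
                   20 * log10(cc), tolerance = 1e-10)
  }
})

test_that("feature extraction reproduces prescribed band levels and H", {
  nf <- manual_floor()
  s0 <- flat_spectrum(1)
  f0 <- extract_features(s0, floor_pre = nf, floor_early = nf)
  expect_equal(f0$h2_db, 0)
  expect_equal(f0$H, 0)
  expect_false(f0$sub_flag)
  expect_false(f0$wide_flag)

  s <- leveled_spectrum(h2_db = 8, h3_db = 6)
  f <- extract_features(s, floor_pre = nf, floor_early = nf)
  expect_equal(f$h2_db, 8, tolerance = 1e-9)
  expect_equal(f$h3_db, 6, tolerance = 1e-9)
  expect_equal(f$H, 7, tolerance = 1e-9)
  expect_equal(f$H, (f$h2_db + f$h3_db) / 2)

  # H is invariant under swapping which harmonic carries which level
  f_sw <- extract_features(leveled_spectrum(h2_db = 6, h3_db = 8),
                           floor_pre = nf, floor_early = nf)
  expect_equal(f$H, f_sw$H, tolerance = 1e-9)
})

test_that("missing early floor leaves detection flags undefined", {
  f <- extract_features(flat_spectrum(1), floor_pre = manual_floor())
  expect_true(is.na(f$sub_flag))
  expect_true(is.na(f$wide_flag))
})

test_that("detection thresholds bracket at k standard deviations", {
  floor_early <- manual_floor(sd_db = 1, source = "early_fixed_power")
  nf <- manual_floor()
  f_hi <- extract_features(leveled_spectrum(sub_db = 3.4),
                           floor_pre = nf, floor_early = floor_early)
  expect_true(f_hi$sub_flag)
  f_lo <- extract_features(leveled_spectrum(sub_db = 3.2),
                           floor_pre = nf, floor_early = floor_early)
  expect_false(f_lo$sub_flag)
  # wideband threshold sits at 4 sd
  expect_true(extract_features(leveled_spectrum(wide_db = 4.1),
                               floor_pre = nf,
                               floor_early = floor_early)$wide_flag)
  expect_false(extract_features(leveled_spectrum(wide_db = 3.9),
                                floor_pre = nf,
                                floor_early = floor_early)$wide_flag)
})

test_that("flags are monotone in level: a wideband trigger level would also trigger the laxer subharmonic threshold", {
  floor_early <- manual_floor(sd_db = 0.8, source = "early_fixed_power")
  nf <- manual_floor()
  for (lv in seq(0.5, 8, by = 0.5)) {
    f <- extract_features(leveled_spectrum(sub_db = lv, wide_db = lv),
                          floor_pre = nf, floor_early = floor_early)
    if (f$wide_flag) expect_true(f$sub_flag)
  }
})

test_that("without microbubbles the harmonic level carries no control signal", {
  set.seed(202)
  em <- synthetic_emitter(fast_params())
  base <- replicate(100, spectrum_record(em$freq, em$mags(0.16, -1, FALSE)),
                    simplify = FALSE)
  nf <- estimate_noise_floor(base)
  sdh <- (nf$harmonic2$sd_db + nf$harmonic3$sd_db) / 2
  h <- replicate(1000, {
    s <- spectrum_record(em$freq, em$mags(0.16, 20, FALSE))
    (band_level_db(s, "harmonic2", nf) +
       band_level_db(s, "harmonic3", nf)) / 2
  })
  expect_gte(mean(abs(h) < 3 * sdh), 0.99)
})

test_that("band set geometry is anchored to the fundamental", {
  b <- band_set()
  expect_equal(mean(b$harmonic2), 2 * 230e3)
  expect_equal(mean(b$harmonic3), 3 * 230e3)
  expect_equal(mean(b$subharmonic), 115e3)
  expect_equal(b$broadband, c(620e3, 700e3))
  # broadband measurement bins exclude the harmonic bands it contains
  idx <- band_indices(test_freq, b, "broadband")
  expect_false(any(test_freq[idx] >= 680e3 & test_freq[idx] <= 700e3))
})
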