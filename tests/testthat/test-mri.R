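seven_trs <- c(6, 3.2, 1.6, 0.8, 0.4, 0.2, 0.1)

test_that("noiseless R1 fits recover the truth to numerical precision", {
  g <- image_geom(nx = 6, ny = 6, dx = 1)
  mask <- matrix(TRUE, 6, 6)
  r1_vals <- seq(0.5, 2, length.out = 36)
  ph <- phantom_spec(g, mask, r1_base = 1, pd = 100)
  ph$r1 <- matrix(r1_vals, 6, 6)
  ser <- simulate_tr_series(ph, trs = seven_trs)
  fit <- fit_r1_map(ser)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$r1 - ph$r1) / ph$r1), 1e-6)
  expect_lt(max(abs(fit$m0 - 100) / 100), 1e-6)
})

test_that("the exact two-point solution agrees with the full fit on noiseless data", {
  r1_true <- 1.3
  s <- 80 * (1 - exp(-seven_trs * r1_true))
  tp <- r1_two_point(s[7], seven_trs[7], s[1], seven_trs[1])
  expect_equal(tp$r1, r1_true, tolerance = 1e-9)
  expect_equal(tp$m0, 80, tolerance = 1e-7)
  g <- image_geom(nx = 2, ny = 2, dx = 1)
  ph <- phantom_spec(g, matrix(TRUE, 2, 2), r1_base = r1_true, pd = 80)
  fit <- fit_r1_map(simulate_tr_series(ph, trs = seven_trs))
  expect_equal(fit$r1[1, 1], tp$r1, tolerance = 1e-7)
})

test_that("degenerate voxels are marked invalid without raising", {
  g <- image_geom(nx = 2, ny = 2, dx = 1)
  ph <- phantom_spec(g, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                     r1_base = 1, pd = 100)
  ser <- simulate_tr_series(ph, trs = seven_trs)
  ser$data[2, 1, ] <- 0  # dead voxel inside the fitted mask
  fit <- fit_r1_map(ser, mask = matrix(TRUE, 2, 2))
  expect_false(fit$valid[2, 1])
  expect_true(fit$valid[1, 1])
  expect_true(is.na(fit$r1[2, 1]))
})

test_that("hemispheric Delta-R1 is zero for identical hemispheres and exact for injected offsets", {
  g <- image_geom(nx = 64, ny = 72, dx = 0.5)
  mask <- brain_mask_ellipse(g)
  grid <- build_target_grid(mask, g)
  rois <- make_roi_masks(grid, g)
  # identical hemispheres
  ph0 <- phantom_spec(g, mask, r1_base = 0.7)
  fit0 <- list(r1 = ph0$r1)
  d0 <- roi_delta_r1(fit0, rois)
  expect_equal(d0$overall$delta_r1, 0)
  expect_true(all(d0$per_target$delta_r1 == 0))
  # injected offset, noiseless, read straight from the ground truth
  ph <- phantom_spec(g, mask, r1_base = 0.7, rois = rois, delta_r1 = 0.075)
  d <- roi_delta_r1(list(r1 = ph$r1), rois)
  expect_equal(d$overall$delta_r1, 0.075, tolerance = 1e-12)
  expect_equal(d$per_group$delta_r1, rep(0.075, 4), tolerance = 1e-12)
})

test_that("the two-group ANOVA equals the squared two-sample t statistic", {
  set.seed(21)
  g <- image_geom(nx = 64, ny = 72, dx = 0.5)
  mask <- brain_mask_ellipse(g)
  rois <- make_roi_masks(build_target_grid(mask, g), g)
  ph <- phantom_spec(g, mask, r1_base = 0.7, noise_sd = 1,
                     rois = rois, delta_r1 = 0.05)
  r1 <- ph$r1 + matrix(rnorm(g$nx * g$ny, 0, 0.02), g$nx, g$ny)
  d <- roi_delta_r1(list(r1 = r1), rois)
  son <- d$per_target$mean_son
  ctl <- d$per_target$mean_ctl
  tt <- t.test(son, ctl, var.equal = TRUE)
  expect_equal(d$overall$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(d$overall$p, tt$p.value, tolerance = 1e-9)
})

test_that("Delta-R1 converts linearly to contrast-agent concentration", {
  expect_equal(gadavist_concentration(0), 0, ignore_attr = TRUE)
  expect_equal(gadavist_concentration(4.44), 1, ignore_attr = TRUE)
  expect_equal(gadavist_concentration(0.075), 0.0168918918919,
               tolerance = 1e-9, ignore_attr = TRUE)
  for (a in c(0.5, 2, 7))
    expect_equal(gadavist_concentration(a * 0.075),
                 a * gadavist_concentration(0.075), ignore_attr = TRUE)
  expect_true(attr(gadavist_concentration(-0.01), "negative"))
})

test_that("percent enhancement uses a voxelwise MIP over repeats", {
  pre <- matrix(10, 8, 8)
  expect_equal(signal_enhancement(pre, list(pre))$map,
               matrix(0, 8, 8))
  expect_equal(signal_enhancement(pre, list(1.1 * pre))$map,
               matrix(10, 8, 8), tolerance = 1e-12)
  # complementary checkerboards: each repeat averages below 5%, the MIP
  # reaches 5% everywhere
  chk <- matrix((row(pre) + col(pre)) %% 2 == 0, 8, 8)
  p1 <- pre * ifelse(chk, 1.05, 1)
  p2 <- pre * ifelse(chk, 1, 1.05)
  enh <- signal_enhancement(pre, list(p1, p2))
  expect_equal(enh$map, matrix(5, 8, 8), tolerance = 1e-12)
  expect_lt(mean(100 * (p1 - pre) / pre), 5)
  # zero-pre voxels are excluded and counted
  pre0 <- pre; pre0[1, 1] <- 0
  enh0 <- signal_enhancement(pre0, list(1.1 * pre0))
  expect_equal(enh0$n_excluded, 1)
  expect_true(is.na(enh0$map[1, 1]))
})

test_that("predicted spin-echo enhancement matches the closed form and quenches at high R2", {
  expect_equal(predict_se_enhancement(0), 0)
  expect_equal(predict_se_enhancement(0.02), 10.3631855317, tolerance = 1e-9)
  cc <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(predict_se_enhancement(cc)) > 0))
  sp_r2 <- sequence_params(relaxivity_r2 = 5)
  expect_lt(predict_se_enhancement(5, sp_r2),
            predict_se_enhancement(4, sp_r2))
  expect_gt(predict_se_enhancement(1, sp_r2), 0)
})

test_that("measured enhancement tracks the spin-echo prediction across ROIs", {
  g <- image_geom(nx = 64, ny = 72, dx = 0.5)
  mask <- brain_mask_ellipse(g)
  rois <- make_roi_masks(build_target_grid(mask, g), g)
  sp <- sequence_params()
  conc <- c(0.012, 0.017, 0.022, 0.027)  # mM per volumetric group
  # per-voxel concentration map (adjacent group unions share some voxels;
  # the later group wins, exactly as the phantom builder assigns offsets)
  cmap <- matrix(0, g$nx, g$ny)
  for (i in seq_along(conc)) cmap[rois$group[[i]]] <- conc[i]
  s0 <- (1 - exp(-sp$tr * sp$r1_tissue)) * exp(-sp$te * sp$r2_tissue)
  sC <- (1 - exp(-sp$tr * (sp$r1_tissue + sp$relaxivity_r1 * cmap))) *
    exp(-sp$te * sp$r2_tissue)
  pre <- matrix(0, g$nx, g$ny)
  pre[mask] <- 100 * s0
  post <- pre
  post[mask] <- 100 * sC[mask]
  enh <- signal_enhancement(pre, list(post), mask, rois)
  # disks can poke slightly outside the brain ellipse; the enhancement map
  # is NA there, so the oracle averages over in-mask ROI voxels only
  expected <- vapply(rois$group, function(m)
    mean(predict_se_enhancement(cmap[m & mask], sp)), numeric(1))
  expect_equal(enh$per_group$mean_son, unname(expected), tolerance = 1e-9)
  # regression through zero of ROI enhancement on ROI-mean concentration
  # sits within 5% of the model's local slope
  conc_roi <- vapply(rois$group, function(m) mean(cmap[m & mask]), numeric(1))
  slope <- coef(lm(enh$per_group$mean_son ~ 0 + conc_roi))[[1]]
  local <- predict_se_enhancement(mean(conc_roi), sp) / mean(conc_roi)
  expect_lt(abs(slope - local) / local, 0.05)
})
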