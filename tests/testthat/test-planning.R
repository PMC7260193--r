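geom <- image_geom()
mask <- brain_mask_ellipse(geom)

test_that("the default brain mask yields 36 in-mask targets in 4 groups of 9", {
  grid <- build_target_grid(mask, geom)
  expect_equal(nrow(grid), 36)
  expect_equal(as.vector(table(grid$group_id)), rep(9L, 4))
  expect_equal(sort(unique(grid$target_id)), 0:8)
  expect_true(all(grid$x_mm > 0))
  expect_true(all(mask[cbind(
    round((grid$x_mm - geom$x0) / geom$dx) + 1,
    round((grid$y_mm - geom$y0) / geom$dy) + 1)]))
  # lattice spacing: nearest neighbours at least 1 mm apart
  d <- as.matrix(dist(grid[, c("x_mm", "y_mm")]))
  diag(d) <- Inf
  expect_gte(min(d), 1 - 1e-9)
  # groups are ordered anterior to posterior
  gy <- tapply(grid$y_mm, grid$group_id, mean)
  expect_true(all(diff(gy) < 0))
  # deterministic: no RNG involved
  expect_identical(grid, build_target_grid(mask, geom))
})

test_that("a rectangular hemisphere mask fits exactly 36 targets and halving the density fails", {
  g <- image_geom(nx = 60, ny = 50, dx = 0.25, x0 = -2, y0 = -5)
  m <- outer(geom_x(g), geom_y(g),
             function(x, y) x >= 0 & x <= 10 & abs(y) <= 4)
  grid <- build_target_grid(m, g)
  expect_equal(nrow(grid), 36)
  expect_equal(as.vector(table(grid$group_id)), rep(9L, 4))
  expect_error(build_target_grid(m, g, spacing = 2), "candidate targets")
})

test_that("ventricle exclusion keeps targets out of the excluded region", {
  vmask <- brain_mask_ellipse(geom, ventricles = TRUE)
  grid <- build_target_grid(vmask, geom)
  excl <- attr(vmask, "exclude")
  hits <- excl[cbind(round((grid$x_mm - geom$x0) / geom$dx) + 1,
                     round((grid$y_mm - geom$y0) / geom$dy) + 1)]
  expect_false(any(hits))
})

test_that("ROI disks match a brute-force rasterization oracle", {
  g <- image_geom(nx = 40, ny = 40, dx = 0.25)
  grid <- structure(data.frame(target_id = 0L, group_id = 0L,
                               x_mm = 2, y_mm = 0),
                    midline_x = 0, spacing = 1,
                    class = c("target_grid", "data.frame"))
  rois <- make_roi_masks(grid, g, radius = 1.25)
  # oracle: loop over every voxel center
  xs <- g$x0 + (seq_len(g$nx) - 1) * g$dx
  ys <- g$y0 + (seq_len(g$ny) - 1) * g$dy
  count <- 0L
  oracle <- integer(0)
  for (iy in seq_len(g$ny)) for (ix in seq_len(g$nx))
    if ((xs[ix] - 2)^2 + (ys[iy] - 0)^2 <= 1.25^2) {
      count <- count + 1L
      oracle <- c(oracle, (iy - 1L) * g$nx + ix)
    }
  expect_setequal(rois$target[[1]], oracle)
  expect_lte(abs(count - pi * (1.25 / 0.25)^2), 5)
  # mirrored disk has the same voxel count on the symmetric grid
  expect_equal(length(rois$mirror[[1]]), length(rois$target[[1]]))
})

test_that("overlapping targets share voxels and mirrors never meet sonicated disks", {
  grid <- build_target_grid(mask, geom)
  rois <- make_roi_masks(grid, geom)
  a <- rois$target[[1]]
  b <- rois$target[[2]]
  # neighbours 1 mm apart with 1.25 mm radius overlap
  expect_lt(length(union(a, b)), length(a) + length(b))
  expect_length(intersect(unlist(rois$target), unlist(rois$mirror)), 0)
  # group masks are unions of their member disks
  g0 <- which(rois$group[["0"]])
  expect_setequal(g0, unique(unlist(rois$target[grid$group_id == 0])))
})

test_that("mask mirroring across the midline is an involution", {
  rois <- make_roi_masks(build_target_grid(mask, geom), geom)
  m <- rois$group[["1"]]
  mm <- mirror_mask(m, geom)
  expect_equal(sum(mm), sum(m))
  expect_identical(mirror_mask(mm, geom), m)
  # the mirrored group union equals the stored contralateral mask
  expect_identical(mm, rois$group_mirror[["1"]])
})

test_that("energy density map is linear in targets and conserves kernel mass", {
  # target on a voxel center so the kernel peak is attained exactly
  one <- structure(data.frame(target_id = 0L, group_id = 0L,
                              x_mm = 1.875, y_mm = 1.125),
                   midline_x = 0, class = c("target_grid", "data.frame"))
  map1 <- energy_density_map(one, focal_kernel(), geom)
  peak <- which(map1 == max(map1), arr.ind = TRUE)
  expect_equal(geom_x(geom)[peak[1, 1]], 1.875)
  expect_equal(geom_y(geom)[peak[1, 2]], 1.125)
  expect_equal(max(map1), 1, tolerance = 1e-9)
  two <- one[c(1, 1), ]
  attr(two, "midline_x") <- 0
  class(two) <- c("target_grid", "data.frame")
  expect_equal(energy_density_map(two, focal_kernel(), geom), 2 * map1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # full plan: total mass = 36 x single-kernel mass
  grid <- build_target_grid(mask, geom)
  map <- energy_density_map(grid, focal_kernel(), geom)
  expect_true(all(map >= 0))
  # anterior-most kernels lose a sliver of tail mass at the image border
  expect_equal(sum(map), 36 * sum(map1), tolerance = 1e-3)
})

test_that("the summed map peaks inside the central region of the plan", {
  grid <- build_target_grid(mask, geom)
  map <- energy_density_map(grid, focal_kernel(), geom)
  peak <- which(map == max(map), arr.ind = TRUE)
  px <- geom_x(geom)[peak[1]]
  py <- geom_y(geom)[peak[2]]
  expect_lt(abs(px - mean(grid$x_mm)), 2)
  expect_lt(abs(py - mean(grid$y_mm)), 2)
  # well inside the convex extent of the plan, not at its rim
  expect_gt(px, min(grid$x_mm))
  expect_lt(px, max(grid$x_mm))
  expect_gt(py, min(grid$y_mm))
  expect_lt(py, max(grid$y_mm))
})
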