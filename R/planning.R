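#' 2D image geometry for planning and quantification
#'
#' A simple axial-plane raster geometry: `nx` x `ny` voxels of size
#' `dx` x `dy` mm, with voxel-center coordinates.  By default the grid is
#' centered on the origin so the brain midline can sit at `x = 0`.
#'
#' @param nx,ny Grid size in voxels (x: left-right, y: anterior-posterior).
#' @param dx,dy Voxel size, mm.
#' @param x0,y0 Coordinate of the first voxel center, mm; default centers
#'   the grid on the origin.
#' @return An object of class `image_geom`.
#' @export
image_geom <- function(nx = 96L, ny = 112L, dx = 0.25, dy = dx,
                       x0 = NULL, y0 = NULL) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, dy > 0)
  if (is.null(x0)) x0 <- -(nx - 1) / 2 * dx
  if (is.null(y0)) y0 <- -(ny - 1) / 2 * dy
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dy = dy, x0 = x0, y0 = y0),
            class = "image_geom")
}

geom_x <- function(geom) geom$x0 + (seq_len(geom$nx) - 1) * geom$dx
geom_y <- function(geom) geom$y0 + (seq_len(geom$ny) - 1) * geom$dy

#' Stylized rat-brain mask
#'
#' An elliptical axial brain outline (half-axes `a` x `b` mm, centered on
#' the origin) serving as a synthetic stand-in for a registered anatomical
#' template.  Optionally carves out a small midline "ventricle" ellipse to
#' exercise the ventricle-exclusion path of [build_target_grid()].
#'
#' @param geom An [image_geom()].
#' @param a,b Half-axes of the brain ellipse, mm (left-right,
#'   anterior-posterior).
#' @param ventricles If `TRUE`, returns the brain mask with an attached
#'   `"exclude"` attribute marking a small periventricular ellipse.
#' @return Logical `nx` x `ny` matrix.
#' @export
brain_mask_ellipse <- function(geom = image_geom(), a = 8, b = 10,
                               ventricles = FALSE) {
  xs <- geom_x(geom); ys <- geom_y(geom)
  m <- outer(xs, ys, function(x, y) (x / a)^2 + (y / b)^2 <= 1)
  if (ventricles) {
    v <- outer(xs, ys, function(x, y)
      ((x - 1.5) / 1)^2 + ((y - 1) / 1.5)^2 <= 1)
    attr(m, "exclude") <- v
  }
  m
}

mask_at <- function(mask, geom, x, y) {
  ix <- round((x - geom$x0) / geom$dx) + 1
  iy <- round((y - geom$y0) / geom$dy) + 1
  ok <- ix >= 1 & ix <= geom$nx & iy >= 1 & iy <= geom$ny
  out <- logical(length(x))
  out[ok] <- mask[cbind(ix[ok], iy[ok])]
  out
}

#' Build the volumetric sonication target grid
#'
#' Places `n_targets` targets on a regular lattice (default 1 mm
#' center-to-center spacing) inside one hemisphere of the brain mask,
#' conforming to its shape, and partitions them into `n_groups` contiguous
#' groups ordered anterior to posterior (each group is one volumetric
#' sonication).  Candidate points are scanned anterior-first, medial to
#' lateral; points inside an exclusion mask (e.g. ventricles) are skipped.
#' Generation is deterministic for a fixed mask.
#'
#' @param mask Logical brain mask matrix (may carry an `"exclude"`
#'   attribute, see [brain_mask_ellipse()]).
#' @param geom The [image_geom()] of `mask`.
#' @param spacing Lattice spacing, mm.
#' @param midline_x Midline x-coordinate, mm; targets are placed at
#'   `x >= midline_x + margin`.
#' @param margin Minimal distance of a target from the midline, mm (keeps
#'   the 2.5 mm analysis ROIs from crossing into the contralateral
#'   hemisphere).
#' @param n_targets Total number of targets.
#' @param n_groups Number of volumetric-sonication groups.
#' @param exclude Optional logical matrix of voxels to avoid (overrides the
#'   mask attribute).
#'
#' @return An object of classes `target_grid` and `data.frame` with columns
#'   `target_id` (0-8 within group), `group_id` (0-based), `x_mm`, `y_mm`;
#'   attributes `spacing` and `midline_x`.
#' @export
build_target_grid <- function(mask, geom = image_geom(), spacing = 1,
                              midline_x = 0, margin = 1.3,
                              n_targets = 36L, n_groups = 4L,
                              exclude = NULL) {
  stopifnot(n_targets %% n_groups == 0L, any(mask))
  if (is.null(exclude)) exclude <- attr(mask, "exclude")
  xs <- seq(midline_x + margin, max(geom_x(geom)), by = spacing)
  ys <- seq(min(geom_y(geom)), max(geom_y(geom)), by = spacing)
  cand <- expand.grid(x = xs, y = ys)
  keep <- mask_at(mask, geom, cand$x, cand$y)
  if (!is.null(exclude))
    keep <- keep & !mask_at(exclude, geom, cand$x, cand$y)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < n_targets)
    stop(sprintf(
      "mask holds only %d candidate targets at %.2g mm spacing; %d needed",
      nrow(cand), spacing, n_targets), call. = FALSE)
  cand <- cand[order(-cand$y, cand$x), , drop = FALSE][seq_len(n_targets), ]
  per_group <- n_targets %/% n_groups
  out <- data.frame(
    target_id = rep(seq_len(per_group) - 1L, times = n_groups),
    group_id = rep(seq_len(n_groups) - 1L, each = per_group),
    x_mm = cand$x, y_mm = cand$y)
  structure(out, spacing = spacing, midline_x = midline_x,
            class = c("target_grid", "data.frame"))
}

disk_indices <- function(geom, xc, yc, radius) {
  xs <- geom_x(geom); ys <- geom_y(geom)
  ix <- which(abs(xs - xc) <= radius)
  iy <- which(abs(ys - yc) <= radius)
  if (length(ix) == 0L || length(iy) == 0L) return(integer(0))
  g <- expand.grid(ix = ix, iy = iy)
  d2 <- (xs[g$ix] - xc)^2 + (ys[g$iy] - yc)^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  (g$iy - 1L) * geom$nx + g$ix
}

#' Analysis ROI masks with contralateral mirrors
#'
#' Rasterizes a disk of the given radius (default 1.25 mm, i.e. the 2.5 mm
#' diameter analysis region) around each sonication target, the reflection
#' of each disk across the midline (the contralateral control region), and
#' their per-group unions.  A voxel belongs to a disk when its center lies
#' within the radius.
#'
#' @param grid A [build_target_grid()] result.
#' @param geom The [image_geom()] the masks are rasterized on.
#' @param radius ROI radius, mm.
#'
#' @return An object of class `roi_set`: lists `target` and `mirror` of
#'   linear voxel-index vectors (one per target, in `grid` row order),
#'   logical matrices `group` and `group_mirror` (one per group), plus
#'   `geom`, `grid`, `radius` and `midline_x`.
#' @export
make_roi_masks <- function(grid, geom = image_geom(), radius = 1.25) {
  midline <- attr(grid, "midline_x")
  if (is.null(midline)) midline <- 0
  xr <- range(geom_x(geom)); yr <- range(geom_y(geom))
  tgt <- vector("list", nrow(grid))
  mir <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x_mm[i]; y <- grid$y_mm[i]
    xm <- 2 * midline - x
    for (xx in c(x, xm))
      if (xx - radius < xr[1] || xx + radius > xr[2] ||
          y - radius < yr[1] || y + radius > yr[2])
        stop(sprintf("ROI for target %d (group %d) extends outside the field of view",
                     grid$target_id[i], grid$group_id[i]), call. = FALSE)
    tgt[[i]] <- disk_indices(geom, x, y, radius)
    mir[[i]] <- disk_indices(geom, xm, y, radius)
  }
  if (length(intersect(unlist(tgt), unlist(mir))) > 0L)
    stop("sonicated and mirrored ROIs overlap; increase the midline margin",
         call. = FALSE)
  groups <- sort(unique(grid$group_id))
  union_mask <- function(idx_list) {
    m <- matrix(FALSE, geom$nx, geom$ny)
    m[unlist(idx_list)] <- TRUE
    m
  }
  grp <- lapply(groups, function(g) union_mask(tgt[grid$group_id == g]))
  grp_m <- lapply(groups, function(g) union_mask(mir[grid$group_id == g]))
  names(grp) <- names(grp_m) <- as.character(groups)
  structure(list(target = tgt, mirror = mir, group = grp,
                 group_mirror = grp_m, geom = geom, grid = grid,
                 radius = radius, midline_x = midline),
            class = "roi_set")
}

#' Reflect a mask across the midline
#'
#' Exact voxelwise reflection for grids symmetric about the midline; an
#' involution (`mirror_mask(mirror_mask(m)) == m`).
#'
#' @param mask Logical matrix.
#' @param geom An [image_geom()].
#' @param midline_x Midline x-coordinate, mm.
#' @return Logical matrix of the same shape.
#' @export
mirror_mask <- function(mask, geom = image_geom(), midline_x = 0) {
  xs <- geom_x(geom)
  ixp <- round((2 * midline_x - xs - geom$x0) / geom$dx) + 1
  out <- matrix(FALSE, geom$nx, geom$ny)
  ok <- ixp >= 1 & ixp <= geom$nx
  out[ixp[ok], ] <- mask[which(ok), ]
  out
}

#' Focal intensity kernel
#'
#' Anisotropic Gaussian model of the focal intensity distribution, peak
#' normalized to 1.  The axial full-width-at-half-maximum defaults to the
#' 3.5 mm length of the disruption along the beam; the lateral width is a
#' configurable 3.0 mm.
#'
#' @param fwhm_lateral,fwhm_axial Full width at half maximum, mm.
#' @return An object of class `focal_kernel`.
#' @export
focal_kernel <- function(fwhm_lateral = 3.0, fwhm_axial = 3.5) {
  stopifnot(fwhm_lateral > 0, fwhm_axial > 0)
  structure(list(fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial),
            class = "focal_kernel")
}

#' Summed-intensity energy-density map
#'
#' Evaluates one focal-kernel translate per sonication target on the image
#' grid and sums them, giving the relative acoustic energy density
#' delivered by the full 36-target plan.  In the axial planning plane both
#' in-plane directions use the lateral kernel width; the map is linear in
#' the target list and nonnegative.
#'
#' @param grid A [build_target_grid()] result.
#' @param kernel A [focal_kernel()].
#' @param geom An [image_geom()].
#' @return Numeric `nx` x `ny` matrix with attribute `geom`.
#' @export
energy_density_map <- function(grid, kernel = focal_kernel(),
                               geom = image_geom()) {
  xs <- geom_x(geom); ys <- geom_y(geom)
  k <- 4 * log(2)
  fw2 <- kernel$fwhm_lateral^2
  map <- matrix(0, geom$nx, geom$ny)
  for (i in seq_len(nrow(grid))) {
    gx <- exp(-k * (xs - grid$x_mm[i])^2 / fw2)
    gy <- exp(-k * (ys - grid$y_mm[i])^2 / fw2)
    map <- map + outer(gx, gy)
  }
  attr(map, "geom") <- geom
  map
}
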