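#' Spin-echo sequence and tissue parameters
#'
#' Parameters of the T1-weighted fast spin-echo acquisition used for
#' contrast-enhancement imaging and of the tissue it images, used by
#' [predict_se_enhancement()].  Tissue baseline relaxation rates are
#' typical low-field brain values and are exposed configuration, not
#' measured quantities.
#'
#' @param tr Repetition time, s.
#' @param te Echo time, s.
#' @param r1_tissue Baseline tissue longitudinal relaxation rate, 1/s.
#' @param r2_tissue Baseline tissue transverse relaxation rate, 1/s.
#' @param relaxivity_r1 Contrast-agent longitudinal relaxivity, 1/s/mM
#'   (gadobutrol: 4.44).
#' @param relaxivity_r2 Contrast-agent transverse relaxivity, 1/s/mM
#'   (default 0: only the R1 effect is modeled).
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(tr = 0.5, te = 0.0138,
                            r1_tissue = 0.7, r2_tissue = 12.5,
                            relaxivity_r1 = 4.44, relaxivity_r2 = 0) {
  stopifnot(tr > 0, te > 0, r1_tissue > 0, r2_tissue > 0,
            relaxivity_r1 > 0, relaxivity_r2 >= 0)
  structure(list(tr = tr, te = te, r1_tissue = r1_tissue,
                 r2_tissue = r2_tissue, relaxivity_r1 = relaxivity_r1,
                 relaxivity_r2 = relaxivity_r2),
            class = "sequence_params")
}

#' Saturation-recovery phantom specification
#'
#' Ground-truth R1 phantom for the variable-TR acquisition: a baseline R1
#' inside the brain mask, plus optional per-group offsets (`delta_r1`)
#' added inside the sonicated ROI unions of a [make_roi_masks()] result,
#' emulating gadolinium accumulation after BBB opening.
#'
#' @param geom An [image_geom()].
#' @param mask Logical brain mask.
#' @param r1_base Baseline R1, 1/s.
#' @param pd Proton-density scale (arbitrary signal units); TE decay and
#'   echo-train weighting of the FSE readout are absorbed into this scale.
#' @param noise_sd Gaussian noise SD in signal units.
#' @param rois Optional [make_roi_masks()] result.
#' @param delta_r1 Scalar or per-group vector of R1 offsets (1/s) added in
#'   the sonicated group ROIs.
#' @return An object of class `phantom_spec` with the ground-truth `r1`
#'   matrix.
#' @export
phantom_spec <- function(geom = image_geom(),
                         mask = brain_mask_ellipse(geom),
                         r1_base = 0.7, pd = 100, noise_sd = 0,
                         rois = NULL, delta_r1 = 0) {
  stopifnot(r1_base > 0, pd > 0, noise_sd >= 0)
  r1 <- matrix(0, geom$nx, geom$ny)
  r1[mask] <- r1_base
  if (!is.null(rois)) {
    ngr <- length(rois$group)
    delta <- rep_len(delta_r1, ngr)
    # voxels shared by adjacent group unions take one offset, not a sum
    dmap <- matrix(0, geom$nx, geom$ny)
    for (i in seq_len(ngr)) dmap[rois$group[[i]]] <- delta[i]
    r1 <- r1 + dmap
  }
  structure(list(geom = geom, mask = mask, r1 = r1, pd = pd,
                 noise_sd = noise_sd, rois = rois),
            class = "phantom_spec")
}

#' Simulate a variable-TR saturation-recovery series
#'
#' Voxel signal `PD * (1 - exp(-TR * R1))` plus Gaussian noise, evaluated
#' at each TR of the acquisition (default: the 7-TR protocol 6000/3200/
#' 1600/800/400/200/100 ms).  The ground-truth R1 map travels with the
#' series.
#'
#' @param phantom A [phantom_spec()].
#' @param trs Repetition times, s.
#' @param seed Optional integer seed.
#' @return An object of class `tr_series`: list with `data`
#'   (`nx` x `ny` x `n_TR` array), `trs`, `geom`, `mask`, `r1_true`, `pd`,
#'   `noise_sd`.
#' @export
simulate_tr_series <- function(phantom,
                               trs = c(6, 3.2, 1.6, 0.8, 0.4, 0.2, 0.1),
                               seed = NULL) {
  stopifnot(all(trs > 0))
  if (!is.null(seed)) set.seed(seed)
  g <- phantom$geom
  dat <- array(0, dim = c(g$nx, g$ny, length(trs)))
  for (k in seq_along(trs)) {
    s <- phantom$pd * (1 - exp(-trs[k] * phantom$r1))
    if (phantom$noise_sd > 0)
      s <- s + stats::rnorm(length(s), 0, phantom$noise_sd)
    dat[, , k] <- s
  }
  structure(list(data = dat, trs = trs, geom = g, mask = phantom$mask,
                 r1_true = phantom$r1, pd = phantom$pd,
                 noise_sd = phantom$noise_sd),
            class = "tr_series")
}

#' Exact two-point R1 solution
#'
#' Solves `S(tr_a) / S(tr_b) = (1 - exp(-tr_a R1)) / (1 - exp(-tr_b R1))`
#' for R1 from two saturation-recovery measurements; used as an algebraic
#' cross-check of the full nonlinear fit (on noiseless data the two agree
#' exactly) and, in approximate form, to initialize it.
#'
#' @param s_a,s_b Signals at the two TRs.
#' @param tr_a,tr_b The two repetition times, s (distinct).
#' @return A list with `r1` (1/s) and `m0`.
#' @export
r1_two_point <- function(s_a, tr_a, s_b, tr_b) {
  stopifnot(tr_a != tr_b, s_a > 0, s_b > 0)
  f <- function(r1) s_b * (1 - exp(-tr_a * r1)) - s_a * (1 - exp(-tr_b * r1))
  root <- stats::uniroot(f, lower = 1e-6, upper = 100, tol = 1e-12)$root
  list(r1 = root, m0 = s_b / (1 - exp(-tr_b * root)))
}

fit_voxel_r1 <- function(y, trs) {
  i_long <- which.max(trs); i_short <- which.min(trs)
  m0_0 <- y[i_long]
  if (!is.finite(m0_0) || m0_0 <= 0) return(NULL)
  ratio <- min(max(y[i_short] / m0_0, 1e-4), 1 - 1e-4)
  r1_0 <- -log(1 - ratio) / trs[i_short]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ m0 * (1 - exp(-trs * r1)),
                      start = list(m0 = m0_0, r1 = r1_0),
                      lower = c(1e-9, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(m0 = cf[["m0"]], r1 = cf[["r1"]],
       rss = sum(stats::resid(fit)^2))
}

#' Fit a voxelwise R1 map from a variable-TR series
#'
#' Per-voxel nonlinear least-squares fit of the saturation-recovery model
#' `S(TR) = M0 (1 - exp(-TR R1))`, initialized from the two extreme TRs.
#' Voxels outside the mask, voxels whose signal at the longest TR falls
#' below `3 * noise_sd`, and voxels where the fit fails to converge are
#' marked invalid.
#'
#' @param series A [simulate_tr_series()] result (or a list with `data`,
#'   `trs`, `geom`, `mask`, `noise_sd`).
#' @param mask Logical matrix restricting the fit (defaults to the series
#'   brain mask); pass a ROI union to fit only the voxels you will analyse.
#' @param noise_sd Noise SD used for the signal cutoff; defaults to the
#'   series value.
#' @return An object of class `r1_map`: matrices `r1`, `m0`, `rss` (NA
#'   outside `valid`), logical `valid`, count `n_failed`, and `geom`.
#' @export
fit_r1_map <- function(series, mask = series$mask,
                       noise_sd = series$noise_sd) {
  trs <- series$trs
  if (length(unique(trs)) < 3L)
    stop("at least 3 distinct TRs are required", call. = FALSE)
  g <- series$geom
  nv <- g$nx * g$ny
  if (is.null(mask)) mask <- matrix(TRUE, g$nx, g$ny)
  if (is.null(noise_sd)) noise_sd <- 0
  r1 <- m0 <- rss <- matrix(NA_real_, g$nx, g$ny)
  valid <- matrix(FALSE, g$nx, g$ny)
  n_failed <- 0L
  ymat <- matrix(series$data, nrow = nv)
  i_long <- which.max(trs)
  for (v in which(as.vector(mask))) {
    y <- ymat[v, ]
    if (noise_sd > 0 && y[i_long] < 3 * noise_sd) next
    fit <- fit_voxel_r1(y, trs)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    r1[v] <- fit$r1; m0[v] <- fit$m0; rss[v] <- fit$rss
    valid[v] <- TRUE
  }
  structure(list(r1 = r1, m0 = m0, rss = rss, valid = valid,
                 n_failed = n_failed, geom = g),
            class = "r1_map")
}

#' Hemispheric R1 differences over the analysis ROIs
#'
#' For each target, the ROI-mean R1 in the sonicated disk minus the mean in
#' its mirrored contralateral disk; aggregated per volumetric-sonication
#' group and overall.  Sonicated vs control comparisons use a one-way ANOVA
#' on the target-level ROI means (for two groups the F statistic is the
#' square of the two-sample t statistic).
#'
#' @param r1_map A [fit_r1_map()] result (or any list with matrix `r1`).
#' @param rois A [make_roi_masks()] result.
#' @return An object of class `roi_delta_r1`: data frames `per_target`
#'   (`group_id`, `target_id`, `mean_son`, `mean_ctl`, `delta_r1`),
#'   `per_group` (adds `f` and `p` from the ANOVA) and `overall`.
#' @export
roi_delta_r1 <- function(r1_map, rois) {
  r1 <- r1_map$r1
  roi_mean <- function(idx, what) {
    if (length(idx) == 0L)
      stop("empty ROI (", what, ")", call. = FALSE)
    mean(r1[idx], na.rm = TRUE)
  }
  grid <- rois$grid
  son <- vapply(seq_along(rois$target), function(i)
    roi_mean(rois$target[[i]], paste0("target ", i)), numeric(1))
  ctl <- vapply(seq_along(rois$mirror), function(i)
    roi_mean(rois$mirror[[i]], paste0("mirror ", i)), numeric(1))
  per_target <- data.frame(group_id = grid$group_id,
                           target_id = grid$target_id,
                           mean_son = son, mean_ctl = ctl,
                           delta_r1 = son - ctl)
  anova_two <- function(a, b) {
    d <- data.frame(v = c(a, b),
                    side = rep(c("son", "ctl"), c(length(a), length(b))))
    tab <- stats::anova(stats::lm(v ~ side, data = d))
    c(f = tab$`F value`[1L], p = tab$`Pr(>F)`[1L])
  }
  groups <- sort(unique(grid$group_id))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    i <- grid$group_id == g
    st <- anova_two(son[i], ctl[i])
    data.frame(group_id = g, mean_son = mean(son[i]), mean_ctl = mean(ctl[i]),
               delta_r1 = mean(son[i]) - mean(ctl[i]),
               f = st[["f"]], p = st[["p"]])
  }))
  st <- anova_two(son, ctl)
  overall <- data.frame(mean_son = mean(son), mean_ctl = mean(ctl),
                        delta_r1 = mean(son) - mean(ctl),
                        f = st[["f"]], p = st[["p"]])
  structure(list(per_target = per_target, per_group = per_group,
                 overall = overall),
            class = "roi_delta_r1")
}

#' Convert an R1 difference to contrast-agent concentration
#'
#' `C = delta_R1 / r1_relaxivity`, exactly linear.  Negative inputs pass
#' through as negative concentrations (physically meaningless but
#' informative about noise); a `negative` attribute flags them.
#'
#' @param delta_r1 R1 difference, 1/s (vectorised).
#' @param relaxivity Longitudinal relaxivity, 1/s/mM.
#' @return Concentration in mM.
#' @export
gadavist_concentration <- function(delta_r1, relaxivity = 4.44) {
  stopifnot(relaxivity > 0)
  out <- delta_r1 / relaxivity
  attr(out, "negative") <- any(delta_r1 < 0)
  out
}

#' Percent signal enhancement with maximum-intensity projection
#'
#' Contrast enhancement relative to pre-injection imaging: the repeated
#' post-injection acquisitions are reduced voxelwise by maximum-intensity
#' projection inside the brain mask, the percent increase over the
#' pre-injection image is computed, and the result is averaged over each
#' volumetric-sonication ROI union and its mirrored control.
#'
#' @param pre Pre-injection image matrix.
#' @param post List of post-injection matrices (or a 3D array).
#' @param mask Logical brain mask.
#' @param rois Optional [make_roi_masks()] result for per-group averages.
#' @return A list with `map` (percent-enhancement matrix, `NA` outside the
#'   mask and at non-positive pre-signal voxels), `n_excluded`
#'   (non-positive pre-signal voxels inside the mask) and, when `rois` is
#'   given, a `per_group` data frame with sonicated and control means.
#' @export
signal_enhancement <- function(pre, post, mask = NULL, rois = NULL) {
  if (is.array(post) && length(dim(post)) == 3L)
    post <- lapply(seq_len(dim(post)[3L]), function(k) post[, , k])
  stopifnot(is.list(post), length(post) >= 1L)
  for (p in post)
    if (!all(dim(p) == dim(pre)))
      stop("pre and post image geometries differ", call. = FALSE)
  mip <- Reduce(pmax, post)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pre), ncol(pre))
  bad <- mask & pre <= 0
  map <- matrix(NA_real_, nrow(pre), ncol(pre))
  ok <- mask & pre > 0
  map[ok] <- 100 * (mip[ok] - pre[ok]) / pre[ok]
  per_group <- NULL
  if (!is.null(rois)) {
    groups <- names(rois$group)
    per_group <- do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(group_id = as.integer(groups[i]),
                 mean_son = mean(map[rois$group[[i]]], na.rm = TRUE),
                 mean_ctl = mean(map[rois$group_mirror[[i]]], na.rm = TRUE))
    }))
    per_group$delta <- per_group$mean_son - per_group$mean_ctl
  }
  list(map = map, n_excluded = sum(bad), per_group = per_group)
}

#' Predicted spin-echo enhancement for a contrast-agent concentration
#'
#' Expected percent signal change of a spin-echo acquisition when the
#' tissue carries concentration `C` of contrast agent:
#' `S(C) = (1 - exp(-TR (R1_0 + r1 C))) * exp(-TE (R2_0 + r2 C))`,
#' returned as `100 (S(C)/S(0) - 1)`.  With `relaxivity_r2 = 0` (default)
#' the curve is strictly increasing in `C`; with a positive r2 it is
#' non-monotone at high concentration (T2 quenching).
#'
#' @param conc_mM Concentration in mM (vectorised, >= 0).
#' @param sp A [sequence_params()].
#' @return Percent enhancement.
#' @export
predict_se_enhancement <- function(conc_mM, sp = sequence_params()) {
  stopifnot(all(conc_mM >= 0))
  s <- function(C)
    (1 - exp(-sp$tr * (sp$r1_tissue + sp$relaxivity_r1 * C))) *
      exp(-sp$te * (sp$r2_tissue + sp$relaxivity_r2 * C))
  100 * (s(conc_mM) / s(0) - 1)
}
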