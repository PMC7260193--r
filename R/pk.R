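#' Geometric mean and geometric %CV with LLOQ censoring
#'
#' Summary statistics for log-normally distributed drug concentrations:
#' `GM = exp(mean(log x))` and `GCV% = 100 sqrt(exp(s2) - 1)` where `s2` is
#' the sample variance of `log x`, both over uncensored values only.
#' Values below the lower limit of quantitation are excluded and counted
#' (`n_detected / n_total`), never imputed.
#'
#' @param values Concentrations (same units throughout).
#' @param censored Logical vector: `TRUE` for below-LLOQ samples.
#' @return A list with `gm`, `gcv_pct`, `n_detected`, `n_total`.  With no
#'   detected values `gm` and `gcv_pct` are `NA` and `n_detected` is 0;
#'   with a single detected value `gcv_pct` is `NA`.
#' @export
geometric_stats <- function(values, censored = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(censored))
  x <- values[!censored]
  n_total <- length(values)
  if (length(x) == 0L)
    return(list(gm = NA_real_, gcv_pct = NA_real_, n_detected = 0L,
                n_total = n_total))
  if (any(x <= 0))
    stop("uncensored concentrations must be positive", call. = FALSE)
  lx <- log(x)
  gcv <- if (length(x) >= 2L) 100 * sqrt(exp(stats::var(lx)) - 1)
         else NA_real_
  list(gm = exp(mean(lx)), gcv_pct = gcv,
       n_detected = length(x), n_total = n_total)
}

#' Paired two-tailed t-test on log-transformed concentrations
#'
#' Classical paired t-test on `log(sonicated) - log(control)`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom,
#' two-tailed p from the t distribution.  `exp(mean(d))` is the geometric
#' mean of the per-pair ratios, which for fully paired data equals the
#' ratio of the two geometric means.
#'
#' @param sonicated,control Positive concentrations, paired by position
#'   (same animal / sampling site).
#' @return A list with `t`, `df`, `p`, `n`, `ratio` (GM of per-pair
#'   ratios) and `degenerate` (`TRUE` when the log-differences have zero
#'   variance, in which case `t` and `p` are `NA`).
#' @export
paired_log_ttest <- function(sonicated, control) {
  n <- length(sonicated)
  if (length(control) != n)
    stop("sonicated and control must have the same length", call. = FALSE)
  if (n < 2L) stop("at least 2 pairs are required", call. = FALSE)
  if (any(sonicated <= 0) || any(control <= 0))
    stop("concentrations must be positive (censored pairs are excluded ",
         "before testing)", call. = FALSE)
  d <- log(sonicated) - log(control)
  s <- stats::sd(d)
  ratio <- exp(mean(d))
  if (s == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, n = n,
                ratio = ratio, degenerate = TRUE))
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       n = n, ratio = ratio, degenerate = FALSE)
}

#' Sonicated / control concentration ratio
#'
#' Ratio of the two geometric means.  For fully paired designs this equals
#' the geometric mean of the per-animal ratios exactly.
#'
#' @param sonicated_gm,control_gm Geometric means (positive).
#' @return The ratio.
#' @export
hemisphere_ratio <- function(sonicated_gm, control_gm) {
  if (!is.finite(sonicated_gm) || !is.finite(control_gm))
    stop("both geometric means must be defined", call. = FALSE)
  stopifnot(sonicated_gm > 0, control_gm > 0)
  sonicated_gm / control_gm
}

#' Cohort-level concentration summary
#'
#' Aggregates a table of concentration samples (schema of
#' [simulate_pk()]: `animal_id`, `cohort`, `analyte`, `compartment`,
#' `hemisphere`, `conc_nM`, `censored`) into per-cohort, per-analyte rows:
#' plasma GM (GCV%), sonicated and control tissue GM (GCV%) with detection
#' counts, the ratio of tissue GMs, the GM of per-pair ratios (identical
#' for fully paired uncensored data, reported separately to surface
#' incomplete pairing), and the paired log-t p-value over pairs where both
#' members were detected.  When a `site` column is present, pairing is by
#' animal and site.
#'
#' @param samples Concentration table (data frame).
#' @return A data frame with one row per cohort x analyte.
#' @export
pk_cohort_summary <- function(samples) {
  needed <- c("animal_id", "cohort", "analyte", "compartment",
              "hemisphere", "conc_nM", "censored")
  if (!all(needed %in% names(samples)))
    stop("missing columns: ",
         paste(setdiff(needed, names(samples)), collapse = ", "),
         call. = FALSE)
  key <- if ("site" %in% names(samples))
    paste(samples$animal_id, samples$site) else samples$animal_id
  samples$.pair <- key
  do.call(rbind, lapply(split(samples,
                              list(samples$cohort, samples$analyte),
                              drop = TRUE), function(d) {
    pl <- d[d$compartment == "plasma", ]
    fus <- d[d$compartment == "tissue" & d$hemisphere == "sonicated", ]
    ctl <- d[d$compartment == "tissue" & d$hemisphere == "control", ]
    gs_pl <- geometric_stats(pl$conc_nM, pl$censored)
    gs_f <- geometric_stats(fus$conc_nM, fus$censored)
    gs_c <- geometric_stats(ctl$conc_nM, ctl$censored)
    ratio <- if (is.na(gs_f$gm) || is.na(gs_c$gm)) NA_real_
             else hemisphere_ratio(gs_f$gm, gs_c$gm)
    m <- match(fus$.pair, ctl$.pair)
    ok <- !is.na(m) & !fus$censored & !ctl$censored[m]
    gm_ratio <- p <- NA_real_
    if (sum(ok) >= 2L) {
      tt <- paired_log_ttest(fus$conc_nM[ok], ctl$conc_nM[m[ok]])
      gm_ratio <- tt$ratio
      p <- tt$p
    }
    data.frame(cohort = d$cohort[1L], analyte = d$analyte[1L],
               plasma_gm = gs_pl$gm, plasma_gcv = gs_pl$gcv_pct,
               tissue_fus_gm = gs_f$gm, tissue_fus_gcv = gs_f$gcv_pct,
               tissue_ctl_gm = gs_c$gm, tissue_ctl_gcv = gs_c$gcv_pct,
               ratio_of_gms = ratio, gm_of_ratios = gm_ratio, p = p,
               n_detected_fus = gs_f$n_detected, n_total_fus = gs_f$n_total,
               n_detected_ctl = gs_c$n_detected, n_total_ctl = gs_c$n_total,
               row.names = NULL)
  }))
}
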