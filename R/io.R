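#' Read band / threshold configuration
#'
#' Reads a JSON or YAML configuration (by file extension) with keys
#' `fundamental_hz`, `harmonic_halfwidth_hz`, `subharmonic_halfwidth_hz`,
#' `broadband_halfwidth_hz`, `k_sub`, `k_wide` and returns the
#' corresponding [band_set()] plus detection thresholds.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `bands` (a `band_set`), `k_sub`, `k_wide`.
#' @export
read_band_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE))
  needed <- c("fundamental_hz", "harmonic_halfwidth_hz",
              "subharmonic_halfwidth_hz", "broadband_halfwidth_hz",
              "k_sub", "k_wide")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0L)
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  list(bands = band_set(
         fundamental_hz = cfg$fundamental_hz,
         harmonic_halfwidth_hz = cfg$harmonic_halfwidth_hz,
         subharmonic_halfwidth_hz = cfg$subharmonic_halfwidth_hz,
         broadband_halfwidth_hz = cfg$broadband_halfwidth_hz),
       k_sub = cfg$k_sub, k_wide = cfg$k_wide)
}

#' Read / write burst spectra in long-format CSV
#'
#' The long format has one row per (burst, frequency bin) with columns
#' `burst`, `target_id`, `group_id`, `t`, `power`, `freq`, `mag`.
#'
#' @param spectra List of [spectrum_record()] objects.
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a list of `spectrum_record` objects.
#' @export
write_spectra_csv <- function(spectra, path) {
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(burst = i, target_id = s$target_id, group_id = s$group_id,
               t = s$t, power = s$power, freq = s$freq, mag = s$mag)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$burst), function(b)
    spectrum_record(freq = b$freq, mag = b$mag,
                    target_id = b$target_id[1L], group_id = b$group_id[1L],
                    t = b$t[1L], power = b$power[1L]))
}

#' Write a simulated TR series as NIfTI
#'
#' Writes the variable-TR image stack, the ground-truth R1 map and the
#' brain mask as three NIfTI files sharing the phantom geometry (requires
#' the RNifti package).
#'
#' @param series A [simulate_tr_series()] result.
#' @param prefix Output path prefix; files `<prefix>_trseries.nii.gz`,
#'   `<prefix>_r1true.nii.gz`, `<prefix>_mask.nii.gz` are written.
#' @return Invisibly, the vector of written paths.
#' @export
write_tr_series_nifti <- function(series, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to write NIfTI output",
         call. = FALSE)
  g <- series$geom
  pix <- c(g$dx, g$dy, 1)
  paths <- paste0(prefix, c("_trseries", "_r1true", "_mask"), ".nii.gz")
  imgs <- list(series$data, series$r1_true, series$mask * 1)
  for (i in seq_along(imgs)) {
    a <- imgs[[i]]
    if (length(dim(a)) < 3L) dim(a) <- c(dim(a), 1L)
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- pix[seq_len(length(dim(a)))]
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read / write concentration sample tables
#'
#' CSV schema: `animal_id`, `cohort`, `analyte`, `compartment`,
#' `hemisphere`, `conc_nM`, `censored` (see [simulate_pk()]).
#'
#' @param samples Concentration data frame.
#' @param path File path.
#' @return `write_pk_samples` returns `path` invisibly; `read_pk_samples`
#'   returns the validated data frame.
#' @export
write_pk_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pk_samples
#' @export
read_pk_samples <- function(path) {
  d <- utils::read.csv(path)
  needed <- c("animal_id", "cohort", "analyte", "compartment",
              "hemisphere", "conc_nM", "censored")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0L)
    stop("sample table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  d$censored <- as.logical(d$censored)
  d
}

#' Write a session summary as JSON
#'
#' @param summary A [summarize_session()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_session_summary_json <- function(summary, path) {
  jsonlite::write_json(list(overall = summary$overall,
                            by_group = summary$by_group),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
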