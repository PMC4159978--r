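#' Region-of-interest summary statistics of a parameter map
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation CoV = sd/mean over the valid, finite voxels selected by the
#' mask. The CoV is the field's standard noise/artifact severity metric for
#' quantitative maps; it is only meaningful over a region of homogeneous
#' tissue, which the synthetic ROIs guarantee by construction.
#'
#' @param map 3D numeric map (e.g. R2* in s^-1); `NA` voxels are ignored.
#' @param roi_mask 3D logical mask selecting at least 2 valid voxels.
#' @return A list of class `roi_stats`: `n_voxels`, `mean`, `sd`, `cov`.
#'   If the ROI mean is not positive the CoV is `NaN` with a warning.
#' @examples
#' m <- array(c(8, 10, 12, NA), dim = c(4, 1, 1))
#' roi_stats(m, array(TRUE, dim = c(4, 1, 1)))
#' @export
roi_stats <- function(map, roi_mask) {
  stopifnot(is.array(map), length(dim(map)) == 3L,
            all(dim(roi_mask) == dim(map)))
  vals <- map[as.logical(roi_mask)]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L)
    stop("ROI must contain at least 2 valid voxels", call. = FALSE)
  m <- mean(vals)
  s <- stats::sd(vals)
  cov <- if (m > 0) s / m else {
    warning("ROI mean is not positive; CoV undefined", call. = FALSE)
    NaN
  }
  structure(list(n_voxels = length(vals), mean = m, sd = s, cov = cov),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> n=%d mean=%.4g sd=%.4g cov=%.4g\n",
              x$n_voxels, x$mean, x$sd, x$cov))
  invisible(x)
}

#' Percent deviation of one map's ROI mean from a reference
#'
#' `100 * (mean_ROI(a) - mean_ROI(b)) / mean_ROI(b)`: the bias metric used
#' to compare alternative R2* estimators against the conventional
#' single-contrast (PDw) estimate.
#'
#' @param map_a,map_b 3D maps (b is the reference).
#' @param roi_mask 3D logical ROI.
#' @return Percent deviation (scalar).
#' @export
percent_deviation <- function(map_a, map_b, roi_mask) {
  roi_mean <- function(m) {
    v <- m[as.logical(roi_mask)]
    v <- v[is.finite(v)]
    if (length(v) < 2L) stop("ROI must contain at least 2 valid voxels",
                             call. = FALSE)
    mean(v)
  }
  ma <- roi_mean(map_a)
  mb <- roi_mean(map_b)
  if (!is.finite(mb) || mb <= 0)
    stop("reference ROI mean must be positive", call. = FALSE)
  100 * (ma - mb) / mb
}

#' Percent reduction in coefficient of variation
#'
#' `100 * (cov_reference - cov_method) / cov_reference`; positive when the
#' method is less variable than the reference, negative when worse (both
#' are reported as-is).
#'
#' @param cov_method,cov_reference Dimensionless CoV values;
#'   `cov_reference > 0`.
#' @return Percent reduction (scalar).
#' @export
cov_reduction <- function(cov_method, cov_reference) {
  stopifnot(cov_reference > 0)
  100 * (cov_reference - cov_method) / cov_reference
}

#' A rigid-body motion trace
#'
#' Timestamped translations (mm) and rotations (degrees: pitch, roll, yaw),
#' as recorded by an optical tracking camera.
#'
#' @param timestamps Strictly increasing sample times in seconds.
#' @param translations n x 3 matrix (x, y, z) in mm.
#' @param rotations n x 3 matrix (pitch, roll, yaw) in degrees.
#' @return A list of class `motion_trace`.
#' @export
motion_trace <- function(timestamps, translations, rotations) {
  timestamps <- as.numeric(timestamps)
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  n <- length(timestamps)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (nrow(translations) != n || nrow(rotations) != n ||
      ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must be n x 3 with n = length(timestamps)",
         call. = FALSE)
  structure(list(timestamps = timestamps, translations = translations,
                 rotations = rotations), class = "motion_trace")
}

#' Read a motion trace from CSV
#'
#' Expects columns `t, tx, ty, tz, pitch, roll, yaw` (seconds, mm, degrees).
#' @param path CSV file path.
#' @return A [motion_trace].
#' @export
read_motion_trace <- function(path) {
  d <- utils::read.csv(path)
  needed <- c("t", "tx", "ty", "tz", "pitch", "roll", "yaw")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("motion CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  motion_trace(d$t, as.matrix(d[c("tx", "ty", "tz")]),
               as.matrix(d[c("pitch", "roll", "yaw")]))
}

#' Scalar motion-speed summary of a tracking trace
#'
#' Numerically differentiates each of the six rigid-body channels, expresses
#' the rates per repetition time, and combines them per sample as the square
#' root of the sum of the six squared rates. The result deliberately mixes
#' units (mm and degrees per TR) — it is a summary severity index, not a
#' physical speed, and is documented as such.
#'
#' @param trace A [motion_trace].
#' @param tr_ms Repetition time in ms used to scale the rates.
#' @return Numeric vector of length `n - 1`: speed per inter-sample interval.
#' @export
motion_speed <- function(trace, tr_ms) {
  stopifnot(inherits(trace, "motion_trace"), tr_ms > 0)
  dt <- diff(trace$timestamps)
  channels <- cbind(trace$translations, trace$rotations)
  rates <- apply(channels, 2L, diff) / dt * (tr_ms / 1000)
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1L)
  sqrt(rowSums(rates^2))
}

#' Run all six estimation modes over a simulated cohort
#'
#' For each subject, fits the single-contrast OLS estimator for every
#' contrast, the joint OLS estimator, and both robust variants; summarizes
#' each R2* map over an ROI eroded from a ground-truth tissue region; and
#' tabulates ROI statistics, the CoV reduction relative to the
#' single-contrast fit of `reference_contrast`, and the RMSE against the
#' ground-truth R2*. Individual fit failures are recorded (`NA` row) and
#' the run continues.
#'
#' @param cohort List of `list(dataset, truth)` as from [simulate_cohort].
#' @param roi_label Tissue-class label defining the ROI (default `"WM"`).
#' @param erode_iterations Erosion passes applied to the tissue region.
#' @param reference_contrast Label of the single-contrast reference fit
#'   (default `"PDw"`).
#' @param schemes Named list with entries `robust` and `robust_high_snr`
#'   giving the [weight_scheme] for each robust variant.
#' @return A `data.frame` with one row per (subject, method): columns
#'   `subject`, `method`, `n_voxels`, `mean`, `sd`, `cov`,
#'   `cov_reduction_vs_ref`, `rmse_vs_truth`. Where the reference CoV is
#'   below 1e-12 (degenerate noiseless case) the reduction is reported as 0.
#' @export
compare_methods <- function(cohort, roi_label = "WM", erode_iterations = 2L,
                            reference_contrast = "PDw",
                            schemes = list(
                              robust = weight_scheme("factorized"),
                              robust_high_snr = weight_scheme("voxelwise_high_snr"))) {
  stopifnot(length(cohort) >= 1L)
  rows <- list()
  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    labels <- dataset_labels(subj$dataset)
    code <- match(roi_label, subj$truth$classes$label)
    if (is.na(code)) stop("unknown ROI tissue label: ", roi_label, call. = FALSE)
    roi <- erode_mask(subj$truth$labels == code, erode_iterations)
    if (sum(roi) < 2L) stop("eroded ROI is empty; reduce erode_iterations",
                            call. = FALSE)
    fits <- list()
    for (lab in labels)
      fits[[paste0("ols_", lab)]] <- try(fit_ols(subj$dataset, subset = lab),
                                         silent = TRUE)
    fits[["ols_joint"]] <- try(fit_ols(subj$dataset), silent = TRUE)
    fits[["robust"]] <- try(fit_robust(subj$dataset, schemes$robust),
                            silent = TRUE)
    fits[["robust_high_snr"]] <- try(fit_robust(subj$dataset,
                                                schemes$robust_high_snr),
                                     silent = TRUE)
    ref_name <- paste0("ols_", reference_contrast)
    ref_cov <- if (!inherits(fits[[ref_name]], "try-error"))
      roi_stats(fits[[ref_name]]$r2s, roi)$cov else NA_real_
    for (meth in names(fits)) {
      f <- fits[[meth]]
      if (inherits(f, "try-error")) {
        warning(sprintf("subject %d, method %s: fit failed (%s)",
                        s, meth, conditionMessage(attr(f, "condition"))),
                call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, method = meth, n_voxels = NA_integer_,
          mean = NA_real_, sd = NA_real_, cov = NA_real_,
          cov_reduction_vs_ref = NA_real_, rmse_vs_truth = NA_real_)
        next
      }
      st <- roi_stats(f$r2s, roi)
      err <- f$r2s[roi] - subj$truth$r2s[roi]
      red <- if (is.na(ref_cov)) NA_real_
      else if (ref_cov < 1e-12) 0
      else cov_reduction(st$cov, ref_cov)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, method = meth, n_voxels = st$n_voxels,
        mean = st$mean, sd = st$sd, cov = st$cov,
        cov_reduction_vs_ref = red,
        rmse_vs_truth = sqrt(mean(err^2, na.rm = TRUE)))
    }
  }
  do.call(rbind, rows)
}
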