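#' Specification of a synthetic multi-contrast phantom
#'
#' Describes a digital brain-like object used to validate the fits: nested
#' ellipsoidal tissue regions with class-specific R2* and per-contrast
#' intensities, the acquisition's echo-time grid, and a magnitude-noise
#' model. The defaults emulate a three-contrast (PDw/T1w/MTw) multi-echo
#' FLASH protocol: 6 equidistant echoes from 2.2 to 14.7 ms for T1w and MTw,
#' 8 from 2.2 to 19.7 ms for PDw, one shared R2* per voxel across contrasts,
#' and white-matter-like, gray-matter-like and CSF-like classes with R2* of
#' 21, 15 and 1 s^-1 respectively. The default noise level puts the
#' white-matter PDw signal at SNR 50 at TE = 0.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param tissue_classes `data.frame` with columns `label`, `r2s` (s^-1) and
#'   one `i0_<contrast>` column per contrast label (intensities at TE = 0).
#' @param geometry List of regions painted in order (later regions overwrite
#'   earlier ones where they overlap — "last wins"); each region is a list
#'   with `label`, `center` and `semi_axes`, both length-3 in fractions of
#'   the grid.
#' @param contrast_labels Character vector of contrast names.
#' @param echo_times Named list: echo-time vector (ms) per contrast.
#' @param noise_sd Magnitude-noise standard deviation in intensity units
#'   (for `"log_gaussian"`: the dimensionless sd of the log signal).
#' @param noise_model `"rician"` (default; magnitude of complex Gaussian
#'   noise, the physical model for magnitude MRI), `"gaussian"` (additive,
#'   for analytic checks) or `"log_gaussian"` (multiplicative log-normal,
#'   matching the log-domain fit assumptions exactly).
#' @param seed Integer seed for the noise draw.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         tissue_classes = default_tissue_classes(),
                         geometry = default_geometry(),
                         contrast_labels = c("PDw", "T1w", "MTw"),
                         echo_times = default_echo_times(),
                         noise_sd = 20, noise_model = c("rician", "gaussian",
                                                        "log_gaussian"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            is.data.frame(tissue_classes), noise_sd >= 0)
  needed <- c("label", "r2s", paste0("i0_", contrast_labels))
  missing <- setdiff(needed, names(tissue_classes))
  if (length(missing))
    stop("tissue_classes lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tissue_classes$r2s <= 0) ||
      any(as.matrix(tissue_classes[paste0("i0_", contrast_labels)]) <= 0))
    stop("all tissue R2* and i0 values must be positive", call. = FALSE)
  stopifnot(setequal(names(echo_times), contrast_labels))
  for (lab in contrast_labels) {
    te <- echo_times[[lab]]
    if (length(te) < 2L || any(te <= 0) || any(diff(te) <= 0))
      stop("invalid echo times for contrast ", lab, call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, tissue_classes = tissue_classes,
                 geometry = geometry, contrast_labels = contrast_labels,
                 echo_times = echo_times, noise_sd = noise_sd,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_classes <- function() {
  data.frame(label = c("WM", "GM", "CSF"),
             r2s = c(21, 15, 1),
             i0_PDw = c(1000, 1100, 1300),
             i0_T1w = c(1000, 750, 350),
             i0_MTw = c(600, 750, 1100),
             stringsAsFactors = FALSE)
}

#' @rdname phantom_spec
#' @export
default_geometry <- function() {
  list(list(label = "GM", center = c(0.5, 0.5, 0.5),
            semi_axes = c(0.42, 0.36, 0.33)),
       list(label = "WM", center = c(0.5, 0.5, 0.5),
            semi_axes = c(0.30, 0.24, 0.21)),
       list(label = "CSF", center = c(0.5, 0.5, 0.5),
            semi_axes = c(0.09, 0.07, 0.06)))
}

#' @rdname phantom_spec
#' @export
default_echo_times <- function() {
  list(PDw = seq(2.2, 19.7, by = 2.5),
       T1w = seq(2.2, 14.7, by = 2.5),
       MTw = seq(2.2, 14.7, by = 2.5))
}

paint_labels <- function(spec) {
  g <- spec$grid_shape
  labels <- array(0L, dim = g)
  ax <- list(seq_len(g[1]), seq_len(g[2]), seq_len(g[3]))
  codes <- seq_len(nrow(spec$tissue_classes))
  names(codes) <- spec$tissue_classes$label
  for (region in spec$geometry) {
    cen <- region$center * g
    sa <- region$semi_axes * g
    d1 <- ((ax[[1]] - cen[1]) / sa[1])^2
    d2 <- ((ax[[2]] - cen[2]) / sa[2])^2
    d3 <- ((ax[[3]] - cen[3]) / sa[3])^2
    inside <- outer(outer(d1, d2, `+`), d3, `+`) <= 1
    labels[inside] <- codes[[region$label]]
  }
  labels
}

add_noise <- function(signal, noise_sd, noise_model) {
  if (noise_sd == 0) return(signal)
  n <- length(signal)
  switch(noise_model,
    rician = sqrt((signal + rnorm(n, sd = noise_sd))^2 +
                  rnorm(n, sd = noise_sd)^2),
    gaussian = signal + rnorm(n, sd = noise_sd),
    log_gaussian = signal * exp(rnorm(n, sd = noise_sd)))
}

#' Generate a synthetic multi-contrast dataset with ground truth
#'
#' Evaluates the mono-exponential forward model ([predict_signal]) on the
#' phantom geometry for every contrast and echo, then adds magnitude noise
#' per the spec's noise model and seed. With `noise_sd = 0` the output is
#' the noiseless forward model exactly. Background voxels (outside every
#' region) have zero noiseless signal; under Rician noise they show the
#' familiar Rayleigh floor. The returned dataset's mask is the tissue
#' support (background excluded), so fits and pooled robust scales are
#' computed over object voxels as they would be over a brain mask.
#'
#' @param spec A [phantom_spec].
#' @return A list with `dataset` (an [estatics_dataset], mask = tissue
#'   support) and `truth`: `r2s` (3D, s^-1), `i0` (named list of 3D maps per
#'   contrast), `labels` (3D integer; 0 = background) and `classes` (the
#'   tissue table, row i coding label i).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- paint_labels(spec)
  g <- spec$grid_shape
  r2s_truth <- array(0, dim = g)
  idx <- labels > 0L
  r2s_truth[idx] <- spec$tissue_classes$r2s[labels[idx]]
  i0_truth <- list()
  contrasts <- list()
  with_seed(spec$seed, {
    for (lab in spec$contrast_labels) {
      i0 <- array(0, dim = g)
      i0[idx] <- spec$tissue_classes[[paste0("i0_", lab)]][labels[idx]]
      i0_truth[[lab]] <- i0
      te <- spec$echo_times[[lab]]
      sig <- array(0, dim = c(g, length(te)))
      for (e in seq_along(te))
        sig[, , , e] <- i0 * exp(-(r2s_truth / 1000) * te[e])
      sig[] <- add_noise(sig, spec$noise_sd, spec$noise_model)
      contrasts[[lab]] <- multi_echo_contrast(lab, pmax(sig, 0), te)
    }
  })
  list(dataset = estatics_dataset(contrasts, mask = idx),
       truth = list(r2s = r2s_truth, i0 = i0_truth, labels = labels,
                    classes = spec$tissue_classes))
}

#' Specification of k-space motion corruption
#'
#' Intra-scan head motion in Cartesian FLASH imaging perturbs the phase of
#' individual phase-encode lines, which reconstructs as ghosting/ringing in
#' the magnitude image. This generator emulates that phenotype: for selected
#' echo volumes of one contrast, a random subset of phase-encode lines is
#' multiplied in k-space by `exp(i * phi)` with `phi` uniform in
#' `[-max_phase_error_rad, max_phase_error_rad]`. It is a translation-like
#' stand-in for real motion trajectories (rotations, which bend the k-space
#' trajectory, are not modeled), sufficient to produce the ringing artifacts
#' a robust fit must reject.
#'
#' The default targets the three longest PDw echoes — the echoes that
#' dominate R2* estimation and are the most motion sensitive — corrupting
#' 15% of lines with phase errors up to pi. The central `center_exclude`
#' lines of k-space are never corrupted so the gross mean intensity is
#' preserved and the artifact is pure ringing/ghosting.
#'
#' @param target_contrast Label of the contrast to corrupt.
#' @param target_echoes Integer echo indices to corrupt.
#' @param line_fraction Fraction of phase-encode lines corrupted, in `[0, 1]`.
#' @param max_phase_error_rad Upper bound of the per-line phase offset (rad).
#' @param corruption_axis Image axis interpreted as phase encode (default 2).
#' @param center_exclude Number of central k-space lines never corrupted.
#' @param seed Integer seed for line selection and phases.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(target_contrast = "PDw", target_echoes = 6:8,
                            line_fraction = 0.15, max_phase_error_rad = pi,
                            corruption_axis = 2L, center_exclude = 4L,
                            seed = 1L) {
  stopifnot(line_fraction >= 0, line_fraction <= 1, max_phase_error_rad >= 0,
            corruption_axis %in% 1:3, center_exclude >= 0)
  structure(list(target_contrast = target_contrast,
                 target_echoes = as.integer(target_echoes),
                 line_fraction = line_fraction,
                 max_phase_error_rad = max_phase_error_rad,
                 corruption_axis = as.integer(corruption_axis),
                 center_exclude = as.integer(center_exclude),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

# Apply per-line phase errors along `axis` of one 3D volume. Only a 1D FFT
# along the phase-encode axis is needed: the phase is constant along the
# other k-space axes, so their transforms cancel.
corrupt_volume <- function(vol, axis, lines, phases) {
  g <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  d <- dim(v)
  dim(v) <- c(d[1], d[2] * d[3])
  ksp <- stats::mvfft(v)
  ksp[lines, ] <- ksp[lines, , drop = FALSE] * exp(1i * phases)
  out <- Mod(stats::mvfft(ksp, inverse = TRUE)) / d[1]
  dim(out) <- d
  aperm(out, order(perm))
}

#' Inject k-space phase-error corruption into one contrast
#'
#' For each target echo volume independently, draws a set of phase-encode
#' lines and per-line phase offsets (line selection is identical across
#' planes of one echo, mimicking rigid-motion consistency within a readout),
#' applies them in k-space, and returns the magnitude image. Non-target
#' echoes are untouched; `line_fraction = 0` or `max_phase_error_rad = 0`
#' returns the input unchanged.
#'
#' @param contrast A [multi_echo_contrast].
#' @param spec A [corruption_spec] whose `target_contrast` matches the
#'   contrast's label.
#' @return A [multi_echo_contrast] with corrupted target echoes.
#' @export
corrupt_kspace <- function(contrast, spec) {
  stopifnot(inherits(contrast, "multi_echo_contrast"),
            inherits(spec, "corruption_spec"))
  if (!identical(contrast$label, spec$target_contrast))
    stop(sprintf("corruption targets '%s' but contrast is '%s'",
                 spec$target_contrast, contrast$label), call. = FALSE)
  ne <- dim(contrast$signal)[4L]
  bad <- setdiff(spec$target_echoes, seq_len(ne))
  if (length(bad))
    stop("target echo index out of range: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (spec$line_fraction == 0 || spec$max_phase_error_rad == 0)
    return(contrast)
  n_lines <- dim(contrast$signal)[spec$corruption_axis]
  # DFT frequency of each line index; the central lines hold the bulk of
  # the image energy and are excluded from corruption
  freq <- c(0:(n_lines %/% 2), -((n_lines - n_lines %/% 2 - 1):1))[seq_len(n_lines)]
  eligible <- order(abs(freq))[-seq_len(min(spec$center_exclude, n_lines))]
  n_corrupt <- min(round(spec$line_fraction * n_lines), length(eligible))
  sig <- contrast$signal
  with_seed(spec$seed, {
    for (e in spec$target_echoes) {
      lines <- sample(eligible, n_corrupt)
      phases <- runif(n_corrupt, -spec$max_phase_error_rad,
                      spec$max_phase_error_rad)
      sig[, , , e] <- corrupt_volume(sig[, , , e], spec$corruption_axis,
                                     lines, phases)
    }
  })
  multi_echo_contrast(contrast$label, sig, contrast$echo_times)
}

#' Simulate a cohort of phantom datasets
#'
#' Generates `n_subjects` independent phantom realizations: per-subject
#' seeds are derived deterministically from `base_seed`, each subject's
#' tissue R2* values are jittered by up to `r2s_jitter` (relative, uniform)
#' to mimic inter-subject variation, noise is redrawn, and the optional
#' k-space corruption is applied with a per-subject seed.
#'
#' @param n_subjects Number of datasets (>= 1).
#' @param spec A [phantom_spec] (its `seed` is overridden per subject).
#' @param corruption Optional [corruption_spec] applied to every subject.
#' @param base_seed Integer base seed.
#' @param r2s_jitter Relative half-width of the per-subject R2* jitter
#'   (default 0.05, i.e. +/-5%).
#' @return List of length `n_subjects`; each element is the
#'   `list(dataset, truth)` returned by [make_phantom].
#' @export
simulate_cohort <- function(n_subjects, spec = phantom_spec(),
                            corruption = NULL, base_seed = 1L,
                            r2s_jitter = 0.05) {
  stopifnot(n_subjects >= 1L, inherits(spec, "phantom_spec"))
  lapply(seq_len(n_subjects), function(i) {
    seed_i <- (as.integer(base_seed) + 7919L * i) %% 2147483647L
    spec_i <- spec
    if (r2s_jitter > 0)
      spec_i$tissue_classes$r2s <- with_seed(seed_i, {
        spec$tissue_classes$r2s *
          (1 + runif(nrow(spec$tissue_classes), -r2s_jitter, r2s_jitter))
      })
    spec_i$seed <- (seed_i + 1L) %% 2147483647L
    subj <- make_phantom(spec_i)
    if (!is.null(corruption)) {
      corr_i <- corruption
      corr_i$seed <- (seed_i + 2L) %% 2147483647L
      lab <- corr_i$target_contrast
      subj$dataset$contrasts[[lab]] <-
        corrupt_kspace(subj$dataset$contrasts[[lab]], corr_i)
    }
    subj
  })
}

#' Erode a binary mask
#'
#' Iterative 6-connectivity erosion, used to shrink ground-truth tissue
#' regions into conservative ROIs free of boundary partial-volume voxels.
#'
#' @param mask 3D logical array.
#' @param iterations Number of single-voxel erosion passes.
#' @return Eroded 3D logical array.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  m <- array(as.logical(mask), dim = dim(mask))
  g <- dim(m)
  for (it in seq_len(iterations)) {
    out <- m
    shift <- function(arr, axis, by) {
      idx <- list(seq_len(g[1]), seq_len(g[2]), seq_len(g[3]))
      src <- idx[[axis]] + by
      pad <- src < 1 | src > g[axis]
      src[pad] <- 1L
      idx[[axis]] <- src
      res <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      # out-of-range neighbours count as background
      bidx <- list(seq_len(g[1]), seq_len(g[2]), seq_len(g[3]))
      bidx[[axis]] <- which(pad)
      if (any(pad)) res[bidx[[1]], bidx[[2]], bidx[[3]]] <- FALSE
      res
    }
    for (axis in 1:3) for (by in c(-1L, 1L))
      out <- out & shift(m, axis, by)
    m <- out
  }
  m
}
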