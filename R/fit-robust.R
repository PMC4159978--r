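#' Configuration of a robust (IRLS) ESTATICS fit
#'
#' Two published flavours of outlier down-weighting are supported:
#' \describe{
#'   \item{`"voxelwise_high_snr"`}{purely voxel-wise weights with a wide
#'     confidence interval (default 5 robust standard deviations). Keeps
#'     more data, hence higher SNR, but is less aggressive on artifacts.}
#'   \item{`"factorized"`}{the voxel-wise weights are multiplied by a
#'     line-wise and a plane-wise varying component (means of the voxel
#'     weights along k-space-related image axes), with a tighter confidence
#'     interval (default 3 robust standard deviations). Motion artifacts
#'     are line/plane structured in Cartesian imaging, so spatially pooled
#'     components reject whole corrupted readout lines or partitions.}
#' }
#'
#' @param variant `"factorized"` or `"voxelwise_high_snr"`.
#' @param tuning_constant Half-width of the confidence interval in units of
#'   the robust residual scale; residuals beyond it get weight 0. Defaults:
#'   3 (factorized) and 5 (high SNR).
#' @param max_iterations Maximum IRLS iterations.
#' @param tolerance Relative change in the R2* map below which the loop stops.
#' @param line_axis Image axis along which line components are formed
#'   (default 2, the phase-encode direction under this package's (x, y, z)
#'   convention).
#' @param plane_axis Axis indexing planes for the plane component (default 3,
#'   the partition direction). Must differ from `line_axis`.
#' @return A list of class `weight_scheme`.
#' @export
weight_scheme <- function(variant = c("factorized", "voxelwise_high_snr"),
                          tuning_constant = NULL, max_iterations = 10L,
                          tolerance = 1e-4, line_axis = 2L, plane_axis = 3L) {
  variant <- match.arg(variant)
  if (is.null(tuning_constant))
    tuning_constant <- if (variant == "factorized") 3 else 5
  stopifnot(tuning_constant > 0, max_iterations >= 1L, tolerance > 0,
            line_axis %in% 1:3, plane_axis %in% 1:3)
  if (line_axis == plane_axis)
    stop("line_axis and plane_axis must differ", call. = FALSE)
  structure(list(variant = variant, tuning_constant = tuning_constant,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, line_axis = as.integer(line_axis),
                 plane_axis = as.integer(plane_axis)),
            class = "weight_scheme")
}

#' Robust scale of a residual distribution
#'
#' Normal-consistent median absolute deviation,
#' \eqn{\hat\sigma = 1.4826 \cdot \mathrm{median}(|r - \mathrm{median}(r)|)}.
#' Used to calibrate the confidence interval of the outlier rejection from
#' the residuals of the model fit; the MAD stays valid with up to half the
#' points corrupted.
#'
#' @param residuals Numeric vector (at least 4 values, not all identical).
#' @return Positive scalar scale estimate, or `0` (a degenerate-scale signal
#'   to the caller, meaning "outlier free") when all residuals coincide.
#' @export
estimate_noise_scale <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 4L)
    stop("need at least 4 finite residuals to estimate a scale", call. = FALSE)
  stats::mad(residuals)   # constant = 1.4826 (normal consistency), default
}

#' Tukey-bisquare outlier weight
#'
#' \eqn{w(u) = (1 - u^2)^2} for \eqn{|u| < 1}, else 0, with
#' \eqn{u = r / (c\,\hat\sigma)} the residual scaled by the confidence
#' interval. Continuous, even, maximal (1) at zero, and — unlike soft
#' down-weighters — fully rejecting beyond the interval, matching the
#' treatment of corrupted echoes as outliers rather than noise.
#'
#' @param scaled_residual Residual divided by `tuning_constant * scale`.
#' @return Weight(s) in `[0, 1]`, same shape as the input.
#' @export
weight_function <- function(scaled_residual) {
  u2 <- scaled_residual^2
  ifelse(u2 < 1, (1 - u2)^2, 0)
}

broadcast_over <- function(values, grid, keep_axes) {
  # values has dim grid[keep_axes]; replicate along the remaining axes
  full <- array(NA_real_, dim = grid)
  perm <- c(keep_axes, setdiff(1:3, keep_axes))
  rep_arr <- array(values, dim = grid[perm])
  aperm(rep_arr, order(perm))
}

#' Factorize voxel weights into voxel-, line- and plane-wise components
#'
#' Multiplies each voxel's weight by the mean weight of its line (along
#' `line_axis`) and the mean weight of its plane (perpendicular to
#' `plane_axis`): \eqn{w = w_{vox} \cdot \bar w_{line} \cdot \bar w_{plane}}.
#' A readout line or partition plane in which most voxels look like outliers
#' is thereby rejected wholesale, mirroring the geometry of Cartesian
#' k-space corruption. `NA` voxels (invalid fits) are ignored in the means
#' and stay `NA` in the output; all-ones input returns all ones.
#'
#' @param voxel_weights 3D weight array in `[0, 1]` for one echo volume, or
#'   a 4D array (echoes in dimension 4) processed volume-by-volume.
#' @param scheme A [weight_scheme]; only `line_axis`/`plane_axis` are used.
#' @return Array of the same shape, values in `[0, 1]`.
#' @export
factorize_weights <- function(voxel_weights, scheme = weight_scheme()) {
  nd <- length(dim(voxel_weights))
  if (nd == 4L) {
    out <- voxel_weights
    for (e in seq_len(dim(voxel_weights)[4L]))
      out[, , , e] <- factorize_weights(voxel_weights[, , , e], scheme)
    return(out)
  }
  if (nd != 3L)
    stop("'voxel_weights' must be a 3D or 4D array", call. = FALSE)
  grid <- dim(voxel_weights)
  la <- scheme$line_axis; pa <- scheme$plane_axis

  other <- setdiff(1:3, la)
  line_means <- apply(voxel_weights, other, mean, na.rm = TRUE)
  line_means[!is.finite(line_means)] <- 1   # lines with no valid voxel
  w_line <- broadcast_over(line_means, grid, other)

  plane_means <- apply(voxel_weights, pa, mean, na.rm = TRUE)
  plane_means[!is.finite(plane_means)] <- 1
  w_plane <- broadcast_over(plane_means, grid, pa)

  voxel_weights * w_line * w_plane
}

#' Robust iteratively-reweighted ESTATICS fit
#'
#' Joint multi-contrast R2* estimation with outlier rejection. The IRLS loop:
#' \enumerate{
#'   \item initial weighted OLS with amplitude weights \eqn{a = I^2}
#'     (the first-order variance-stabilizing weight that corrects the
#'     distortion of the residual distribution caused by fitting the
#'     logarithm of the signal — low-signal late echoes have inflated log
#'     noise);
#'   \item log-domain residuals per data point, standardized by the current
#'     predicted signal amplitude: \eqn{\tilde r = r \cdot \hat I}. To first
#'     order \eqn{\tilde r} is the intensity-domain residual, whose thermal
#'     noise is homoscedastic across echoes, contrasts and tissues — the
#'     same distortion correction as the amplitude weights, applied to the
#'     residuals;
#'   \item one global robust scale pooled over all data points and masked
#'     voxels ([estimate_noise_scale]). Pooling globally keeps the scale
#'     anchored by the uncorrupted majority of echo volumes even when an
#'     artifact contaminates an entire volume (a per-volume scale would be
#'     inflated by exactly the corruption it is meant to detect);
#'   \item outlier weights from [weight_function] with the scheme's
#'     confidence interval;
#'   \item for the factorized variant, [factorize_weights];
#'   \item refit with total weight = amplitude weight x outlier weight
#'     (amplitude weights from the current predicted signal), until the R2*
#'     map changes by less than `tolerance` (relative) or `max_iterations`
#'     is reached.
#' }
#' Voxels where fewer than `k_max + 1` points retain positive weight are
#' marked invalid; non-convergence returns the last iterate with a warning
#' diagnostic. The fit is fully deterministic.
#'
#' @param dataset An [estatics_dataset].
#' @param scheme A [weight_scheme].
#' @param subset Optional contrast labels (default: all).
#' @return A `fit_result`; `method` is `"robust"` (factorized) or
#'   `"robust_high_snr"`, and `weights` holds the final per-point outlier
#'   weights as one 4D array per contrast.
#' @export
fit_robust <- function(dataset, scheme = weight_scheme(), subset = NULL) {
  stopifnot(inherits(scheme, "weight_scheme"))
  asm <- assemble_system(dataset, subset)
  if (!any(asm$valid))
    stop("no usable voxels: empty mask or non-positive signal everywhere",
         call. = FALSE)
  X <- asm$design$design
  p <- ncol(X)
  sig <- asm$signal[, asm$valid, drop = FALSE]
  Y <- log(sig)
  grid <- asm$grid
  n_pts <- nrow(Y)

  # (1) initial fit, amplitude weights from the observed signal
  w_amp <- sig^2
  w_amp <- sweep(w_amp, 2L, apply(w_amp, 2L, max), "/")
  sol <- batch_wls(X, Y, w_amp)
  coef <- sol$coef
  w_out <- matrix(1, n_pts, ncol(Y))
  converged <- FALSE
  iter <- 0L
  contrast_rows <- lapply(asm$design$labels, function(lab)
    which(asm$design$row_index$contrast == lab))
  # degenerate-scale cutoff relative to the data scale: residuals that are
  # pure floating-point noise must not be mistaken for a noise level
  deg_tol <- 1e-10 * stats::median(sig[is.finite(sig) & sig > 0])
  for (iter in seq_len(scheme$max_iterations)) {
    fitted <- X %*% coef
    res <- Y - fitted
    # (2) amplitude-standardized residuals: ~ intensity-domain residuals,
    # homoscedastic under uniform thermal noise
    res_std <- res * exp(fitted)
    # (3) one global robust scale pooled over all points and voxels
    pooled <- res_std[is.finite(res_std)]
    sigma <- if (length(pooled) >= 4L) estimate_noise_scale(pooled) else 0
    # (4) outlier weights; degenerate scale => data treated outlier-free
    if (sigma > deg_tol) {
      u <- res_std / (scheme$tuning_constant * sigma)
      w_out <- weight_function(u)
      w_out[!is.finite(w_out)] <- 0
    } else {
      w_out <- matrix(1, n_pts, ncol(Y))
      u <- NULL
    }
    # (5) line/plane factorization, volume by volume
    if (scheme$variant == "factorized" && sigma > deg_tol) {
      for (r_i in seq_len(n_pts)) {
        vol <- to_map(w_out[r_i, ], asm$valid, grid)
        fac <- factorize_weights(vol, scheme)
        w_out[r_i, ] <- fac[asm$valid]
      }
    }
    # identifiability floor: if every point of one contrast is rejected at
    # a voxel, its intercept column would be zero and the solve singular.
    # Keep that contrast's least-outlying point alive with a token weight
    # so the intercept stays estimable and clean echoes can be re-admitted
    # once the fit has shaken off the contamination.
    if (!is.null(u)) {
      for (rows_k in contrast_rows) {
        wk <- w_out[rows_k, , drop = FALSE]
        dead <- which(apply(wk, 2L, max) <= 0)
        if (length(dead)) {
          au <- abs(u[rows_k, dead, drop = FALSE])
          pick <- rows_k[apply(au, 2L, which.min)]
          w_out[cbind(pick, dead)] <- 1e-3
        }
      }
    }
    # (6) refit; amplitude weights now follow the predicted signal
    w_amp <- exp(2 * fitted)
    w_amp <- sweep(w_amp, 2L, apply(w_amp, 2L, max), "/")
    sol <- batch_wls(X, Y, w_amp * w_out)
    new_coef <- sol$coef
    fail <- !as.vector(sol$ok)
    # a transiently unsolvable voxel keeps its previous iterate so its
    # residuals remain computable (it may recover; final validity is
    # decided by the last solve)
    if (any(fail)) new_coef[, fail] <- coef[, fail]
    delta <- abs(new_coef[p, ] - coef[p, ]) / (abs(coef[p, ]) + 1e-8)
    coef <- new_coef
    # median rather than max: with hard rejection a few voxels sit on the
    # weight boundary and oscillate indefinitely
    delta <- delta[is.finite(delta)]
    if (!length(delta) || stats::median(delta) < scheme$tolerance) {
      converged <- TRUE
      break
    }
  }
  ok <- as.vector(sol$ok) & colSums(w_out > 0) >= p
  method <- if (scheme$variant == "factorized") "robust" else "robust_high_snr"
  result <- build_result(coef, as.vector(sol$rss), ok, asm, method,
                         weights = w_out, n_iter = iter)
  # Non-convergence is recorded, not raised: the last iterate is returned
  # and the flag travels with the result (and into provenance).
  result$diagnostics$converged <- converged
  result
}
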