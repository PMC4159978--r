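#' One contrast weighting's multi-echo image series
#'
#' Bundles the 3D magnitude volumes acquired at increasing echo times for a
#' single basic contrast (e.g. PD-, T1- or MT-weighted FLASH) together with
#' the echo times themselves. This is the elementary unit of the joint R2*
#' fit: the decay of the signal across the fourth (echo) dimension carries
#' the R2* information, while the overall scale carries the contrast-specific
#' intercept \eqn{I_k(0)}.
#'
#' Echoes are stored sorted by ascending echo time; if `echo_times` arrives
#' unsorted the volumes are reordered to match. Magnitude data must be
#' non-negative and finite.
#'
#' @param label Character scalar identifying the contrast, e.g. `"PDw"`.
#' @param signal 4D numeric array, dimensions `(nx, ny, nz, n_echoes)`,
#'   magnitude intensities in arbitrary scanner units.
#' @param echo_times Numeric vector of echo times in milliseconds, one per
#'   echo volume, strictly increasing after sorting, all positive. At least
#'   two echoes are required (a decay slope is undefined from one point).
#' @return An object of class `multi_echo_contrast`: a list with elements
#'   `label`, `signal` and `echo_times`.
#' @examples
#' te <- seq(2.2, 19.7, by = 2.5)
#' sig <- array(1000 * exp(-0.02 * rep(te, each = 8)), dim = c(2, 2, 2, 8))
#' pdw <- multi_echo_contrast("PDw", sig, te)
#' pdw
#' @export
multi_echo_contrast <- function(label, signal, echo_times) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("'signal' must be a 4D array (nx, ny, nz, n_echoes)", call. = FALSE)
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 2L)
    stop("at least 2 echoes are required to estimate a decay rate", call. = FALSE)
  if (length(echo_times) != dim(signal)[4L])
    stop(sprintf("echo count mismatch: %d echo times but %d volumes",
                 length(echo_times), dim(signal)[4L]), call. = FALSE)
  ord <- order(echo_times)
  echo_times <- echo_times[ord]
  signal <- signal[, , , ord, drop = FALSE]
  if (any(!is.finite(echo_times)) || any(echo_times <= 0))
    stop("echo times must be finite and positive", call. = FALSE)
  if (any(diff(echo_times) <= 0))
    stop("echo times must be strictly increasing (duplicates found)", call. = FALSE)
  if (any(!is.finite(signal)))
    stop(sprintf("contrast '%s': non-finite signal values", label), call. = FALSE)
  if (any(signal < 0))
    stop(sprintf("contrast '%s': negative magnitude intensities", label), call. = FALSE)
  structure(list(label = label, signal = signal, echo_times = echo_times),
            class = "multi_echo_contrast")
}

#' @export
print.multi_echo_contrast <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<multi_echo_contrast '%s'> %dx%dx%d voxels, %d echoes (TE %.2f..%.2f ms)\n",
              x$label, d[1], d[2], d[3], d[4],
              min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' A co-registered multi-contrast multi-echo dataset
#'
#' Collects several [multi_echo_contrast] objects that live on the same voxel
#' grid (assumed co-registered upstream; no resampling is performed here).
#' This is the input to the joint ESTATICS fit, in which all contrasts share
#' one R2* per voxel but keep contrast-specific intercepts.
#'
#' @param contrasts List of [multi_echo_contrast] objects with unique labels
#'   and identical grid dimensions.
#' @param mask Optional 3D logical array restricting all fits to a subset of
#'   voxels (e.g. a brain or object mask). `NULL` means all voxels.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @return An object of class `estatics_dataset`.
#' @export
estatics_dataset <- function(contrasts, mask = NULL, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(contrasts, "multi_echo_contrast")) contrasts <- list(contrasts)
  stopifnot(is.list(contrasts), length(contrasts) >= 1L)
  ok <- vapply(contrasts, inherits, logical(1), "multi_echo_contrast")
  if (!all(ok)) stop("all elements of 'contrasts' must be multi_echo_contrast objects",
                     call. = FALSE)
  labels <- vapply(contrasts, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("contrast labels must be unique: ", paste(labels, collapse = ", "),
         call. = FALSE)
  dims <- vapply(contrasts, function(ct) dim(ct$signal)[1:3], integer(3))
  if (ncol(dims) > 1 && any(dims[, -1] != dims[, 1]))
    stop("all contrasts must share the same 3D grid dimensions", call. = FALSE)
  grid <- dims[, 1]
  if (!is.null(mask)) {
    if (!is.array(mask) || length(dim(mask)) != 3L || !all(dim(mask) == grid))
      stop("'mask' must be a 3D array matching the contrast grid", call. = FALSE)
    mask <- array(as.logical(mask), dim = grid)
    if (anyNA(mask)) stop("'mask' must not contain NA", call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  names(contrasts) <- labels
  structure(list(contrasts = contrasts, mask = mask,
                 voxel_size_mm = voxel_size_mm),
            class = "estatics_dataset")
}

#' @export
print.estatics_dataset <- function(x, ...) {
  grid <- dim(x$contrasts[[1]]$signal)[1:3]
  ne <- vapply(x$contrasts, function(ct) length(ct$echo_times), integer(1))
  cat(sprintf("<estatics_dataset> %dx%dx%d grid, %d contrast(s): %s\n",
              grid[1], grid[2], grid[3], length(x$contrasts),
              paste(sprintf("%s[%d echoes]", names(ne), ne), collapse = ", ")))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d voxels\n", sum(x$mask)))
  invisible(x)
}

#' @rdname estatics_dataset
#' @param x An `estatics_dataset`.
#' @export
dataset_labels <- function(x) {
  stopifnot(inherits(x, "estatics_dataset"))
  names(x$contrasts)
}

grid_dim <- function(dataset) dim(dataset$contrasts[[1]]$signal)[1:3]

# Internal constructor for fit outputs; invariants are guaranteed by the
# fitting code, so no re-validation here.
new_fit_result <- function(r2s, intercepts, log_residual_sos, weights,
                           n_iterations, method, valid, diagnostics = list()) {
  structure(list(r2s = r2s, intercepts = intercepts,
                 log_residual_sos = log_residual_sos, weights = weights,
                 n_iterations = n_iterations, method = method, valid = valid,
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<fit_result method='%s'> %s grid, %d valid voxels\n",
              x$method, paste(dim(x$r2s), collapse = "x"), nv))
  if (nv > 0) {
    q <- stats::quantile(x$r2s[x$valid], c(.05, .5, .95))
    cat(sprintf("  R2* [s^-1] 5%%/50%%/95%%: %.2f / %.2f / %.2f\n", q[1], q[2], q[3]))
  }
  if (length(x$diagnostics))
    cat(sprintf("  diagnostics: %s\n",
                paste(names(x$diagnostics), unlist(lapply(x$diagnostics, format)),
                      sep = "=", collapse = ", ")))
  invisible(x)
}
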