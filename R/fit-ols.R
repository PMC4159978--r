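#' Mono-exponential gradient-echo signal model
#'
#' Evaluates \eqn{I(TE) = I(0) \exp(-R_2^* \, TE)}, the forward model behind
#' every fit in this package. Note the decay rate here is per millisecond
#' (matching TE in ms); maps are reported in \eqn{s^{-1}} elsewhere.
#'
#' @param i0 Signal at TE = 0 (positive, arbitrary units).
#' @param r2s_per_ms Apparent transverse relaxation rate in 1/ms.
#' @param te Echo time(s) in ms, non-negative.
#' @return Predicted signal, same length as the longest argument.
#' @examples
#' predict_signal(1000, 0.02, c(0, 10, 19.7))
#' @export
predict_signal <- function(i0, r2s_per_ms, te) {
  stopifnot(all(i0 > 0), all(te >= 0))
  i0 * exp(-r2s_per_ms * te)
}

#' Build the shared log-linear design system
#'
#' Linearizing the mono-exponential model in the log domain gives, per voxel,
#' \deqn{\ln I_k(TE_n) = \ln I_k(0) - R_2^* \, TE_n ,}
#' a linear system shared by every voxel. The design matrix has one row per
#' (contrast k, echo n) data point and `k_max + 1` columns: one indicator
#' column per contrast (carrying \eqn{\ln I_k(0)}) and a final slope column
#' equal to \eqn{-TE_n} (so the slope coefficient is R2* in 1/ms directly).
#' With a single contrast this reduces to the classical two-column
#' log-linear decay fit.
#'
#' @param dataset An [estatics_dataset].
#' @param subset Optional character vector of contrast labels to restrict to.
#' @return A list of class `design_system` with elements `design` (matrix),
#'   `row_index` (data.frame with columns `contrast`, `echo`, `te_ms`) and
#'   `labels`.
#' @export
build_design <- function(dataset, subset = NULL) {
  stopifnot(inherits(dataset, "estatics_dataset"))
  labels <- dataset_labels(dataset)
  if (!is.null(subset)) {
    missing <- setdiff(subset, labels)
    if (length(missing))
      stop("unknown contrast label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    labels <- subset
  }
  te_all <- unlist(lapply(dataset$contrasts[labels], `[[`, "echo_times"),
                   use.names = FALSE)
  if (length(unique(te_all)) < 2L)
    stop("all echo times identical: decay slope is unidentifiable", call. = FALSE)
  k_max <- length(labels)
  rows <- length(te_all)
  X <- matrix(0, nrow = rows, ncol = k_max + 1L,
              dimnames = list(NULL, c(labels, "r2s_per_ms")))
  ri <- data.frame(contrast = character(rows), echo = integer(rows),
                   te_ms = numeric(rows), stringsAsFactors = FALSE)
  r <- 0L
  for (k in seq_along(labels)) {
    te <- dataset$contrasts[[labels[k]]]$echo_times
    idx <- r + seq_along(te)
    X[idx, k] <- 1
    X[idx, k_max + 1L] <- -te
    ri$contrast[idx] <- labels[k]
    ri$echo[idx] <- seq_along(te)
    ri$te_ms[idx] <- te
    r <- r + length(te)
  }
  structure(list(design = X, row_index = ri, labels = labels),
            class = "design_system")
}

# Flatten the dataset into the (points x voxels) log-signal matrix used by
# every fit. Voxels outside the mask, or with any non-positive/non-finite
# intensity at a used echo, are excluded (marked invalid) rather than
# clamped: clamping log(0) would bias the slope.
assemble_system <- function(dataset, subset = NULL) {
  ds <- build_design(dataset, subset)
  grid <- grid_dim(dataset)
  n_vox <- prod(grid)
  sig <- matrix(NA_real_, nrow = nrow(ds$design), ncol = n_vox)
  r <- 0L
  for (lab in ds$labels) {
    s <- dataset$contrasts[[lab]]$signal
    ne <- dim(s)[4L]
    dim(s) <- c(n_vox, ne)
    sig[r + seq_len(ne), ] <- t(s)
    r <- r + ne
  }
  usable <- colSums(!is.finite(sig) | sig <= 0) == 0L
  if (!is.null(dataset$mask)) usable <- usable & as.vector(dataset$mask)
  list(design = ds, grid = grid, signal = sig, valid = usable)
}

# Shape a per-valid-voxel vector back into a 3D map (NA elsewhere).
to_map <- function(values, valid, grid) {
  m <- rep(NA_real_, prod(grid))
  m[valid] <- values
  array(m, dim = grid)
}

# Per-contrast 4D arrays from a (points x n_valid) matrix.
to_weight_arrays <- function(W, ds, valid, grid) {
  out <- list()
  for (lab in ds$labels) {
    rows <- which(ds$row_index$contrast == lab)
    arr <- array(NA_real_, dim = c(grid, length(rows)))
    flat <- matrix(NA_real_, nrow = prod(grid), ncol = length(rows))
    flat[valid, ] <- t(W[rows, , drop = FALSE])
    arr[] <- flat
    out[[lab]] <- arr
  }
  out
}

build_result <- function(coef, rss, ok, asm, method, weights = NULL,
                         n_iter = 1L) {
  ds <- asm$design; grid <- asm$grid
  k_max <- length(ds$labels)
  valid_vec <- asm$valid
  valid_vec[valid_vec] <- ok
  r2s <- to_map(coef[k_max + 1L, ok] * 1000, valid_vec, grid)
  intercepts <- lapply(seq_len(k_max), function(k)
    to_map(exp(coef[k, ok]), valid_vec, grid))
  names(intercepts) <- ds$labels
  n_it <- array(0L, dim = grid)
  n_it[valid_vec] <- n_iter
  diagnostics <- list(n_negative_r2s = sum(r2s[valid_vec] < 0),
                      n_invalid = sum(!valid_vec))
  new_fit_result(
    r2s = r2s, intercepts = intercepts,
    log_residual_sos = to_map(rss[ok], valid_vec, grid),
    weights = if (!is.null(weights))
      to_weight_arrays(weights[, ok, drop = FALSE], ds,
                       valid_vec, grid),
    n_iterations = n_it, method = method,
    valid = array(valid_vec, dim = grid), diagnostics = diagnostics)
}

#' Ordinary least-squares R2* fit (single contrast or joint)
#'
#' Fits, per voxel, the log-linear model built by [build_design]: minimizes
#' \deqn{\varepsilon = \sum_k \sum_n \big[\ln I_k(TE_n) + \hat R_2^* TE_n -
#'   \ln \hat I_k(0)\big]^2} over the shared slope \eqn{\hat R_2^*} and the
#' per-contrast intercepts. Restricting `subset` to a single label gives the
#' classical single-contrast estimator (PDw-only being the conventional
#' reference). The solve uses one QR factorization of the shared design
#' applied to all voxels at once; with per-point `weights` each voxel gets
#' its own small weighted normal-equations solve (compiled).
#'
#' Negative slope estimates are retained in the map (not clipped) and counted
#' in `diagnostics$n_negative_r2s`: clipping would hide exactly the noise and
#' artifact behaviour the evaluation metrics must see.
#'
#' @param dataset An [estatics_dataset].
#' @param subset Optional contrast labels to fit (default: all).
#' @param weights Optional per-point weights: a named list (one 4D array per
#'   contrast, echoes in the fourth dimension) with values >= 0. All-ones
#'   reproduces plain OLS.
#' @return A `fit_result` with the R2* map in \eqn{s^{-1}}, per-contrast
#'   intercept maps in input intensity units, the minimized (weighted)
#'   squared log-residual map, and a validity mask. `method` is
#'   `"ols_single"` or `"ols_joint"`.
#' @export
fit_ols <- function(dataset, subset = NULL, weights = NULL) {
  asm <- assemble_system(dataset, subset)
  if (!any(asm$valid))
    stop("no usable voxels: empty mask or non-positive signal everywhere",
         call. = FALSE)
  X <- asm$design$design
  Y <- log(asm$signal[, asm$valid, drop = FALSE])
  method <- if (length(asm$design$labels) == 1L) "ols_single" else "ols_joint"
  if (is.null(weights)) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
    coef <- qr.coef(qrX, Y)
    res <- Y - X %*% coef
    rss <- colSums(res^2)
    ok <- rep(TRUE, ncol(Y))
  } else {
    W <- weights_to_matrix(weights, asm)
    sol <- batch_wls(X, Y, W)
    coef <- sol$coef; rss <- as.vector(sol$rss); ok <- as.vector(sol$ok)
  }
  build_result(coef, rss, ok, asm, method, n_iter = 1L)
}

weights_to_matrix <- function(weights, asm) {
  ds <- asm$design
  stopifnot(is.list(weights), all(ds$labels %in% names(weights)))
  W <- matrix(NA_real_, nrow = nrow(ds$design), ncol = sum(asm$valid))
  for (lab in ds$labels) {
    w <- weights[[lab]]
    rows <- which(ds$row_index$contrast == lab)
    stopifnot(length(dim(w)) == 4L, dim(w)[4L] == length(rows))
    dim(w) <- c(prod(asm$grid), length(rows))
    W[rows, ] <- t(w[asm$valid, , drop = FALSE])
  }
  if (any(!is.finite(W)) || any(W < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  W
}
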