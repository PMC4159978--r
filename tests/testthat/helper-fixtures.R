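# Shared fixtures: all synthetic, built in code at test time.

group_echo_times <- function() default_echo_times()

# A reduced phantom for fast tests; geometry and tissue values are the
# package defaults, only the grid shrinks.
small_phantom_spec <- function(grid = c(20, 20, 20), noise_sd = 20,
                               noise_model = "rician", seed = 1L) {
  phantom_spec(grid_shape = grid, noise_sd = noise_sd,
               noise_model = noise_model, seed = seed)
}

# Dataset of n independent voxels laid out as an (n, 1, 1) grid, generated
# from the mono-exponential forward model with optional multiplicative
# log-normal noise. i0 is a named list of per-contrast intensities (scalar
# or length-n); r2s_s is shared across contrasts (s^-1).
synthetic_voxels <- function(n, r2s_s, i0, te = group_echo_times(),
                             log_sd = 0, seed = 1L) {
  te <- te[names(i0)]
  contrasts <- withr_seed(seed, {
    lapply(names(i0), function(lab) {
      tes <- te[[lab]]
      sig <- array(0, dim = c(n, 1, 1, length(tes)))
      for (e in seq_along(tes))
        sig[, 1, 1, e] <- i0[[lab]] * exp(-(r2s_s / 1000) * tes[e])
      if (log_sd > 0)
        sig <- sig * exp(array(rnorm(length(sig), sd = log_sd), dim = dim(sig)))
      multi_echo_contrast(lab, sig, tes)
    })
  })
  estatics_dataset(contrasts)
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent least-squares oracle: SVD pseudoinverse (the fit itself uses
# QR / per-voxel normal equations, so the routes stay distinct).
pinv_coef <- function(X, Y) {
  s <- svd(X)
  s$v %*% (crossprod(s$u, Y) / s$d)
}

write_contrast_files <- function(contrast, dir, stem = contrast$label,
                                 te_order = seq_along(contrast$echo_times)) {
  vol <- file.path(dir, paste0(stem, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(contrast$signal[, , , te_order,
                                                     drop = FALSE]),
                     vol, datatype = "double")
  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(list(Label = contrast$label,
                            EchoTime_ms = contrast$echo_times[te_order]),
                       side, auto_unbox = TRUE, digits = NA)
  list(volume = vol, sidecar = side)
}
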