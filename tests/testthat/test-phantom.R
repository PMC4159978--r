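test_that("the noiseless phantom equals the forward model everywhere", {
  spec <- small_phantom_spec(grid = c(16, 16, 16), noise_sd = 0)
  ph <- make_phantom(spec)
  for (lab in spec$contrast_labels) {
    te <- spec$echo_times[[lab]]
    i0 <- ph$truth$i0[[lab]]
    for (e in c(1, length(te))) {
      expected <- i0 * exp(-(ph$truth$r2s / 1000) * te[e])
      expect_equal(ph$dataset$contrasts[[lab]]$signal[, , , e], expected,
                   tolerance = 1e-14)
    }
  }
  # geometry: nested classes present, last-wins gave CSF the centre
  expect_setequal(unique(as.vector(ph$truth$labels)), c(0L, 1L, 2L, 3L))
  expect_identical(ph$truth$labels[8, 8, 8],
                   match("CSF", spec$tissue_classes$label))
})

test_that("phantom generation is deterministic in the seed", {
  a <- make_phantom(small_phantom_spec(grid = c(10, 10, 10), seed = 4))
  b <- make_phantom(small_phantom_spec(grid = c(10, 10, 10), seed = 4))
  c <- make_phantom(small_phantom_spec(grid = c(10, 10, 10), seed = 5))
  expect_identical(a$dataset$contrasts$PDw$signal, b$dataset$contrasts$PDw$signal)
  expect_false(identical(a$dataset$contrasts$PDw$signal,
                         c$dataset$contrasts$PDw$signal))
})

test_that("Rician background level matches the Rayleigh mean", {
  spec <- small_phantom_spec(grid = c(24, 24, 24), noise_sd = 20, seed = 10)
  ph <- make_phantom(spec)
  bg <- ph$truth$labels == 0L
  vals <- ph$dataset$contrasts$PDw$signal[, , , 1][bg]
  expect_equal(mean(vals), 20 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("zero-strength corruption is the identity", {
  ph <- make_phantom(small_phantom_spec(grid = c(12, 12, 12)))
  ct <- ph$dataset$contrasts$PDw
  expect_identical(corrupt_kspace(ct, corruption_spec(line_fraction = 0)), ct)
  expect_identical(corrupt_kspace(ct, corruption_spec(max_phase_error_rad = 0)),
                   ct)
})

test_that("phase-only corruption conserves image energy (Parseval)", {
  # multiplying k-space lines by a unit phase leaves every |k| unchanged,
  # so by Parseval the total signal energy of the magnitude image is
  # conserved exactly, even though the image itself is rearranged
  ph <- make_phantom(small_phantom_spec(grid = c(16, 16, 16)))
  ct <- ph$dataset$contrasts$PDw
  spec <- corruption_spec(target_echoes = 8L, line_fraction = 0.3, seed = 6)
  out <- corrupt_kspace(ct, spec)
  expect_equal(sum(out$signal[, , , 8]^2), sum(ct$signal[, , , 8]^2),
               tolerance = 1e-10)
  expect_gt(max(abs(out$signal[, , , 8] - ct$signal[, , , 8])), 1)
})

test_that("corruption touches only the targeted echoes and contrast", {
  ph <- make_phantom(small_phantom_spec(grid = c(12, 12, 12)))
  spec <- corruption_spec(target_echoes = c(7L, 8L), seed = 2)
  out <- corrupt_kspace(ph$dataset$contrasts$PDw, spec)
  for (e in 1:6)
    expect_identical(out$signal[, , , e], ph$dataset$contrasts$PDw$signal[, , , e])
  for (e in 7:8)
    expect_false(identical(out$signal[, , , e],
                           ph$dataset$contrasts$PDw$signal[, , , e]))
  expect_error(corrupt_kspace(ph$dataset$contrasts$T1w, spec), "targets")
  expect_error(corrupt_kspace(ph$dataset$contrasts$PDw,
                              corruption_spec(target_echoes = 99L)),
               "out of range")
})

test_that("ROI CoV of the corrupted-contrast fit grows with line fraction", {
  spec <- small_phantom_spec(grid = c(32, 32, 32), seed = 3)
  ph <- make_phantom(spec)
  roi <- erode_mask(ph$truth$labels == 1L, 2)
  covs <- vapply(c(0, 0.1, 0.3), function(lf) {
    ds <- ph$dataset
    if (lf > 0)
      ds$contrasts$PDw <- corrupt_kspace(
        ds$contrasts$PDw,
        corruption_spec(line_fraction = lf, seed = 17))
    roi_stats(fit_ols(ds, subset = "PDw")$r2s, roi)$cov
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("cohorts are seeded per subject and reproducible", {
  spec <- small_phantom_spec(grid = c(10, 10, 10))
  co <- simulate_cohort(3, spec, base_seed = 7)
  expect_length(co, 3)
  expect_false(identical(co[[1]]$dataset$contrasts$PDw$signal,
                         co[[2]]$dataset$contrasts$PDw$signal))
  # per-subject R2* jitter stays within +/-5%
  for (s in co)
    expect_true(all(abs(s$truth$classes$r2s / spec$tissue_classes$r2s - 1)
                    <= 0.05))
  co2 <- simulate_cohort(3, spec, base_seed = 7)
  expect_identical(co[[2]]$dataset$contrasts$MTw$signal,
                   co2[[2]]$dataset$contrasts$MTw$signal)

  # n = 1 with corruption equals the explicit composition
  corr <- corruption_spec(target_echoes = 7:8)
  one <- simulate_cohort(1, spec, corr, base_seed = 11, r2s_jitter = 0)
  seed1 <- (11L + 7919L) %% 2147483647L
  spec_manual <- spec; spec_manual$seed <- (seed1 + 1L) %% 2147483647L
  manual <- make_phantom(spec_manual)
  corr_manual <- corr; corr_manual$seed <- (seed1 + 2L) %% 2147483647L
  manual$dataset$contrasts$PDw <-
    corrupt_kspace(manual$dataset$contrasts$PDw, corr_manual)
  expect_identical(one[[1]]$dataset$contrasts$PDw$signal,
                   manual$dataset$contrasts$PDw$signal)
})

test_that("mask erosion removes exactly the boundary shell", {
  m <- array(FALSE, dim = c(9, 9, 9)); m[3:7, 3:7, 3:7] <- TRUE
  e1 <- erode_mask(m, 1)
  expect_identical(which(e1, arr.ind = TRUE),
                   which(array(FALSE, dim = c(9, 9, 9)) |
                         (function(a) {a[4:6, 4:6, 4:6] <- TRUE; a})(
                           array(FALSE, dim = c(9, 9, 9))), arr.ind = TRUE))
  # eroding to nothing is possible and signalled downstream
  expect_equal(sum(erode_mask(m, 3)), 0)
})
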