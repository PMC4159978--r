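test_that("forward model matches its closed form", {
  expect_identical(predict_signal(1000, 0.02, 0), 1000)
  expect_identical(predict_signal(1000, 0, 19.7), 1000)
  # frozen high-precision evaluation of 1000 * exp(-0.02 * 14.7)
  expect_equal(predict_signal(1000, 0.02, 14.7), 745.276491443289,
               tolerance = 1e-12)
  expect_error(predict_signal(-1, 0.02, 5))
})

test_that("design system has the documented shape, indicators and rank", {
  ds3 <- synthetic_voxels(1, 21, list(PDw = 1000, T1w = 1000, MTw = 600))
  d <- build_design(ds3)
  expect_identical(dim(d$design), c(20L, 4L))          # 8 + 6 + 6 points
  expect_true(all(rowSums(d$design[, 1:3] != 0) == 1)) # one indicator per row
  expect_identical(d$design[d$row_index$contrast == "PDw", 4],
                   -d$row_index$te_ms[d$row_index$contrast == "PDw"])
  expect_identical(qr(d$design)$rank, 4L)

  d1 <- build_design(ds3, subset = "PDw")
  expect_identical(dim(d1$design), c(8L, 2L))          # single-contrast case

  # two contrasts with identical TE vectors: indicators + shared slope
  te <- list(A = seq(2.2, 14.7, by = 2.5), B = seq(2.2, 14.7, by = 2.5))
  ds2 <- synthetic_voxels(1, 20, list(A = 500, B = 700), te = te)
  d2 <- build_design(ds2)
  expect_identical(qr(d2$design)$rank, 3L)
  # brute-force rank oracle via SVD
  expect_identical(sum(svd(d2$design)$d > 1e-10), 3L)
})

test_that("noiseless voxels are fitted exactly", {
  # two points determine the line
  te <- list(PDw = c(2, 10))
  ds <- synthetic_voxels(1, 50, list(PDw = 1000), te = te)
  f <- fit_ols(ds)
  expect_equal(f$r2s[1, 1, 1], 50, tolerance = 1e-10)
  expect_equal(f$intercepts$PDw[1, 1, 1], 1000, tolerance = 1e-8)

  # consistent 3-contrast system: exact recovery of all four parameters
  ds3 <- synthetic_voxels(5, 25, list(PDw = 1000, T1w = 700, MTw = 550))
  f3 <- fit_ols(ds3)
  expect_equal(unname(f3$r2s[, 1, 1]), rep(25, 5), tolerance = 1e-8)
  expect_equal(unname(f3$intercepts$PDw[, 1, 1]), rep(1000, 5), tolerance = 1e-6)
  expect_equal(unname(f3$intercepts$T1w[, 1, 1]), rep(700, 5), tolerance = 1e-6)
  expect_equal(unname(f3$intercepts$MTw[, 1, 1]), rep(550, 5), tolerance = 1e-6)
  expect_identical(f3$method, "ols_joint")
  expect_true(all(f3$log_residual_sos[f3$valid] < 1e-16))
})

test_that("joint OLS coefficients match an independent pseudoinverse oracle", {
  n <- 1000
  ds <- synthetic_voxels(n, runif(n, 10, 40),
                         list(PDw = 1000, T1w = 700, MTw = 550),
                         log_sd = 0.05, seed = 42)
  f <- fit_ols(ds)
  X <- build_design(ds)$design
  Y <- log(do.call(rbind, lapply(c("PDw", "T1w", "MTw"), function(lab) {
    s <- ds$contrasts[[lab]]$signal
    ne <- dim(s)[4]
    t(matrix(s, nrow = n, ncol = ne))
  })))
  oracle <- pinv_coef(X, Y)
  expect_equal(f$r2s[, 1, 1], oracle[4, ] * 1000, tolerance = 1e-10)
  expect_equal(f$intercepts$PDw[, 1, 1], exp(oracle[1, ]), tolerance = 1e-10)
})

test_that("single-contrast subset equals a dataset containing only that contrast", {
  ds3 <- synthetic_voxels(200, runif(200, 5, 45),
                          list(PDw = 1000, T1w = 700, MTw = 550),
                          log_sd = 0.05, seed = 7)
  sub <- fit_ols(ds3, subset = "PDw")
  alone <- fit_ols(estatics_dataset(list(ds3$contrasts$PDw)))
  expect_equal(sub$r2s, alone$r2s, tolerance = 1e-12)
  expect_equal(sub$intercepts$PDw, alone$intercepts$PDw, tolerance = 1e-12)
  expect_identical(sub$method, "ols_single")
})

test_that("rescaling one contrast changes only its own intercept", {
  ds <- synthetic_voxels(100, runif(100, 10, 40),
                         list(PDw = 1000, T1w = 700, MTw = 550),
                         log_sd = 0.03, seed = 11)
  f0 <- fit_ols(ds)
  c_scale <- 3.7
  ds$contrasts$MTw <- multi_echo_contrast("MTw",
                                          ds$contrasts$MTw$signal * c_scale,
                                          ds$contrasts$MTw$echo_times)
  f1 <- fit_ols(ds)
  expect_equal(f1$r2s, f0$r2s, tolerance = 1e-10)
  expect_equal(f1$intercepts$PDw, f0$intercepts$PDw, tolerance = 1e-10)
  expect_equal(f1$intercepts$MTw, f0$intercepts$MTw * c_scale,
               tolerance = 1e-10)
})

test_that("the joint 20-point fit is less variable than the 8-point PDw fit", {
  n <- 2000
  ds <- synthetic_voxels(n, 21, list(PDw = 1000, T1w = 1000, MTw = 600),
                         log_sd = 0.02, seed = 5)
  sd_joint <- sd(fit_ols(ds)$r2s)
  sd_pdw <- sd(fit_ols(ds, subset = "PDw")$r2s)
  expect_lt(sd_joint, sd_pdw)
})

test_that("unit weights reproduce plain OLS and invalid voxels are skipped", {
  n <- 50
  ds <- synthetic_voxels(n, 20, list(PDw = 1000, T1w = 700),
                         log_sd = 0.05, seed = 3)
  w1 <- list(PDw = array(1, dim = c(n, 1, 1, 8)),
             T1w = array(1, dim = c(n, 1, 1, 6)))
  fw <- fit_ols(ds, weights = w1)
  f0 <- fit_ols(ds)
  expect_equal(fw$r2s, f0$r2s, tolerance = 1e-9)

  # a zero intensity invalidates the voxel instead of aborting the run
  sigz <- ds$contrasts$PDw$signal
  sigz[7, 1, 1, 2] <- 0
  dsz <- estatics_dataset(list(
    multi_echo_contrast("PDw", sigz, ds$contrasts$PDw$echo_times),
    ds$contrasts$T1w))
  fz <- fit_ols(dsz)
  expect_false(fz$valid[7, 1, 1])
  expect_true(is.na(fz$r2s[7, 1, 1]))
  expect_true(all(fz$valid[-7, 1, 1]))

  # an empty mask is an error
  dsz$mask <- array(FALSE, dim = c(n, 1, 1))
  expect_error(fit_ols(dsz), "no usable voxels")
})
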