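test_that("wave_curve evaluates the damped sine in closed form", {
  expect_equal(max(abs(wave_curve(solvation_wave(0, 3), default_rgrid(0, 10))$g)), 0)

  # phase 0, r = lambda/4, no decay: sine maximum A
  w <- solvation_wave(2.5, 4, phase = 0, decay = 1e9)
  cv <- wave_curve(w, default_rgrid(0, 10))
  expect_equal(cv$g[cv$r == 1], 2.5, tolerance = 1e-6)

  # decay length 2: envelope at r = 2 is A/e
  w2 <- solvation_wave(1, 4, phase = pi / 2, decay = 2)
  cv2 <- wave_curve(w2, default_rgrid(0, 10))
  expect_equal(cv2$g[cv2$r == 0], 1)
  env2 <- 1 * exp(-1)  # |envelope| at r = 2
  expect_lte(abs(cv2$g[cv2$r == 2]), env2 + 1e-12)

  expect_error(solvation_wave(1, -1), class = "clusterpdf_validation_error")
})

test_that("refinement is a fixed point on self-generated data", {
  toy <- make_toy_cluster()
  data <- calc_pdf(toy, default_rgrid())
  res <- refine_positions(toy, data, refinement_options(continuation = FALSE))
  expect_lt(res$rw_value, 1e-6)
  expect_lt(max(abs(coords(res$model) - coords(toy))), 0.01)
  expect_equal(res$scale, 1, tolerance = 1e-4)
})

test_that("refinement reproduces data from a small noiseless displacement", {
  toy <- make_toy_cluster()
  set.seed(21)
  shifted <- set_coords(toy, coords(toy) +
                          matrix(runif(54, -0.0577, 0.0577), ncol = 3))
  data <- calc_pdf(shifted, default_rgrid())
  res <- refine_positions(toy, data, refinement_options())
  rms <- sqrt(mean(rowSums((coords(res$model) - coords(shifted))^2)))
  # the fit becomes near-exact; residual position error stays at the scale
  # of the (data-silent) null-space component of the perturbation
  expect_lt(res$rw_value, 1e-3)
  expect_lt(res$rw_value, res$rw_start / 100)
  expect_lt(rms, 0.1)
})

test_that("dmax = 0 refines only the scale", {
  toy <- make_toy_cluster()
  data <- calc_pdf(toy, default_rgrid(), scale = 2.4)
  res <- refine_positions(toy, data, refinement_options(dmax = 0))
  expect_equal(coords(res$model), coords(toy), ignore_attr = TRUE)
  expect_equal(res$scale, 2.4, tolerance = 1e-6)
  expect_lt(res$rw_value, 1e-10)
})

test_that("positions stay within dmax of the start per coordinate", {
  toy <- make_toy_cluster()
  gt <- apply_distortion(toy, c(9, 12, -3, -3), jitter = 0.05, seed = 2)
  data <- simulate_pdf(gt$distorted, noise_sigma = 0.01, seed = 4)
  opts <- refinement_options(dmax = 0.15)
  res <- refine_positions(toy, data, opts)
  expect_lte(max(abs(coords(res$model) - coords(toy))), 0.15 + 1e-9)
})

test_that("stage 2 recovers a known wave and never degrades Rw", {
  toy <- make_toy_cluster()
  rg <- default_rgrid()
  truth <- solvation_wave(amplitude = 4, wavelength = 3.2, phase = 0.6,
                          decay = 4.5)
  data <- pdf_curve(rg, calc_pdf(toy, rg)$g + wave_curve(truth, rg)$g)
  res1 <- refine_positions(toy, data, refinement_options(dmax = 0))
  res2 <- refine_wave(res1, data)
  expect_lte(res2$rw_value, res1$rw_value)
  expect_equal(res2$wave$amplitude, truth$amplitude, tolerance = 0.05)
  expect_equal(res2$wave$wavelength, truth$wavelength, tolerance = 0.05 * 3.2)
  expect_equal(res2$wave$decay, truth$decay, tolerance = 0.05 * 4.5)

  # exact data: refined amplitude ~ 0 and Rw unchanged
  clean <- calc_pdf(toy, rg)
  r1 <- refine_positions(toy, clean, refinement_options(dmax = 0))
  r2 <- suppressWarnings(refine_wave(r1, clean))
  expect_lte(r2$rw_value, r1$rw_value)
  expect_lt(abs(r2$wave$amplitude) * exp(-2 / r2$wave$decay),
            0.01 * max(abs(clean$g)))
})

test_that("stage 2 Rw never exceeds stage 1 on noisy inputs", {
  toy <- make_toy_cluster()
  gt <- apply_distortion(toy, c(9, 12, -3, -3), jitter = 0.05, seed = 6)
  for (seed in c(11, 12)) {
    data <- simulate_pdf(gt$distorted, wave = solvation_wave(5, 3, 0.4, 4),
                         noise_sigma = 0.02, seed = seed)
    r1 <- suppressWarnings(refine_positions(perturb(toy, 0.2, seed), data,
                                            refinement_options(max_iter = 60)))
    r2 <- suppressWarnings(refine_wave(r1, data))
    expect_lte(r2$rw_value, r1$rw_value + 1e-12)
    expect_equal(r2$rw_stage1, r1$rw_value)
  }
})

test_that("refinement is deterministic and gauge-consistent", {
  toy <- make_toy_cluster()
  gt <- apply_distortion(toy, c(5, 5, -5, -5), jitter = 0.03, seed = 9)
  data <- simulate_pdf(gt$distorted, noise_sigma = 0.01, seed = 10)
  opts <- refinement_options(max_iter = 40)
  a <- suppressWarnings(refine_positions(toy, data, opts))
  b <- suppressWarnings(refine_positions(toy, data, opts))
  expect_identical(coords(a$model), coords(b$model))
  expect_identical(a$rw_value, b$rw_value)

  # rigid translation of start and data-generating model leaves Rw unchanged
  shift <- c(3.2, -1.1, 0.7)
  toy_t <- set_coords(toy, sweep(coords(toy), 2, shift, `+`))
  gt_t <- set_coords(gt$distorted, sweep(coords(gt$distorted), 2, shift, `+`))
  data_t <- simulate_pdf(gt_t, noise_sigma = 0.01, seed = 10)
  a_t <- suppressWarnings(refine_positions(toy_t, data_t, opts))
  expect_equal(a_t$rw_value, a$rw_value, tolerance = 1e-8)
})

test_that("the stage-1 parameter count is 3N + 1 with refined scale", {
  toy <- make_toy_cluster()
  expect_equal(3 * nrow(toy) + 1, 55)
})
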