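test_that("perturb respects bounds, distribution and determinism", {
  toy <- make_toy_cluster()
  expect_identical(coords(perturb(toy, 0, 1)), coords(toy))
  expect_identical(coords(perturb(toy, 0.2, 7)), coords(perturb(toy, 0.2, 7)))
  expect_false(identical(coords(perturb(toy, 0.2, 7)),
                         coords(perturb(toy, 0.2, 8))))

  # 1e4 draws: all within +/- 0.2 per component, approximately uniform
  m <- two_atom_model()
  shifts <- unlist(lapply(1:1700, function(s) {
    coords(perturb(m, 0.2, s)) - coords(m)
  }))
  expect_gte(length(shifts), 1e4)
  expect_lte(max(abs(shifts)), 0.2)
  ks <- suppressWarnings(stats::ks.test(shifts, "punif", -0.2, 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate ensemble equals the single refinement", {
  toy <- make_toy_cluster()
  gt <- apply_distortion(toy, c(5, 5, -5, -5), jitter = 0.03, seed = 2)
  data <- simulate_pdf(gt$distorted, noise_sigma = 0.01, seed = 3)
  opts <- refinement_options(max_iter = 40)
  single <- suppressWarnings(refine_two_stage(toy, data, opts, cycles = 2))
  ens <- suppressWarnings(run_ensemble(toy, data,
                                       ensemble_spec(1, 0, base_seed = 5),
                                       opts))
  expect_equal(coords(ens$results[[1]]$model), coords(single$model),
               ignore_attr = TRUE)
  expect_equal(ens$results[[1]]$rw_value, single$rw_value)
  expect_equal(coords(average_structure(ens)), coords(single$model),
               ignore_attr = TRUE)
})

test_that("rw summary orders and seeds are distinct and reproducible", {
  toy <- make_toy_cluster()
  gt <- apply_distortion(toy, c(5, 5, -5, -5), jitter = 0.03, seed = 2)
  data <- simulate_pdf(gt$distorted, noise_sigma = 0.01, seed = 3)
  opts <- refinement_options(max_iter = 25)
  ens <- suppressWarnings(run_ensemble(toy, data, ensemble_spec(4, 0.2, 77),
                                       opts, refine_wave_stage = FALSE))
  s <- ens$rw_summary
  expect_lte(s[["min"]], s[["mean"]])
  expect_lte(s[["mean"]], s[["max"]])
  expect_false(anyDuplicated(ens$seeds) > 0)
  # every perturbed start within the spec bound of the reference
  for (st in ens$start_models) {
    expect_lte(max(abs(coords(st) - coords(toy))), 0.2)
  }
  ens2 <- suppressWarnings(run_ensemble(toy, data, ensemble_spec(4, 0.2, 77),
                                        opts, refine_wave_stage = FALSE))
  expect_identical(tidy(ens)$rw, tidy(ens2)$rw)
})

test_that("average_structure and spreads match direct recomputation", {
  toy <- make_toy_cluster()
  # hand-built ensemble around known per-atom means
  mk <- function(res_model, rwv) {
    structure(list(model = res_model, scale = 1, wave = NULL,
                   rw_value = rwv, rw_start = 1, rw_stage1 = rwv,
                   residual = pdf_curve(seq(1, 2, 0.01), rep(0, 101)),
                   converged = TRUE, iterations = 1,
                   options = refinement_options()),
              class = "pdf_refinement")
  }
  up <- set_coords(toy, sweep(coords(toy), 2, c(0.2, 0, 0), `+`))
  dn <- set_coords(toy, sweep(coords(toy), 2, c(-0.2, 0, 0), `+`))
  ens <- structure(list(results = list(mk(up, 0.1), mk(dn, 0.2)),
                        start_models = list(toy, toy),
                        seeds = c(1L, 2L), reference = toy,
                        spec = ensemble_spec(2, 0.2, 1),
                        opts = refinement_options(),
                        failed = c(FALSE, FALSE),
                        rw_summary = c(min = 0.1, max = 0.2, mean = 0.15)),
                   class = "pdf_ensemble")
  avg <- average_structure(ens)
  expect_lt(max(abs(coords(avg) - coords(toy))), 1e-12)

  pd <- position_distribution(ens)
  expect_equal(unique(round(pd$stats$median, 12)), 0.2)
  expect_lt(max(pd$stats$iqr), 1e-12)

  # one-atom jitter: only that atom spreads
  up1 <- toy; up1$x[3] <- up1$x[3] + 0.4
  ens1 <- ens
  ens1$results <- list(mk(up1, 0.1), mk(toy, 0.2))
  pd1 <- position_distribution(ens1)
  spread <- setNames(pd1$stats$max, pd1$stats$label)
  jittered <- toy$label[3]
  expect_gt(spread[[jittered]], 0.1)
  expect_lt(max(spread[setdiff(names(spread), jittered)]), 1e-12)
})

test_that("mean stage-1 residual averages noise down and keeps the common part", {
  rg <- default_rgrid(2, 10)
  common <- 0.5 * dnorm(rg, 5.2, 0.5) + 0.4 * dnorm(rg, 7.7, 0.6)
  mk <- function(g) {
    structure(list(model = make_toy_cluster(), scale = 1, wave = NULL,
                   rw_value = 0.1, rw_start = 1, rw_stage1 = 0.1,
                   residual = pdf_curve(rg, g), converged = TRUE,
                   iterations = 1, options = refinement_options()),
              class = "pdf_refinement")
  }
  n <- 64
  set.seed(13)
  noise_sd <- 0.2
  res <- lapply(seq_len(n), function(i) mk(common + rnorm(length(rg), 0, noise_sd)))
  ens <- structure(list(results = res, start_models = res, seeds = seq_len(n),
                        reference = make_toy_cluster(),
                        spec = ensemble_spec(n, 0.2, 1),
                        opts = refinement_options(), failed = rep(FALSE, n),
                        rw_summary = c(min = 0.1, max = 0.1, mean = 0.1)),
                   class = "pdf_ensemble")
  avg <- mean_stage1_residual(ens)
  resid_noise <- sd(avg$g - common)
  expect_lt(resid_noise, 2 * noise_sd / sqrt(n))
  expect_gt(cor(avg$g, common), 0.95)

  # alternating +-c residuals cancel exactly
  res2 <- lapply(seq_len(4), function(i) mk(rep(c(1, -1)[i %% 2 + 1], length(rg))))
  ens2 <- ens; ens2$results <- res2; ens2$failed <- rep(FALSE, 4)
  expect_equal(max(abs(mean_stage1_residual(ens2)$g)), 0)
})

test_that("Cl constrained tighter than Ag shows in spread statistics", {
  toy <- make_toy_cluster()
  mkj <- function(seed) {
    set.seed(seed)
    jit <- matrix(rnorm(54, 0, 0.15), ncol = 3)
    jit[toy$element == "Cl", ] <- jit[toy$element == "Cl", ] * 0.1
    structure(list(model = set_coords(toy, coords(toy) + jit), scale = 1,
                   wave = NULL, rw_value = 0.1, rw_start = 1, rw_stage1 = 0.1,
                   residual = pdf_curve(seq(1, 2, 0.01), rep(0, 101)),
                   converged = TRUE, iterations = 1,
                   options = refinement_options()),
              class = "pdf_refinement")
  }
  res <- lapply(1:30, mkj)
  ens <- structure(list(results = res, start_models = res, seeds = 1:30,
                        reference = toy, spec = ensemble_spec(30, 0.2, 1),
                        opts = refinement_options(), failed = rep(FALSE, 30),
                        rw_summary = c(min = 0.1, max = 0.1, mean = 0.1)),
                   class = "pdf_ensemble")
  stats <- position_distribution(ens)$stats
  cl_med <- stats$median[stats$element == "Cl"]
  ag_med <- stats$median[stats$element == "Ag"]
  expect_lt(max(cl_med), min(ag_med))
})
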