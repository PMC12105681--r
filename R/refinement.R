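#' Empirical solvation wave
#'
#' Dissolved particles restructure the solvent around them; in a
#' background-subtracted PDF this shows up as a slowly decaying oscillation
#' in the residual. The standard empirical model is an exponentially damped
#' sine wave, g(r) = A sin(2 pi r / lambda + phi) exp(-r / xi).
#'
#' @param amplitude A, PDF units (may be negative; a sign flip equals a
#'   phase shift of pi).
#' @param wavelength lambda, Angstrom (> 0).
#' @param phase phi, radians.
#' @param decay xi, decay length, Angstrom (> 0).
#' @return A `solvation_wave` object.
#' @export
solvation_wave <- function(amplitude, wavelength, phase = 0, decay = 5) {
  if (wavelength <= 0 || decay <= 0) {
    abort("wavelength and decay must be > 0.",
          class = "clusterpdf_validation_error")
  }
  structure(list(amplitude = amplitude, wavelength = wavelength,
                 phase = phase, decay = decay),
            class = "solvation_wave")
}

#' @export
print.solvation_wave <- function(x, ...) {
  cat(sprintf(
    "<solvation_wave> A = %.4g, lambda = %.4g A, phi = %.4g rad, xi = %.4g A\n",
    x$amplitude, x$wavelength, x$phase, x$decay))
  invisible(x)
}

#' Evaluate a solvation wave on an r grid
#'
#' @param wave A [solvation_wave()].
#' @param rgrid Uniform r grid, Angstrom.
#' @return A [pdf_curve()].
#' @export
wave_curve <- function(wave, rgrid = default_rgrid()) {
  g <- wave$amplitude * sin(2 * pi * rgrid / wave$wavelength + wave$phase) *
    exp(-rgrid / wave$decay)
  pdf_curve(rgrid, g, meta = list(source = "solvation_wave"))
}

#' Refinement options
#'
#' @param r_range Fit range (r_lo, r_hi), Angstrom. The default 1.7-15
#'   excludes sub-bond artifacts below the shortest physical contact and the
#'   featureless high-r region.
#' @param dmax Per-coordinate position bound from the start model, Angstrom.
#'   Bounds fix the gauge: the PDF is invariant to rigid motion, so
#'   unbounded positions are unidentifiable.
#' @param tol Convergence tolerance on the cost.
#' @param max_iter Maximum optimizer iterations.
#' @param refine_scale Refine the overall scale alongside positions (for an
#'   18-atom cluster this gives the 54 + 1 = 55 stage-1 parameters).
#' @param sigma0 Resolution floor passed to [calc_pdf()].
#' @param continuation Solve a short sequence of progressively sharper
#'   problems, each started from the previous solution. Gaussian pair peaks
#'   only attract an atom from within about one peak width, so
#'   sharp-resolution cost surfaces have narrow basins; mild broadening
#'   first widens the basin, and the schedule is fixed, so the result stays
#'   deterministic.
#' @param cont_levels Extra Gaussian widths (Angstrom, descending, ending
#'   in 0) defining the continuation schedule. Widths are added in
#'   quadrature to the pair widths and the data are smoothed to match.
#'   Levels much wider than the pair width are counterproductive: heavy
#'   smoothing merges peaks into a surface whose minimum is a different
#'   geometry.
#' @return A list of class `refinement_options`.
#' @export
refinement_options <- function(r_range = c(1.7, 15), dmax = 1.0,
                               tol = 1e-10, max_iter = 500,
                               refine_scale = TRUE, sigma0 = 0.05,
                               continuation = TRUE,
                               cont_levels = c(0.1, 0)) {
  if (r_range[1] >= r_range[2]) {
    abort("r_range must satisfy r_lo < r_hi.",
          class = "clusterpdf_validation_error")
  }
  if (dmax < 0) {
    abort("dmax must be >= 0.", class = "clusterpdf_validation_error")
  }
  structure(list(r_range = r_range, dmax = dmax, tol = tol,
                 max_iter = max_iter, refine_scale = refine_scale,
                 sigma0 = sigma0, continuation = continuation,
                 cont_levels = cont_levels),
            class = "refinement_options")
}

# Model G(r) and its Jacobian wrt atom coordinates on a uniform grid.
# Returns list(g = unscaled G, jac = d(unscaled G)/d(coords) [n_r x 3N])
# using truncated Gaussian windows. sigma per pair includes the floor.
.pdf_model_eval <- function(xyz, pairs, sigmas, weights2, rgrid, want_jac = FALSE) {
  pdf_model_eval_cpp(xyz, pairs, sigmas, weights2,
                     rgrid[1], grid_step(rgrid), length(rgrid), want_jac)
}

# Gaussian smoothing with edge renormalisation (scale-space level for the
# continuation schedule).
.gauss_smooth <- function(y, dr, s) {
  if (s <= 0) return(y)
  half <- ceiling(4 * s / dr)
  k <- dnorm(seq(-half, half) * dr, 0, s)
  num <- .linconv(y, k, half)
  den <- .linconv(rep(1, length(y)), k, half)
  num / den
}

# Soft-wall collision penalty: residual entries k * max(0, dmin - d_ij).
.collision_penalty <- function(xyz, pairs, dmin = 0.5, k = 100) {
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  k * pmax(0, dmin - d)
}

#' Refine atomic positions against a PDF
#'
#' Stage 1 of the two-stage strategy: minimises Rw over the 3N Cartesian
#' coordinates (plus one overall scale when `refine_scale`) with bounded
#' Levenberg-Marquardt least squares on the pointwise residual. Positions
#' are bounded within `dmax` of the start per coordinate, which both keeps
#' the refinement in the start model's frame and prevents unidentifiable
#' rigid drift. Steps that would bring two atoms closer than 0.5 Angstrom
#' are repelled by a hinge penalty on the residual.
#'
#' @param start A [cluster_model()] start model.
#' @param data Observed [pdf_curve()]; must cover the fit range.
#' @param opts A [refinement_options()].
#' @return A `pdf_refinement` object: refined model, scale, `rw_value`,
#'   `rw_start`, the stage-1 residual curve (data minus scaled model PDF
#'   over the fit range), convergence flag and iteration count.
#' @export
refine_positions <- function(start, data, opts = refinement_options()) {
  validate_cluster_model(start)
  if (min(data$r) > opts$r_range[1] || max(data$r) < opts$r_range[2]) {
    abort("Data does not cover the fit range.",
          class = "clusterpdf_validation_error")
  }
  keep <- data$r >= opts$r_range[1] & data$r <= opts$r_range[2]
  robs <- data$r[keep]
  gobs <- data$g[keep]
  denom <- sqrt(sum(gobs^2))
  if (denom == 0) {
    abort("Observed curve is zero over the fit range.",
          class = "clusterpdf_division_error")
  }

  pt <- pair_table(start)
  pairs <- cbind(pt$i, pt$j)
  sigmas <- sqrt(pt$sigma^2 + opts$sigma0^2)
  weights2 <- 2 * pt$weight
  n <- nrow(start)
  xyz0 <- coords(start)

  scale_of <- function(gmod) {
    s <- sum(gobs * gmod) / sum(gmod^2)
    max(s, 1e-9)
  }
  g0 <- .pdf_model_eval(xyz0, pairs, sigmas, weights2, robs)$g
  s_start <- if (opts$refine_scale) scale_of(g0) else 1
  rw_start <- sqrt(sum((gobs - s_start * g0)^2)) / denom

  if (opts$dmax == 0) {
    # positions fixed; closed-form scale refinement only
    s <- if (opts$refine_scale) scale_of(g0) else 1
    resid <- gobs - s * g0
    return(.new_refinement(start, s, sqrt(sum(resid^2)) / denom, rw_start,
                           robs, resid, TRUE, 0L, opts))
  }

  par0 <- c(as.vector(t(xyz0)), if (opts$refine_scale) s_start)
  np <- 3L * n
  center <- if (is.null(opts$bounds_center)) par0[seq_len(np)] else
    as.vector(t(opts$bounds_center))
  lower <- c(center - opts$dmax, if (opts$refine_scale) 1e-9)
  upper <- c(center + opts$dmax, if (opts$refine_scale) Inf)
  par0[seq_len(np)] <- pmin(pmax(par0[seq_len(np)], lower[seq_len(np)]),
                            upper[seq_len(np)])

  unpack <- function(par) {
    list(xyz = matrix(par[seq_len(np)], n, 3, byrow = TRUE),
         s = if (opts$refine_scale) par[np + 1L] else 1)
  }
  dr <- grid_step(robs)
  r0 <- robs[1]
  levels <- if (isTRUE(opts$continuation)) opts$cont_levels else 0
  par <- par0
  iterations <- 0L
  for (s_extra in levels) {
    sig_lvl <- sqrt(sigmas^2 + s_extra^2)
    gobs_lvl <- .gauss_smooth(gobs, dr, s_extra)
    fn <- function(par) {
      pp <- unpack(par)
      pdf_resid_jac_cpp(pp$xyz, pairs, sig_lvl, weights2, r0, dr, gobs_lvl,
                        pp$s, opts$refine_scale, 0.5, 100, FALSE)$resid
    }
    jac <- function(par) {
      pp <- unpack(par)
      pdf_resid_jac_cpp(pp$xyz, pairs, sig_lvl, weights2, r0, dr, gobs_lvl,
                        pp$s, opts$refine_scale, 0.5, 100, TRUE)$jac
    }
    fit <- minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = fn, jac = jac,
      control = minpack.lm::nls.lm.control(
        maxiter = opts$max_iter, ftol = opts$tol, ptol = opts$tol, gtol = 0))
    par <- fit$par
    iterations <- iterations + fit$niter
  }

  pp <- unpack(par)
  gfit <- .pdf_model_eval(pp$xyz, pairs, sigmas, weights2, robs)$g
  resid <- gobs - pp$s * gfit
  model <- set_coords(start, pp$xyz)
  if (!endsWith(model_name(start), "(refined)")) {
    attr(model, "name") <- paste0(model_name(start), " (refined)")
  }
  .new_refinement(model, pp$s, sqrt(sum(resid^2)) / denom, rw_start,
                  robs, resid, fit$info %in% 1:4, iterations, opts)
}

.new_refinement <- function(model, scale, rw_value, rw_start, robs, resid,
                            converged, iterations, opts, wave = NULL,
                            rw_stage1 = NULL) {
  structure(list(model = model, scale = scale, wave = wave,
                 rw_value = rw_value, rw_start = rw_start,
                 rw_stage1 = rw_stage1 %||% rw_value,
                 residual = pdf_curve(robs, resid,
                                      meta = list(source = "stage1 residual")),
                 converged = converged, iterations = iterations,
                 options = opts),
            class = "pdf_refinement")
}

#' @export
print.pdf_refinement <- function(x, ...) {
  cat(sprintf("<pdf_refinement> %s\n", model_name(x$model)))
  cat(sprintf("  Rw: start %.4f -> refined %.4f%s\n", x$rw_start, x$rw_value,
              if (!is.null(x$wave)) sprintf(" (stage 1: %.4f)", x$rw_stage1) else ""))
  cat(sprintf("  scale %.4g, %s after %d iterations\n", x$scale,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (!is.null(x$wave)) print(x$wave)
  invisible(x)
}

# Dominant Fourier period of a uniformly sampled signal, for wave
# initialisation from the sinusoidal stage-1 residual.
.dominant_period <- function(r, y) {
  n <- length(y)
  sp <- Mod(fft(y - mean(y)))[2:floor(n / 2)]
  k <- which.max(sp)
  n * grid_step(r) / k
}

#' Two-stage refinement with position/wave alternation
#'
#' Runs [refine_positions()] followed by [refine_wave()], then alternates:
#' the fitted wave is subtracted from the data, positions are re-refined
#' against the wave-free signal, and the wave is refit against the new
#' residual. An unmodelled solvation wave biases a pure stage-1 position
#' fit (atoms chase the baseline oscillation); one or two alternations let
#' the two components separate. The position bounds stay anchored at the
#' original start model throughout.
#'
#' @param start A [cluster_model()] start model.
#' @param data Observed [pdf_curve()].
#' @param opts A [refinement_options()].
#' @param cycles Number of position/wave alternations (1 = plain two-stage).
#' @return A `pdf_refinement` with `wave` set; `rw_value` is the final
#'   misfit of model + wave against the data, `rw_stage1` the wave-free
#'   misfit of the final positions, and `residual` the final stage-1
#'   residual (data minus scaled model PDF, before the wave).
#' @export
refine_two_stage <- function(start, data, opts = refinement_options(),
                             cycles = 2) {
  res <- refine_positions(start, data, opts)
  rw_start <- res$rw_start
  res <- refine_wave(res, data, opts)
  if (cycles > 1) {
    bounds_anchor <- start
    for (cyc in seq_len(cycles - 1)) {
      wsub <- pdf_curve(data$r, data$g - wave_curve(res$wave, data$r)$g)
      # re-refine positions against the wave-subtracted data, keeping the
      # original bounds by restarting from the anchor-centred box
      res_pos <- refine_positions_anchored(res$model, bounds_anchor, wsub, opts)
      res2 <- refine_wave(res_pos, data, opts)
      if (res2$rw_value <= res$rw_value) res <- res2 else break
    }
  }
  res$rw_start <- rw_start
  res
}

# refine_positions with the bound box centred on `anchor` but the search
# started from `start` (used by the alternation cycles).
refine_positions_anchored <- function(start, anchor, data, opts) {
  shift_box <- coords(start) - coords(anchor)
  if (max(abs(shift_box)) > opts$dmax + 1e-9) {
    # start already at/outside the anchor box: clip back in
    clipped <- pmin(pmax(shift_box, -opts$dmax), opts$dmax)
    start <- set_coords(start, coords(anchor) + clipped)
  }
  res <- refine_positions(start, data, opts_with_anchor(opts, anchor, start))
  res
}

# Encode the anchor-centred bounds by passing absolute bounds through opts.
opts_with_anchor <- function(opts, anchor, start) {
  opts$bounds_center <- coords(anchor)
  opts
}

#' Refine the solvation wave against the stage-1 residual
#'
#' Stage 2: adds an exponentially damped sine wave to the scaled model PDF
#' and refines its parameters (amplitude, wavelength, phase, decay) by
#' bounded least squares; optionally the atomic positions are re-relaxed
#' jointly. The wave is initialised from the stage-1 residual: wavelength
#' from its dominant Fourier period, amplitude from its extreme value. The
#' zero-amplitude wave reproduces stage 1 exactly, and the better of the
#' refined and zero-wave solutions is kept, so Rw never increases.
#'
#' @param result A `pdf_refinement` from [refine_positions()].
#' @param data The observed [pdf_curve()] (same as stage 1).
#' @param opts [refinement_options()]; defaults to the stage-1 options.
#' @param refit_positions Re-relax atomic positions jointly with the wave.
#' @return A `pdf_refinement` with `wave` set, `rw_value` updated and
#'   `rw_stage1` preserved.
#' @export
refine_wave <- function(result, data, opts = result$options,
                        refit_positions = FALSE) {
  if (!inherits(result, "pdf_refinement")) {
    abort("result must come from refine_positions().",
          class = "clusterpdf_validation_error")
  }
  keep <- data$r >= opts$r_range[1] & data$r <= opts$r_range[2]
  robs <- data$r[keep]
  gobs <- data$g[keep]
  denom <- sqrt(sum(gobs^2))

  pt <- pair_table(result$model)
  pairs <- cbind(pt$i, pt$j)
  sigmas <- sqrt(pt$sigma^2 + opts$sigma0^2)
  weights2 <- 2 * pt$weight
  xyz1 <- coords(result$model)
  gmod <- .pdf_model_eval(xyz1, pairs, sigmas, weights2, robs)$g
  resid1 <- gobs - result$scale * gmod

  dr <- grid_step(robs)
  lam0 <- .dominant_period(robs, resid1)
  # solvent-restructuring wavelengths are set by solvent-shell spacings;
  # below ~1 Angstrom a "wave" can only chase noise
  lam_lo <- max(4 * dr, 1)
  lam_hi <- 2 * (opts$r_range[2] - opts$r_range[1])
  lam0 <- min(max(lam0, lam_lo), lam_hi)
  a0 <- max(abs(resid1))
  wave_eval <- function(par, r) {
    par[1] * sin(2 * pi * r / par[2] + par[3]) * exp(-r / par[4])
  }

  n <- nrow(xyz1)
  np <- 3L * n
  if (refit_positions) {
    par0 <- c(as.vector(t(xyz1)), result$scale, a0, lam0, 0, 5)
    lower <- c(as.vector(t(xyz1)) - opts$dmax, 1e-9, -Inf, lam_lo, -2 * pi, 1)
    upper <- c(as.vector(t(xyz1)) + opts$dmax, Inf, Inf, lam_hi, 2 * pi, 1e4)
    fn <- function(par) {
      xyz <- matrix(par[seq_len(np)], n, 3, byrow = TRUE)
      g <- .pdf_model_eval(xyz, pairs, sigmas, weights2, robs)$g
      c(gobs - par[np + 1] * g - wave_eval(par[np + 1 + 1:4], robs),
        .collision_penalty(xyz, pairs))
    }
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                           ftol = opts$tol, ptol = opts$tol))
    xyz2 <- matrix(fit$par[seq_len(np)], n, 3, byrow = TRUE)
    s2 <- fit$par[np + 1]
    wpar <- fit$par[np + 1 + 1:4]
    g2 <- .pdf_model_eval(xyz2, pairs, sigmas, weights2, robs)$g
    resid2 <- gobs - s2 * g2 - wave_eval(wpar, robs)
    model2 <- set_coords(result$model, xyz2)
  } else {
    # the overall scale is re-refined jointly with the wave: a scale fitted
    # against wave-containing data is biased, and that bias would otherwise
    # leak into the wave amplitude and decay
    par0 <- c(a0, lam0, 0, 5, result$scale)
    lower <- c(-Inf, lam_lo, -2 * pi, 1, 1e-9)
    upper <- c(Inf, lam_hi, 2 * pi, 1e4, Inf)
    fn <- function(par) gobs - par[5] * gmod - wave_eval(par[1:4], robs)
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                           ftol = opts$tol, ptol = opts$tol))
    wpar <- fit$par[1:4]
    s2 <- fit$par[5]
    resid2 <- gobs - s2 * gmod - wave_eval(wpar, robs)
    model2 <- result$model
  }

  rw2 <- sqrt(sum(resid2^2)) / denom
  degenerate <- wpar[2] <= lam_lo * (1 + 1e-6)
  if (degenerate) {
    warn("Solvation wavelength collapsed to the grid-scale bound; flagged.")
  }
  if (rw2 > result$rw_value + 1e-12) {
    # nested model guarantee: zero wave reproduces stage 1
    wpar <- c(0, lam0, 0, 5)
    rw2 <- result$rw_value
    s2 <- result$scale
    model2 <- result$model
  }
  wave <- solvation_wave(wpar[1], wpar[2], wpar[3], wpar[4])
  out <- result
  out$model <- model2
  out$scale <- s2
  out$wave <- wave
  out$rw_stage1 <- result$rw_value
  out$rw_value <- rw2
  out$converged <- result$converged && fit$info %in% 1:4
  out$iterations <- result$iterations + fit$niter
  out
}
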