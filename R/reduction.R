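#' Subtract a scaled background in Q space
#'
#' Pointwise `y_sample - scale * y_background`. The background is linearly
#' resampled onto the sample grid when the grids differ; the two curves must
#' overlap in Q. For dissolved DNA-stabilized clusters the background is the
#' aqueous-DNA measurement, and careful scaling here is what isolates the
#' metal-core correlations.
#'
#' @param sample,background [iq_curve()] objects.
#' @param scale Background scale factor (>= 0 normally; not enforced).
#' @return An [iq_curve()] on the sample grid.
#' @export
subtract_background <- function(sample, background, scale) {
  if (min(background$q) > max(sample$q) || max(background$q) < min(sample$q)) {
    abort("Sample and background Q ranges do not overlap.",
          class = "clusterpdf_validation_error")
  }
  yb <- if (length(background$q) == length(sample$q) &&
            max(abs(background$q - sample$q)) < 1e-9) {
    background$y
  } else {
    approx(background$q, background$y, xout = sample$q, rule = 2)$y
  }
  iq_curve(sample$q, sample$y - scale * yb,
           meta = c(curve_meta(sample), list(bg_scale = scale)))
}

#' Estimate the background scale
#'
#' Returns the scale minimising the integrated squared residual of
#' `sample - scale * background` over a background-dominated Q window — the
#' closed-form least-squares projection. With `enforce_nonneg` the scale is
#' additionally capped so the subtracted signal does not dip below
#' `-neg_tol` times the sample's maximum anywhere in the window (meaningful
#' for intensity-like curves; reduced F(Q) oscillates around zero, so the
#' cap is off by default). The result is a helper for the user-set scale in
#' [subtract_background()], never applied silently.
#'
#' @param sample,background [iq_curve()] objects.
#' @param window Length-2 Q window dominated by background features; `NULL`
#'   uses the full overlap.
#' @param enforce_nonneg Cap the scale to avoid negative excursions.
#' @param neg_tol Allowed negative excursion as a fraction of max |sample|.
#' @return Single numeric scale.
#' @export
auto_scale <- function(sample, background, window = NULL,
                       enforce_nonneg = FALSE, neg_tol = 0.01) {
  yb <- approx(background$q, background$y, xout = sample$q, rule = 2)$y
  keep <- sample$q >= max(min(sample$q), min(background$q)) &
    sample$q <= min(max(sample$q), max(background$q))
  if (!is.null(window)) keep <- keep & sample$q >= window[1] & sample$q <= window[2]
  if (!any(keep)) {
    abort("Empty overlap window.", class = "clusterpdf_validation_error")
  }
  ys <- sample$y[keep]
  ybw <- yb[keep]
  denom <- sum(ybw^2)
  if (denom == 0) {
    abort("Background is zero over the window: scale unbounded.",
          class = "clusterpdf_optimization_error")
  }
  s <- sum(ys * ybw) / denom
  tol <- neg_tol * max(abs(ys))
  if (enforce_nonneg && s > 0 && min(ys - s * ybw) < -tol) {
    # largest scale (<= s) keeping residual >= -tol where background is positive
    pos <- ybw > 0
    if (any(pos)) {
      s_max <- min((ys[pos] + tol) / ybw[pos])
      s <- max(0, min(s, s_max))
    }
  }
  s
}

#' Sine Fourier transform of F(Q) to G(r)
#'
#' G(r) = (2/pi) * integral from qmin to qmax of F(Q) sin(Qr) dQ, evaluated
#' by trapezoidal quadrature on each point of the r grid. Termination ripples
#' shrink as qmax grows.
#'
#' @param fq An [iq_curve()] holding the reduced structure function.
#' @param qmin,qmax Transform bounds, 1/Angstrom; `qmax` must lie within the
#'   data range.
#' @param rgrid Output r grid ([default_rgrid()]).
#' @return A [pdf_curve()].
#' @export
fq_to_gr <- function(fq, qmin = 0.7, qmax = 20, rgrid = default_rgrid()) {
  if (qmin < 0 || qmin >= qmax) {
    abort("Need 0 <= qmin < qmax.", class = "clusterpdf_validation_error")
  }
  if (qmax > max(fq$q) + 1e-9) {
    abort("qmax exceeds the data range.", class = "clusterpdf_validation_error")
  }
  if (!all(is.finite(fq$y))) {
    abort("F(Q) contains non-finite values.", class = "clusterpdf_validation_error")
  }
  keep <- fq$q >= qmin & fq$q <= qmax
  q <- fq$q[keep]
  y <- fq$y[keep]
  dq <- diff(q)
  # trapezoid weights on the (possibly non-uniform) q grid
  wq <- c(dq / 2, 0) + c(0, dq / 2)
  yw <- y * wq
  g <- (2 / pi) * as.numeric(sin(outer(rgrid, q)) %*% yw)
  pdf_curve(rgrid, g,
            meta = list(source = "fq_to_gr", qmin = qmin, qmax = qmax,
                        note = curve_meta(fq)$note))
}

#' Inverse transform of a PDF back to F(Q)
#'
#' F(Q) = integral of G(r) sin(Qr) dr by trapezoidal quadrature; the inverse
#' of [fq_to_gr()] up to termination effects. Mainly used to build
#' self-consistency fixtures and synthetic reciprocal-space data.
#'
#' @param gr A [pdf_curve()].
#' @param qgrid Output Q grid, 1/Angstrom.
#' @return An [iq_curve()].
#' @export
gr_to_fq <- function(gr, qgrid = seq(0, 25, by = 0.02)) {
  dr <- diff(gr$r)
  wr <- c(dr / 2, 0) + c(0, dr / 2)
  gw <- gr$g * wr
  y <- as.numeric(sin(outer(qgrid, gr$r)) %*% gw)
  iq_curve(qgrid, y, meta = list(source = "gr_to_fq"))
}
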