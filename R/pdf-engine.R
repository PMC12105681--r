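#' Enumerate weighted atom pairs of a model
#'
#' Lists every unordered atom pair once with its distance and scattering
#' weight w_ij = f_i f_j / <f>^2, where f is the per-element weight
#' ([element_weight()]) and <f> the composition-weighted mean weight of the
#' model. With this normalisation a single-element model has all weights 1.
#'
#' @param model A [cluster_model()].
#' @return A tibble with columns `i`, `j` (site indices, i < j), `label_i`,
#'   `label_j`, `rij` (distance, Angstrom), `weight`, `sigma` (Gaussian
#'   width from the two sites' biso, before any resolution floor).
#' @export
pair_table <- function(model) {
  validate_cluster_model(model)
  n <- nrow(model)
  xyz <- coords(model)
  d <- as.matrix(dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  rij <- d[idx]
  if (any(rij < 1e-6)) {
    abort("Coincident atoms (pair distance < 1e-6 Angstrom).",
          class = "clusterpdf_degenerate_geometry_error")
  }
  f <- element_weight(model$element)
  fbar <- mean(f)
  w <- f[i] * f[j] / fbar^2
  sigma <- sqrt((model$biso[i] + model$biso[j]) / (8 * pi^2))
  tibble(i = i, j = j,
         label_i = model$label[i], label_j = model$label[j],
         rij = rij, weight = w, sigma = sigma)
}

# Accumulate sum of weight * unit-area Gaussian(r; center, sigma) onto a
# uniform grid, truncating each Gaussian at +/- 8 sigma (relative error
# < 1e-14). Vectorised over grid points within each pair's window.
.gauss_accumulate <- function(rgrid, centers, sigmas, weights) {
  g <- numeric(length(rgrid))
  r0 <- rgrid[1]
  dr <- grid_step(rgrid)
  n <- length(rgrid)
  for (p in seq_along(centers)) {
    s <- sigmas[p]
    lo <- max(1L, floor((centers[p] - 8 * s - r0) / dr) + 1L)
    hi <- min(n, ceiling((centers[p] + 8 * s - r0) / dr) + 1L)
    if (lo > hi) next
    win <- lo:hi
    g[win] <- g[win] + weights[p] * dnorm(rgrid[win], centers[p], s)
  }
  g
}

#' Simulate the reduced PDF of an atomic model
#'
#' Computes G(r) = (s/r) * sum over pairs i<j of 2 w_ij N(r; r_ij, sigma_ij)
#' on a uniform grid, where N is a unit-area Gaussian,
#' sigma_ij^2 = (biso_i + biso_j) / (8 pi^2) + sigma0^2, and s an overall
#' scale. The resolution floor sigma0 stands in for the finite-Qmax
#' broadening always present in experimental PDFs and keeps sharp pairs from
#' aliasing on the grid. The value at r = 0 is defined as 0. No 4 pi rho0 r
#' baseline is subtracted: a dissolved cluster after background subtraction
#' is treated as an isolated scatterer.
#'
#' @param model A [cluster_model()].
#' @param rgrid Uniform ascending grid, Angstrom ([default_rgrid()]).
#' @param scale Overall scale s.
#' @param sigma0 Resolution floor added in quadrature, Angstrom.
#' @return A [pdf_curve()].
#' @examples
#' m <- cluster_model(data.frame(element = "Ag", x = c(0, 2.8), y = 0, z = 0))
#' curve <- calc_pdf(m, default_rgrid(0, 6))
#' curve$r[which.max(curve$g)]
#' @export
calc_pdf <- function(model, rgrid = default_rgrid(), scale = 1, sigma0 = 0.05) {
  pt <- pair_table(model)
  sigma <- sqrt(pt$sigma^2 + sigma0^2)
  if (any(sigma <= 0)) {
    off <- abs((pt$rij - rgrid[1]) / grid_step(rgrid)) %% 1
    if (any(pmin(off, 1 - off) > 1e-9)) {
      warn("Zero pair width with off-grid distance: peak may be aliased.")
    }
    sigma <- pmax(sigma, 1e-12)
  }
  g <- .gauss_accumulate(rgrid, pt$rij, sigma, 2 * pt$weight)
  g <- scale * g / ifelse(rgrid > 0, rgrid, Inf)
  pdf_curve(rgrid, g, meta = list(source = model_name(model),
                                  scale = scale, sigma0 = sigma0))
}

#' Weighted profile residual Rw
#'
#' Rw = sqrt( sum (g_obs - g_calc)^2 / sum g_obs^2 ) over the fit range.
#' The calculated curve is linearly resampled onto the observed grid when
#' the grids differ. Lower is better; Rw of a zero model is 1.
#'
#' @param obs,calc [pdf_curve()] objects.
#' @param r_range Length-2 fit range (Angstrom) or `NULL` for the full
#'   observed grid.
#' @return Single non-negative number.
#' @export
rw <- function(obs, calc, r_range = NULL) {
  gc <- if (isTRUE(all.equal(obs$r, calc$r, tolerance = 1e-12))) {
    calc$g
  } else {
    approx(calc$r, calc$g, xout = obs$r, rule = 2)$y
  }
  keep <- rep(TRUE, length(obs$r))
  if (!is.null(r_range)) keep <- obs$r >= r_range[1] & obs$r <= r_range[2]
  go <- obs$g[keep]
  gcv <- gc[keep]
  denom <- sum(go^2)
  if (denom == 0) {
    abort("Observed curve is zero over the fit range: Rw undefined.",
          class = "clusterpdf_division_error")
  }
  sqrt(sum((go - gcv)^2) / denom)
}

#' Pointwise linear combination of PDF curves
#'
#' @param curves List of [pdf_curve()] on a common grid.
#' @param weights Non-negative weights, one per curve.
#' @param normalize Normalise weights to sum 1 before combining.
#' @return A [pdf_curve()].
#' @export
linear_combination <- function(curves, weights, normalize = TRUE) {
  if (length(curves) != length(weights)) {
    abort("One weight per curve required.", class = "clusterpdf_validation_error")
  }
  if (any(weights < 0)) {
    abort("Weights must be non-negative.", class = "clusterpdf_validation_error")
  }
  r <- curves[[1]]$r
  for (cu in curves[-1]) {
    if (length(cu$r) != length(r) || max(abs(cu$r - r)) > 1e-9) {
      abort("Curves must share one r grid.", class = "clusterpdf_validation_error")
    }
  }
  if (normalize) weights <- weights / sum(weights)
  g <- Reduce(`+`, Map(function(cu, w) w * cu$g, curves, weights))
  pdf_curve(r, g, meta = list(source = "linear_combination"))
}

#' Locate PDF peaks
#'
#' Finds local maxima whose prominence over the higher of the two flanking
#' minima exceeds `min_prominence` times the global maximum, then refines
#' each position by parabolic interpolation through the three points around
#' the maximum.
#'
#' @param curve A [pdf_curve()].
#' @param min_prominence Prominence threshold as a fraction of max(g).
#' @return Ascending numeric vector of peak positions (Angstrom); empty when
#'   nothing qualifies.
#' @export
find_peaks <- function(curve, min_prominence = 0.05) {
  g <- curve$g
  r <- curve$r
  n <- length(g)
  if (n < 3 || max(g) <= 0) return(numeric(0))
  cand <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  thresh <- min_prominence * max(g)
  out <- numeric(0)
  for (k in cand) {
    # walk to the bracketing minima
    left <- k
    while (left > 1 && g[left - 1] <= g[left]) left <- left - 1
    right <- k
    while (right < n && g[right + 1] <= g[right]) right <- right + 1
    prom <- g[k] - max(g[left], g[right])
    if (prom < thresh) next
    # parabolic refinement through (k-1, k, k+1)
    y1 <- g[k - 1]; y2 <- g[k]; y3 <- g[k + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y1 - y3) / denom
    out <- c(out, r[k] + delta * grid_step(r))
  }
  sort(out)
}

#' Structural coherence length from a PDF
#'
#' Smooths |G(r)| with a moving window to form an envelope and returns the
#' r interval bracketing the last contiguous excursion of that envelope
#' above `noise_floor` — an approximate upper bound on the ordered object's
#' size (for the dissolved Ag16Cl2 core the paper-scale analogue is the
#' 10-12 Angstrom region beyond which the PDF is featureless).
#'
#' @param curve A [pdf_curve()].
#' @param noise_floor Positive amplitude threshold.
#' @param window Smoothing window width, Angstrom.
#' @return Named numeric vector `c(r_low, r_high)`.
#' @export
coherence_length <- function(curve, noise_floor, window = 0.5) {
  if (noise_floor <= 0) {
    abort("noise_floor must be > 0.", class = "clusterpdf_validation_error")
  }
  k <- max(1L, as.integer(round(window / grid_step(curve$r))))
  if (k %% 2 == 0) k <- k + 1L
  env <- as.numeric(stats::filter(abs(curve$g), rep(1 / k, k), sides = 2))
  env[is.na(env)] <- abs(curve$g)[is.na(env)]
  above <- env > noise_floor
  if (!any(above)) {
    abort("Signal never exceeds the noise floor: coherence length undefined.",
          class = "clusterpdf_undefined_coherence_error")
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  last <- max(which(runs$values))
  c(r_low = curve$r[starts[last]], r_high = curve$r[ends[last]])
}
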