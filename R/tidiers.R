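#' Tidy a refinement result
#'
#' One row per atom with start and refined coordinates and the per-atom
#' shift magnitude.
#'
#' @param x A `pdf_refinement`.
#' @param start Optional start [cluster_model()] to difference against; when
#'   omitted only refined coordinates are returned.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pdf_refinement
#' @export
tidy.pdf_refinement <- function(x, start = NULL, ...) {
  m <- x$model
  out <- tibble(label = m$label, element = m$element,
                x = m$x, y = m$y, z = m$z, biso = m$biso)
  if (!is.null(start)) {
    st <- .match_models(m, start)
    out$shift <- sqrt((m$x - st$x)^2 + (m$y - st$y)^2 + (m$z - st$z)^2)
  }
  out
}

#' @rdname tidy.pdf_refinement
#' @method glance pdf_refinement
#' @export
glance.pdf_refinement <- function(x, ...) {
  tibble(rw = x$rw_value, rw_stage1 = x$rw_stage1, rw_start = x$rw_start,
         scale = x$scale,
         wave_amplitude = if (is.null(x$wave)) NA_real_ else x$wave$amplitude,
         wave_wavelength = if (is.null(x$wave)) NA_real_ else x$wave$wavelength,
         wave_decay = if (is.null(x$wave)) NA_real_ else x$wave$decay,
         converged = x$converged, iterations = x$iterations)
}

#' Tidy an ensemble
#'
#' One row per model: seed, Rw values, scale, convergence.
#'
#' @param x A `pdf_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pdf_ensemble
#' @export
tidy.pdf_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$results, function(res, k) {
    if (inherits(res, "condition")) {
      tibble(model = k, seed = x$seeds[k], rw = NA_real_,
             rw_stage1 = NA_real_, scale = NA_real_, converged = FALSE,
             failed = TRUE)
    } else {
      tibble(model = k, seed = x$seeds[k], rw = res$rw_value,
             rw_stage1 = res$rw_stage1, scale = res$scale,
             converged = res$converged, failed = FALSE)
    }
  })
}

#' @rdname tidy.pdf_ensemble
#' @method glance pdf_ensemble
#' @export
glance.pdf_ensemble <- function(x, ...) {
  tibble(n_models = x$spec$n_models, n_failed = sum(x$failed),
         max_disp = x$spec$max_disp, base_seed = x$spec$base_seed,
         rw_min = x$rw_summary[["min"]], rw_mean = x$rw_summary[["mean"]],
         rw_max = x$rw_summary[["max"]])
}

#' Summarise a displacement field
#'
#' @param x A `displacement_field` tibble.
#' @param ... Unused.
#' @return One-row tibble: min/max/mean displacement magnitude and
#'   min/max/mean rotation over atoms with a defined angle.
#' @method glance displacement_field
#' @export
glance.displacement_field <- function(x, ...) {
  rot <- x$rotation[!is.na(x$rotation)]
  tibble(n = nrow(x),
         magnitude_min = min(x$magnitude), magnitude_max = max(x$magnitude),
         magnitude_mean = mean(x$magnitude),
         rotation_min = if (length(rot)) min(rot) else NA_real_,
         rotation_max = if (length(rot)) max(rot) else NA_real_,
         rotation_mean = if (length(rot)) mean(rot) else NA_real_)
}

#' @rdname glance.displacement_field
#' @method glance biso_scan
#' @export
glance.biso_scan <- function(x, ...) {
  tibble(optimum = attr(x, "optimum"), rw = attr(x, "optimum_rw"),
         scale = attr(x, "optimum_scale"), offset = attr(x, "optimum_offset"),
         rms_displacement = biso_to_rms(attr(x, "optimum")))
}
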