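#' Plot a PDF curve
#'
#' @param object A [pdf_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pdf_curve
#' @export
autoplot.pdf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "G(r)",
                  title = curve_meta(object)$source) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pdf_curve
#' @method autoplot iq_curve
#' @export
autoplot.iq_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Q (1/Å)", y = "F(Q)") +
    ggplot2::theme_minimal()
}

#' Plot a refinement fit
#'
#' Observed data, scaled model (plus wave when present) and offset
#' difference curve over the fit range.
#'
#' @param object A `pdf_refinement`.
#' @param data The observed [pdf_curve()] used in the fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pdf_refinement
#' @export
autoplot.pdf_refinement <- function(object, data, ...) {
  opts <- object$options
  keep <- data$r >= opts$r_range[1] & data$r <= opts$r_range[2]
  robs <- data$r[keep]
  calc <- calc_pdf(object$model, robs, scale = object$scale,
                   sigma0 = opts$sigma0)$g
  if (!is.null(object$wave)) calc <- calc + wave_curve(object$wave, robs)$g
  obs <- data$g[keep]
  offset <- -1.2 * max(abs(obs))
  df <- dplyr::bind_rows(
    tibble(r = robs, g = obs, curve = "observed"),
    tibble(r = robs, g = calc, curve = "model"),
    tibble(r = robs, g = obs - calc + offset, curve = "difference"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$g,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "G(r)",
                  subtitle = sprintf("Rw = %.3f", object$rw_value)) +
    ggplot2::theme_minimal()
}

#' Box plot of ensemble positional spreads
#'
#' Distances of each model's refined position from the per-atom ensemble
#' mean, one box per atom.
#'
#' @param object A `position_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot position_distribution
#' @export
autoplot.position_distribution <- function(object, ...) {
  ggplot2::ggplot(object$positions,
                  ggplot2::aes(x = .data$label, y = .data$distance,
                               fill = .data$element)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "distance from ensemble mean (Å)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a displacement field
#'
#' Rotation angle against radial distance, coloured by channel.
#'
#' @param object A `displacement_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, ...) {
  df <- object[!is.na(object$rotation), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radial_distance,
                                   y = .data$rotation,
                                   colour = .data$channel,
                                   size = .data$magnitude)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "radial distance from principal axis (Å)",
                  y = "rotation about principal axis (°)") +
    ggplot2::theme_minimal()
}

#' Plot a Biso scan
#'
#' Misfit against trial Biso with the optimum marked.
#'
#' @param object A `biso_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot biso_scan
#' @export
autoplot.biso_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$biso, y = .data$rw)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "optimum"), linetype = 2) +
    ggplot2::labs(x = expression(B[iso] ~ (ring(A)^2)), y = "Rw") +
    ggplot2::theme_minimal()
}
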