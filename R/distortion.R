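#' Principal axis of a cluster
#'
#' The direction of maximal coordinate variance: the leading eigenvector of
#' the covariance matrix of the centered reference coordinates, unweighted.
#' The axis is computed from the reference (crystal) structure so it is
#' independent of refinement noise. Sign convention: the component with the
#' largest absolute value is made positive (tie broken toward +z), which
#' makes reported rotation signs reproducible.
#'
#' @param reference A [cluster_model()] with at least 3 non-collinear atoms.
#' @return A `principal_axis`: list with `origin` (centroid, Angstrom) and
#'   `direction` (unit 3-vector).
#' @export
principal_axis <- function(reference) {
  xyz <- coords(reference)
  if (nrow(xyz) < 3) {
    abort("Need at least 3 atoms.", class = "clusterpdf_validation_error")
  }
  origin <- colMeans(xyz)
  cen <- sweep(xyz, 2, origin)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  if (ev$values[1] < 1e-12) {
    abort("Degenerate geometry: no principal direction.",
          class = "clusterpdf_validation_error")
  }
  if (ev$values[1] / max(ev$values[2], 1e-300) < 1.05) {
    warn("Leading eigenvalues nearly degenerate: principal axis ambiguous.")
  }
  v <- ev$vectors[, 1]
  k <- which.max(abs(v))
  if (abs(abs(v[k]) - abs(v[3])) < 1e-12) k <- 3L  # tie -> +z
  if (v[k] < 0) v <- -v
  structure(list(origin = origin, direction = v / sqrt(sum(v^2))),
            class = "principal_axis")
}

#' @export
print.principal_axis <- function(x, ...) {
  cat(sprintf("<principal_axis> origin (%.3f, %.3f, %.3f), direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

.match_models <- function(reference, refined) {
  if (!setequal(reference$label, refined$label)) {
    abort("Models do not share the same site labels.",
          class = "clusterpdf_pairing_error")
  }
  refined[match(reference$label, refined$label), , drop = FALSE]
}

#' Per-atom displacement field between two structures
#'
#' Displacement vector (refined minus reference), its magnitude, and the
#' signed rotation angle of each atom about the cluster's principal axis.
#' Atoms are paired by label. For the solution-vs-crystal comparison these
#' records quantify the displacive and rotational distortions of the core.
#'
#' @param reference,refined [cluster_model()] objects with matching labels.
#' @param axis A `principal_axis`; computed from `reference` by default.
#' @param channels Optional named vector (label -> channel id) merged into
#'   the records; falls back to a `channel` column on `reference`.
#' @return A tibble of class `displacement_field`: label, element, strand,
#'   channel, dx, dy, dz, magnitude, radial_distance (from the axis),
#'   rotation (signed degrees; NA for on-axis atoms).
#' @export
displacement_field <- function(reference, refined,
                               axis = principal_axis(reference),
                               channels = NULL) {
  refined <- .match_models(reference, refined)
  d <- unname(coords(refined) - coords(reference))
  mag <- sqrt(rowSums(d^2))
  chan <- if (!is.null(channels)) {
    unname(channels[reference$label])
  } else if ("channel" %in% names(reference)) {
    reference$channel
  } else {
    NA
  }
  ang <- rotation_angles(reference, refined, axis)
  out <- tibble(label = reference$label, element = reference$element,
                strand = reference$strand, channel = chan,
                dx = d[, 1], dy = d[, 2], dz = d[, 3],
                magnitude = mag,
                radial_distance = ang$radial_distance,
                rotation = ang$rotation)
  class(out) <- c("displacement_field", class(out))
  out
}

#' Signed rotation angles about the principal axis
#'
#' Projects each atom's reference and refined positions (relative to the
#' axis origin) into the plane perpendicular to the axis and returns the
#' signed angle between the projections. Positive means counterclockwise
#' when looking down the +axis direction (right-hand rule). Atoms closer
#' than `min_radius` to the axis have an undefined angle and are flagged NA
#' and excluded from summaries.
#'
#' @param reference,refined Paired [cluster_model()] objects.
#' @param axis A `principal_axis`.
#' @param min_radius Radial cutoff below which the angle is undefined, Angstrom.
#' @return A tibble: label, radial_distance, rotation (degrees, in
#'   (-180, 180]).
#' @export
rotation_angles <- function(reference, refined,
                            axis = principal_axis(reference),
                            min_radius = 0.1) {
  refined <- .match_models(reference, refined)
  a <- axis$direction
  proj <- function(xyz) {
    rel <- sweep(xyz, 2, axis$origin)
    rel - outer(as.numeric(rel %*% a), a)
  }
  u <- unname(proj(coords(reference)))
  v <- unname(proj(coords(refined)))
  ru <- sqrt(rowSums(u^2))
  cross <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sinterm <- as.numeric(cross %*% a)
  costerm <- rowSums(u * v)
  ang <- atan2(sinterm, costerm) * 180 / pi
  ang[ru < min_radius] <- NA_real_
  tibble(label = reference$label, radial_distance = ru, rotation = ang)
}

#' Per-group distortion statistics
#'
#' Arithmetic mean rotation angle and displacement magnitude per group
#' (channel or strand). On-axis atoms (NA rotation) are excluded; empty
#' groups are dropped with a warning. The `sense` column labels each group
#' clockwise/counterclockwise under the package's axis convention.
#'
#' @param records A `displacement_field` tibble.
#' @param grouping Column to group by: `"channel"` or `"strand"`.
#' @param elements Restrict to these elements first (default `"Ag"`; the
#'   caps sit on the axis and have no defined rotation).
#' @return A tibble: group, n, mean_rotation (degrees), mean_magnitude
#'   (Angstrom), sense.
#' @export
channel_stats <- function(records, grouping = "channel", elements = "Ag") {
  if (!grouping %in% names(records)) {
    abort(paste0("No '", grouping, "' column in records."),
          class = "clusterpdf_validation_error")
  }
  df <- dplyr::filter(records, .data$element %in% elements)
  if (any(is.na(df[[grouping]]))) {
    warn("Records with missing group dropped.")
    df <- df[!is.na(df[[grouping]]), , drop = FALSE]
  }
  df <- dplyr::filter(df, !is.na(.data$rotation))
  if (nrow(df) == 0) {
    abort("No atoms with defined rotation in any group.",
          class = "clusterpdf_validation_error")
  }
  df |>
    dplyr::group_by(group = .data[[grouping]]) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_rotation = mean(.data$rotation),
                     mean_magnitude = mean(.data$magnitude),
                     .groups = "drop") |>
    dplyr::mutate(sense = ifelse(.data$mean_rotation >= 0,
                                 "counterclockwise", "clockwise"))
}
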