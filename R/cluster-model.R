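#' Build an atomic cluster model
#'
#' A `cluster_model` is a tibble of atom sites — one row per atom — with
#' columns `label` (unique site identifier), `element` (chemical symbol),
#' `x`, `y`, `z` (Cartesian coordinates, Angstrom), `biso` (isotropic
#' displacement parameter, Angstrom^2) and `strand` (which DNA strand
#' coordinates the atom: `"A"`, `"B"`, `"both"` or `"none"`). An optional
#' `channel` column groups atoms into the axial Ag channels used in the
#' rotation analysis. It is the refinable object of the pipeline.
#'
#' @param sites Data frame with at least `element`, `x`, `y`, `z`. Missing
#'   `label` is auto-generated as element + index; missing `biso` defaults to
#'   0 (sharp pairs — broadening must be an explicit modelling choice);
#'   missing `strand` defaults to `"none"`.
#' @param name Free-text model name stored as an attribute.
#' @return A `cluster_model` tibble.
#' @examples
#' m <- cluster_model(data.frame(element = c("Ag", "Ag"),
#'                               x = c(0, 2.8), y = 0, z = 0))
#' m
#' @export
cluster_model <- function(sites, name = "model") {
  sites <- as_tibble(sites)
  required <- c("element", "x", "y", "z")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    abort(paste0("cluster_model needs column(s): ", paste(missing, collapse = ", ")),
          class = "clusterpdf_validation_error")
  }
  if (!("label" %in% names(sites))) {
    sites$label <- paste0(sites$element, seq_len(nrow(sites)))
  }
  if (!("biso" %in% names(sites))) sites$biso <- 0
  if (!("strand" %in% names(sites))) sites$strand <- "none"
  sites <- dplyr::relocate(sites, "label", "element", "x", "y", "z", "biso", "strand")
  out <- new_tibble(sites, name = name, class = "cluster_model")
  validate_cluster_model(out)
}

#' @rdname cluster_model
#' @param model Object to validate.
#' @export
validate_cluster_model <- function(model) {
  if (nrow(model) < 2) {
    abort("A cluster model needs at least 2 sites.",
          class = "clusterpdf_validation_error")
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("All coordinates must be finite.", class = "clusterpdf_validation_error")
  }
  if (any(model$biso < 0)) {
    abort("biso must be >= 0.", class = "clusterpdf_validation_error")
  }
  if (anyDuplicated(model$label)) {
    abort("Site labels must be unique within a model.",
          class = "clusterpdf_validation_error")
  }
  if (!all(.known_element(model$element))) {
    bad <- unique(model$element[!.known_element(model$element)])
    abort(paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "clusterpdf_validation_error")
  }
  ok_tags <- c("A", "B", "both", "none")
  if (!all(model$strand %in% ok_tags)) {
    abort('strand tags must be one of "A", "B", "both", "none".',
          class = "clusterpdf_validation_error")
  }
  model
}

model_name <- function(model) attr(model, "name") %||% "model"

#' Coordinate matrix of a cluster model
#'
#' @param model A [cluster_model()].
#' @return Numeric n x 3 matrix of Cartesian coordinates (Angstrom), row
#'   names set to site labels.
#' @export
coords <- function(model) {
  m <- as.matrix(model[, c("x", "y", "z")])
  rownames(m) <- model$label
  m
}

#' @rdname coords
#' @param xyz Numeric n x 3 matrix of replacement coordinates.
#' @export
set_coords <- function(model, xyz) {
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

#' Read an XYZ structure file
#'
#' Standard XYZ: an atom-count line, a comment line, then `element x y z`
#' rows. Coordinates are taken as Cartesian Angstrom; `biso` is set to 0 and
#' labels are auto-generated element + index.
#'
#' @param path Path to an XYZ file.
#' @param name Model name; defaults to the file name.
#' @return A [cluster_model()].
#' @export
read_xyz <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2]
  if (length(lines) < 3) {
    abort("XYZ file too short: need count line, comment line and atom rows.",
          class = "clusterpdf_parse_error")
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    abort("Malformed XYZ count line.", class = "clusterpdf_parse_error")
  }
  rows <- lines[3:length(lines)]
  if (length(rows) < n) {
    abort(sprintf("XYZ declares %d atoms but has %d rows.", n, length(rows)),
          class = "clusterpdf_parse_error")
  }
  rows <- rows[seq_len(n)]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 4
  if (any(bad)) {
    abort("Malformed XYZ atom row(s).", class = "clusterpdf_parse_error")
  }
  element <- vapply(parts, `[[`, character(1), 1)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), k)))
    if (anyNA(v)) abort("Non-numeric coordinate in XYZ file.",
                        class = "clusterpdf_parse_error")
    v
  }
  cluster_model(tibble(element = element, x = num(2), y = num(3), z = num(4)),
                name = name)
}

#' Write a cluster model as XYZ
#'
#' @param model A [cluster_model()].
#' @param path Output path.
#' @param comment Comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(model, path, comment = model_name(model)) {
  rows <- sprintf("%-2s %15.8f %15.8f %15.8f", model$element,
                  model$x, model$y, model$z)
  writeLines(c(as.character(nrow(model)), comment, rows), path)
  invisible(path)
}

#' Read a strand-coordination map
#'
#' CSV with columns `label`, `strand_tag`; tags must be `"A"`, `"B"`,
#' `"both"` or `"none"`. Ag sites in DNA-stabilized clusters are coordinated
#' entirely or partially by one of the two DNA strands; the assignment comes
#' from inspection of the crystal contacts and is supplied as input.
#'
#' @param path CSV path.
#' @return Named character vector mapping label to strand tag.
#' @export
read_strand_map <- function(path) {
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                 strip.white = TRUE)
  if (!all(c("label", "strand_tag") %in% names(df))) {
    abort("Strand map needs columns 'label' and 'strand_tag'.",
          class = "clusterpdf_parse_error")
  }
  ok_tags <- c("A", "B", "both", "none")
  if (!all(df$strand_tag %in% ok_tags)) {
    bad <- unique(df$strand_tag[!df$strand_tag %in% ok_tags])
    abort(paste0("Unknown strand tag(s): ", paste(bad, collapse = ", ")),
          class = "clusterpdf_validation_error")
  }
  if (anyDuplicated(df$label)) {
    abort("Duplicate labels in strand map.", class = "clusterpdf_validation_error")
  }
  setNames(df$strand_tag, df$label)
}

#' Apply a strand map to a model
#'
#' @param model A [cluster_model()].
#' @param map Named vector from [read_strand_map()].
#' @return The model with its `strand` column filled in.
#' @export
apply_strand_map <- function(model, map) {
  missing <- setdiff(model$label, names(map))
  if (length(missing) > 0) {
    abort(paste0("Strand map has no entry for label(s): ",
                 paste(missing, collapse = ", ")),
          class = "clusterpdf_key_error")
  }
  model$strand <- unname(map[model$label])
  validate_cluster_model(model)
}
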