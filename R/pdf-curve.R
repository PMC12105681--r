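#' PDF and reciprocal-space curve containers
#'
#' A `pdf_curve` is a tibble with columns `r` (uniform ascending grid,
#' Angstrom) and `g` (reduced-PDF values G(r), arbitrary units); an
#' `iq_curve` holds `q` (ascending, 1/Angstrom) and `y` (reduced structure
#' function F(Q) or scaled intensity). Provenance (source tag, Qmax,
#' background-subtraction note) travels in a `meta` attribute.
#'
#' @param r,g Grid and values for `pdf_curve`.
#' @param q,y Grid and values for `iq_curve`.
#' @param meta Named list of provenance metadata.
#' @return A `pdf_curve` / `iq_curve` tibble.
#' @examples
#' pdf_curve(seq(0, 10, 0.01), sin(seq(0, 10, 0.01)))
#' @export
pdf_curve <- function(r, g, meta = list()) {
  if (length(r) != length(g)) {
    abort("r and g must have equal length.", class = "clusterpdf_validation_error")
  }
  if (any(r < 0)) {
    abort("r must be >= 0.", class = "clusterpdf_validation_error")
  }
  if (length(r) >= 2) {
    dr <- diff(r)
    if (any(dr <= 0)) {
      abort("r must be strictly increasing.", class = "clusterpdf_validation_error")
    }
    if (max(dr) - min(dr) > 1e-9) {
      abort("r grid must be uniform (spacing constant to 1e-9).",
            class = "clusterpdf_validation_error")
    }
  }
  new_tibble(tibble(r = as.numeric(r), g = as.numeric(g)),
             meta = meta, class = "pdf_curve")
}

#' @rdname pdf_curve
#' @export
iq_curve <- function(q, y, meta = list()) {
  if (length(q) != length(y)) {
    abort("q and y must have equal length.", class = "clusterpdf_validation_error")
  }
  if (any(q < 0)) {
    abort("q must be >= 0.", class = "clusterpdf_validation_error")
  }
  if (length(q) >= 2 && any(diff(q) <= 0)) {
    abort("q must be strictly increasing.", class = "clusterpdf_validation_error")
  }
  new_tibble(tibble(q = as.numeric(q), y = as.numeric(y)),
             meta = meta, class = "iq_curve")
}

curve_meta <- function(curve) attr(curve, "meta") %||% list()

grid_step <- function(r) if (length(r) < 2) NA_real_ else (r[length(r)] - r[1]) / (length(r) - 1)

#' Default real-space grid
#'
#' Uniform grid from 0 to 30 Angstrom in 0.01 Angstrom steps: covers the
#' region where dissolved-cluster PDFs are featureless (beyond ~15 Angstrom)
#' with margin.
#'
#' @param rmin,rmax,dr Grid bounds and step, Angstrom.
#' @return Numeric vector.
#' @export
default_rgrid <- function(rmin = 0, rmax = 30, dr = 0.01) seq(rmin, rmax, by = dr)

.read_two_column <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2) {
    abort(sprintf("%s file needs at least 2 data rows.", what),
          class = "clusterpdf_parse_error")
  }
  parts <- strsplit(lines, "[\\s,]+", perl = TRUE)
  if (any(vapply(parts, length, integer(1)) < 2)) {
    abort(sprintf("Malformed row in %s file.", what),
          class = "clusterpdf_parse_error")
  }
  a <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
  b <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(a) || anyNA(b)) {
    abort(sprintf("Non-numeric token in %s file.", what),
          class = "clusterpdf_parse_error")
  }
  list(a = a, b = b)
}

#' Read and write two-column G(r) text files
#'
#' The `.gr` dialect follows the dominant community convention for PDF data:
#' comment lines beginning `#`, then whitespace-separated `r G(r)` pairs.
#' A write-then-read round trip reproduces `r` and `g` to 1e-6.
#'
#' @param path File path.
#' @param meta Metadata list attached to the returned curve.
#' @return [pdf_curve()] for `read_gr`; `path` invisibly for `write_gr`.
#' @export
read_gr <- function(path, meta = list(source = basename(path))) {
  cols <- .read_two_column(path, ".gr")
  if (any(diff(cols$a) <= 0)) {
    abort("r values in .gr file must be strictly increasing.",
          class = "clusterpdf_validation_error")
  }
  pdf_curve(cols$a, cols$b, meta = meta)
}

#' @rdname read_gr
#' @param curve A [pdf_curve()].
#' @export
write_gr <- function(curve, path) {
  meta <- curve_meta(curve)
  header <- c("# G(r) written by clusterpdf",
              if (length(meta) > 0)
                paste0("# ", names(meta), ": ",
                       vapply(meta, function(x) paste(format(x), collapse = " "),
                              character(1))))
  writeLines(c(header, sprintf("%.8f %.10g", curve$r, curve$g)), path)
  invisible(path)
}

#' Read and write two-column F(Q) text files
#'
#' Same dialect as [read_gr()] but in reciprocal space (`q` in 1/Angstrom).
#'
#' @inheritParams read_gr
#' @return [iq_curve()] for `read_fq`; `path` invisibly for `write_fq`.
#' @export
read_fq <- function(path, meta = list(source = basename(path))) {
  cols <- .read_two_column(path, ".fq")
  if (any(diff(cols$a) <= 0)) {
    abort("Q values in .fq file must be strictly increasing.",
          class = "clusterpdf_validation_error")
  }
  iq_curve(cols$a, cols$b, meta = meta)
}

#' @rdname read_fq
#' @param curve An [iq_curve()].
#' @export
write_fq <- function(curve, path) {
  writeLines(c("# F(Q) written by clusterpdf",
               sprintf("%.8f %.10g", curve$q, curve$y)), path)
  invisible(path)
}
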