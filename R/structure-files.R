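#' Extract an atom subset from a PDB or mmCIF file
#'
#' Reads a crystal-structure file and returns the matching atoms as a
#' [cluster_model()], coordinates in Cartesian Angstrom. Typical uses are
#' pulling the Ag16Cl2 metal/halide core out of a deposited
#' DNA-nanocluster structure (`elements = c("Ag", "Cl")`, 18 sites) or the
#' DNA scaffold (`chains =` the nucleic-acid chain identifiers).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param elements Character vector of element symbols to keep, or `NULL`.
#' @param chains Character vector of chain identifiers to keep, or `NULL`.
#'   When both selectors are given, atoms must match both.
#' @param name Model name.
#' @return A [cluster_model()] with atoms in file order.
#' @export
extract_subset <- function(path, elements = NULL, chains = NULL,
                           name = basename(path)) {
  if (is.null(elements) && is.null(chains)) {
    abort("Give at least one selector: elements or chains.",
          class = "clusterpdf_validation_error")
  }
  ext <- tolower(tools::file_ext(path))
  atoms <- tryCatch({
    if (ext %in% c("cif", "mmcif")) {
      bio3d::read.cif(path, verbose = FALSE)$atom
    } else {
      bio3d::read.pdb(path, verbose = FALSE)$atom
    }
  }, error = function(e) {
    abort(paste0("Could not parse structure file: ", conditionMessage(e)),
          class = "clusterpdf_parse_error")
  })
  elem <- .normalise_element(atoms$elesy, atoms$elety)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(elements)) keep <- keep & elem %in% elements
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  if (!any(keep)) {
    abort("Selection matched no atoms.", class = "clusterpdf_empty_selection_error")
  }
  atoms <- atoms[keep, , drop = FALSE]
  elem <- elem[keep]
  cluster_model(
    tibble(element = elem,
           x = as.numeric(atoms$x),
           y = as.numeric(atoms$y),
           z = as.numeric(atoms$z),
           label = paste0(elem, seq_along(elem))),
    name = name
  )
}

# Element symbol from the PDB/mmCIF element column, falling back to the atom
# name when the element field is blank (common in minimal files).
.normalise_element <- function(elesy, elety) {
  e <- trimws(as.character(elesy))
  fallback <- is.na(e) | !nzchar(e)
  if (any(fallback)) {
    guess <- gsub("[^A-Za-z].*$", "", trimws(as.character(elety[fallback])))
    e[fallback] <- guess
  }
  # PDB element fields are upper case ("AG", "CL"); symbols are title case.
  paste0(toupper(substring(e, 1, 1)), tolower(substring(e, 2)))
}
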