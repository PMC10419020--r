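#' Read an XYZ geometry file
#'
#' Parses a standard XYZ file (atom count line, free-text comment line, then
#' one `element x y z` row per atom, coordinates in Angstrom) into an atom
#' table. Molecule membership is unassigned until [annotate()] attaches a
#' sidecar annotation.
#'
#' @param path Path to an XYZ file.
#' @return A tibble of class `cd_atoms` with columns `index` (1-based, file
#'   order), `element`, `x`, `y`, `z`, and the comment line stored in the
#'   `"comment"` attribute.
#' @seealso [write_xyz()], [annotate()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("3", "water", "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"), f)
#' read_xyz(f)
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) {
    abort(sprintf("XYZ file '%s' has fewer than 2 lines", path))
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) {
    abort(sprintf("line 1 of '%s': malformed atom count '%s'", path, lines[1]))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    abort(sprintf(
      "'%s': header declares %d atoms but %d atom rows found", path, n, length(body)
    ))
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(fields, length, integer(1)) < 4L)
  if (length(bad)) {
    abort(sprintf("line %d of '%s': expected 'element x y z'", bad[1] + 2L, path))
  }
  element <- vapply(fields, `[[`, character(1), 1L)
  coords <- lapply(2:4, function(k) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), k)))
  })
  bad <- which(is.na(coords[[1]]) | is.na(coords[[2]]) | is.na(coords[[3]]))
  if (length(bad)) {
    abort(sprintf("line %d of '%s': non-numeric coordinate", bad[1] + 2L, path))
  }
  atoms <- tibble::tibble(
    index = seq_len(n),
    element = element,
    x = coords[[1]], y = coords[[2]], z = coords[[3]]
  )
  attr(atoms, "comment") <- lines[2]
  class(atoms) <- c("cd_atoms", class(atoms))
  atoms
}

#' Write an atom table to an XYZ file
#'
#' Inverse of [read_xyz()]: round-tripping preserves atom order, elements and
#' coordinates to the printed precision.
#'
#' @param atoms Atom tibble with columns `element`, `x`, `y`, `z`.
#' @param path Output path.
#' @param comment Comment line; defaults to the table's `"comment"` attribute
#'   or an empty string.
#' @param digits Decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = NULL, digits = 8) {
  comment <- comment %||% attr(atoms, "comment") %||% ""
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  lines <- c(
    as.character(nrow(atoms)),
    comment,
    sprintf(fmt, atoms$element, atoms$x, atoms$y, atoms$z)
  )
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
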