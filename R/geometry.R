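# geometries are data.frames with columns symbol, x, y, z (Angstrom)

as_geometry <- function(symbols, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(symbols) == nrow(xyz))
  data.frame(symbol = as.character(symbols),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Read an XYZ geometry file
#'
#' Accepts both the standard XYZ layout (atom count line + comment line) and a
#' bare list of `symbol x y z` lines. Coordinates are in Angstrom.
#'
#' @param path path to the file.
#' @return a geometry data.frame with columns `symbol`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty geometry file: ", path)
  first <- strsplit(lines[1], "\\s+")[[1]]
  is_atom_line <- function(ln) {
    p <- strsplit(ln, "\\s+")[[1]]
    length(p) == 4 && !anyNA(suppressWarnings(as.numeric(p[2:4])))
  }
  if (length(first) == 1 && !is.na(suppressWarnings(as.integer(first)))) {
    n <- as.integer(first)
    body <- lines[-1]
    # a comment line may or may not be present
    if (length(body) >= 1 && !is_atom_line(body[1]))
      body <- body[-1]
    if (length(body) < n) stop("malformed XYZ file: fewer atoms than declared")
    lines <- body[seq_len(n)]
  }
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, length, integer(1)) != 4
  if (any(bad)) stop("malformed geometry line(s): ",
                     paste(lines[bad], collapse = "; "))
  symbols <- vapply(parts, `[[`, character(1), 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords)) stop("non-numeric coordinates in geometry file")
  element_number(symbols) # validates symbols
  as_geometry(symbols, coords)
}

#' Write an XYZ geometry file
#'
#' @param geometry a geometry data.frame (`symbol`, `x`, `y`, `z` in Angstrom).
#' @param path output path.
#' @param comment second-line comment.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  lines <- c(nrow(geometry), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     geometry$symbol, geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}

# nuclear repulsion energy in hartree from an Angstrom geometry
nuclear_repulsion <- function(geometry) {
  n <- nrow(geometry)
  if (n < 2) return(0)
  z <- element_number(geometry$symbol)
  xyz <- as.matrix(geometry[, c("x", "y", "z")]) * ANGSTROM_TO_BOHR
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      e <- e + z[i] * z[j] / r
    }
  }
  e
}

# interatomic distance in Angstrom
atom_distance <- function(geometry, i, j) {
  sqrt(sum((as.numeric(geometry[i, c("x", "y", "z")]) -
            as.numeric(geometry[j, c("x", "y", "z")]))^2))
}
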