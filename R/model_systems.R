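# ---------------------------------------------------------------------------
# desk-scale model systems, dissociation scans and oracle wrappers
# ---------------------------------------------------------------------------

#' Build a named desk-scale fixture
#'
#' Geometries are built from internal coordinates: `H2(R)` places the atoms
#' at `(0, 0, +/- R/2)`; `H4_chain(R)` is a collinear chain with spacing `R`;
#' `LiH` and `H2O` use standard near-equilibrium structures.
#'
#' @param name one of `"H"`, `"H2"`, `"H4_chain"`, `"LiH"`, `"H2O"`.
#' @param R bond length / chain spacing in Angstrom (fixtures with a length
#'   parameter).
#' @param basis basis set name attached to the fixture.
#' @return list with `name`, `system` (a [molecular_system()]), `basis`.
#' @export
make_fixture <- function(name, R = 0.74, basis = "sto-3g") {
  geom <- switch(name,
    H = as_geometry("H", c(0, 0, 0)),
    H2 = as_geometry(c("H", "H"), rbind(c(0, 0, -R / 2), c(0, 0, R / 2))),
    H4_chain = as_geometry(rep("H", 4),
                           cbind(0, 0, (0:3) * R)),
    LiH = as_geometry(c("Li", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5957))),
    H2O = as_geometry(c("O", "H", "H"),
                      rbind(c(0, 0, 0.1173),
                            c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692))),
    stop("unknown fixture name: ", name))
  multiplicity <- if (name == "H") 2L else 1L
  list(name = name,
       system = molecular_system(geom, charge = 0,
                                 multiplicity = multiplicity),
       basis = basis)
}

#' Exact (FCI) reference for a fixture
#'
#' Full diagonalization in the fixture's basis; the reference energy and
#' natural occupations against which the pair functionals are validated.
#'
#' @param fixture a [make_fixture()] result (or compatible list).
#' @param ao optional precomputed [ao_integrals()].
#' @return list with `e_total`, `e_elec` and per-spin natural `occupations`.
#' @export
fci_oracle <- function(fixture, ao = NULL) {
  if (is.null(ao)) ao <- ao_integrals(fixture$system, fixture$basis)
  fci(ao, fixture$system)
}

#' Dissociation scan of a fixture family
#'
#' Converges the functional at each grid distance, warm-starting each point
#' from the previous one, and reports Mulliken fragment electron populations
#' at the largest separation. Non-converged points are flagged and the scan
#' continues.
#'
#' @param name fixture family (`"H2"` or `"H4_chain"`).
#' @param R_grid increasing vector of distances (Angstrom).
#' @param functional functional label.
#' @param basis basis set name.
#' @param coupling pairing coupling.
#' @param ... further arguments to [nof()].
#' @return object of class `"dissociation_scan"`: data.frame `curve`
#'   (R, e_total, converged) plus `fragment_populations` at the last R.
#' @export
dissociation_scan <- function(name, R_grid, functional = "PNOF5",
                              basis = "sto-3g", coupling = "perfect", ...) {
  stopifnot(length(R_grid) >= 1)
  curve <- data.frame(R = R_grid, e_total = NA_real_, converged = NA)
  donor <- NULL
  last_fit <- NULL
  for (i in seq_along(R_grid)) {
    fx <- make_fixture(name, R = R_grid[i], basis = basis)
    fit <- try(nof(fx$system, fx$basis, functional = functional,
                   coupling = coupling, warm_from = donor, ...),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      curve$converged[i] <- FALSE
      donor <- NULL
      next
    }
    curve$e_total[i] <- fit$energy$e_total
    curve$converged[i] <- fit$converged
    donor <- fit
    last_fit <- fit
  }
  pops <- if (!is.null(last_fit)) mulliken_populations(last_fit) else NULL
  structure(list(name = name, functional = functional, curve = curve,
                 fragment_populations = pops, last_fit = last_fit),
            class = "dissociation_scan")
}

#' Mulliken electron populations per atom
#'
#' @param state a solved `nof_state`.
#' @return named numeric vector of electron populations.
#' @export
mulliken_populations <- function(state) {
  m <- state$scheme$n_coupled
  Cc <- state$C[, seq_len(m), drop = FALSE]
  D <- Cc %*% (2 * state$n * t(Cc))
  ds <- diag(D %*% state$ao$S)
  atoms <- state$ao$basis$ao_atom
  pop <- tapply(ds, atoms, sum)
  out <- as.numeric(pop)
  names(out) <- state$system$atoms$symbol[as.integer(names(pop))]
  out
}

#' Load an external XYZ geometry with optional FeP sanity checks
#'
#' Parses an XYZ file; when `tag = "FeP"` the structure is checked against
#' the iron(II) porphyrin fingerprints: 37 atoms, 186 electrons, and the
#' per-multiplicity Fe-N distance (1.979 A singlet, 1.976 A triplet, 2.053 A
#' quintet, each +/- 0.01 A). Failed checks raise warnings, not errors.
#'
#' @param path XYZ file.
#' @param tag `NULL` or `"FeP"`.
#' @param multiplicity multiplicity used to pick the reference Fe-N distance.
#' @return the geometry data.frame.
#' @export
load_external_geometry <- function(path, tag = NULL, multiplicity = 3) {
  geom <- read_xyz(path)
  if (identical(tag, "FeP")) {
    if (nrow(geom) != 37)
      warning(sprintf("FeP check: expected 37 atoms, found %d", nrow(geom)))
    nel <- sum(element_number(geom$symbol))
    if (nel != 186)
      warning(sprintf("FeP check: expected 186 electrons, found %d", nel))
    fe <- which(geom$symbol == "Fe")
    nn <- which(geom$symbol == "N")
    if (length(fe) == 1 && length(nn) >= 1) {
      dists <- vapply(nn, function(j) atom_distance(geom, fe, j), numeric(1))
      ref <- c(`1` = 1.979, `3` = 1.976, `5` = 2.053)[as.character(multiplicity)]
      if (!is.na(ref)) {
        near <- sort(dists)[seq_len(min(4, length(dists)))]
        if (any(abs(near - ref) > 0.01))
          warning(sprintf(
            "FeP check: Fe-N distances (%s A) deviate from the reference %.3f A",
            paste(sprintf("%.3f", near), collapse = ", "), ref))
      }
    } else {
      warning("FeP check: could not locate a unique Fe and its N neighbours")
    }
  }
  geom
}
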