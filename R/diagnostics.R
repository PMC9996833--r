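# ---------------------------------------------------------------------------
# solution diagnostics
# ---------------------------------------------------------------------------

#' M diagnostic of a NOF solution
#'
#' Locates the least strongly occupied NO (LSONO: occupation farthest from 1
#' within the strongly occupied block, index <= N_II/2) and the least weakly
#' occupied NO (LWONO: occupation farthest from 0 above N_Omega) and
#' evaluates `M = (1 - n_LSONO) + n_LWONO`. Integer occupations give M = 0; a
#' perfect-pairing diradical (both occupations 1/2) gives M = 1. Values below
#' `threshold` (default 0.1) are classified dynamic-dominated, at or above it
#' static-dominated. Ties are broken by the lowest orbital index.
#'
#' @param state a `nof_state` (or any list with `n` and `scheme`).
#' @param threshold regime boundary.
#' @return object of class `"m_diagnostic"` with `M`, the LSONO/LWONO indices
#'   and occupancies, and the `regime` label.
#' @export
m_diagnostic <- function(state, threshold = 0.1) {
  scheme <- state$scheme
  if (scheme$n_pairs == 0)
    stop("M diagnostic undefined: system has no paired-electron block (N_II = 0)")
  m <- scheme$n_coupled
  reg <- scheme$region[seq_len(m)]
  n <- state$n
  strong <- which(reg == "strong")
  weak <- which(reg == "weak")
  ls_rel <- which.min(n[strong])     # farthest from 1; first index on ties
  lw_rel <- which.max(n[weak])       # farthest from 0; first index on ties
  lsono <- strong[ls_rel]
  lwono <- weak[lw_rel]
  M <- (1 - n[lsono]) + n[lwono]
  structure(list(M = M, lsono_index = lsono, lwono_index = lwono,
                 lsono_occ = n[lsono], lwono_occ = n[lwono],
                 threshold = threshold,
                 regime = if (M < threshold) "dynamic-dominated"
                          else "static-dominated"),
            class = "m_diagnostic")
}

#' @export
print.m_diagnostic <- function(x, ...) {
  cat(sprintf("M diagnostic: %.4f (%s, threshold %.2f)\n", x$M, x$regime,
              x$threshold))
  cat(sprintf("  LSONO: orbital %d, n = %.6f\n", x$lsono_index, x$lsono_occ))
  cat(sprintf("  LWONO: orbital %d, n = %.6f\n", x$lwono_index, x$lwono_occ))
  invisible(x)
}

#' Adiabatic spin-gap table
#'
#' Collects total energies per multiplicity and reports the singlet-triplet
#' gap `ST = E(singlet) - E(triplet)` and quintet-triplet gap
#' `QT = E(quintet) - E(triplet)` in kcal/mol (1 hartree = 627.509 kcal/mol).
#' Positive values mean the triplet lies lower.
#'
#' @param states list of solved `nof_state`s (adiabatic convention: each at
#'   its own structure).
#' @return object of class `"gap_table"`: per-multiplicity energies (hartree)
#'   and `st_gap`/`qt_gap` (kcal/mol, `NA` when a leg is missing).
#' @export
gap_table <- function(states) {
  mult <- vapply(states, function(s) s$system$multiplicity, integer(1))
  e <- vapply(states, function(s) s$energy$e_total, numeric(1))
  conv <- vapply(states, function(s) isTRUE(s$converged), logical(1))
  if (!any(mult == 3))
    stop("gap table requires a triplet (multiplicity 3) reference state")
  et <- e[match(3, mult)]
  st <- if (any(mult == 1)) (e[match(1, mult)] - et) * HARTREE_TO_KCAL else NA_real_
  qt <- if (any(mult == 5)) (e[match(5, mult)] - et) * HARTREE_TO_KCAL else NA_real_
  structure(list(multiplicity = mult, e_total = e, converged = conv,
                 st_gap = st, qt_gap = qt),
            class = "gap_table")
}

#' @export
print.gap_table <- function(x, digits = 0, ...) {
  cat("Spin-state energies (hartree):\n")
  for (i in seq_along(x$multiplicity))
    cat(sprintf("  2S+1 = %d   E = %16.6f%s\n", x$multiplicity[i],
                x$e_total[i], if (x$converged[i]) "" else "  [not converged]"))
  if (!is.na(x$st_gap))
    cat(sprintf("  ST gap: %+.*f kcal/mol\n", digits, x$st_gap))
  if (!is.na(x$qt_gap))
    cat(sprintf("  QT gap: %+.*f kcal/mol\n", digits, x$qt_gap))
  invisible(x)
}

#' 1RDM trace check
#'
#' The pairing sum rules make the 1RDM trace equal the electron count by
#' construction; this reports the deviation `|sum(2 n_p) - N|` (singles carry
#' n = 1/2) and passes when it is below `tol`.
#'
#' @param state a `nof_state`.
#' @param tol pass tolerance.
#' @return list with `trace`, `expected`, `deviation`, `pass`.
#' @export
trace_check <- function(state, tol = 1e-10) {
  tr <- sum(2 * state$n)
  dev <- abs(tr - state$system$n_electrons)
  list(trace = tr, expected = state$system$n_electrons, deviation = dev,
       pass = dev < tol)
}

# ---------------------------------------------------------------------------
# orbital export: molden and cube
# ---------------------------------------------------------------------------

#' Export natural orbitals to a molden file
#'
#' Writes geometry, the Gaussian basis and the selected NOs with their
#' (per-spin doubled) occupation numbers. Only s/p/d shells are supported;
#' spherical d functions are declared with the `[5D]` flag.
#'
#' @param state a `nof_state`.
#' @param path output file.
#' @param selection `"frontier"` (strong/single/weak orbitals around the
#'   occupation edge, up to 6), `"all"`, or an integer index vector.
#' @return invisibly, the indices written.
#' @export
export_orbitals <- function(state, path, selection = "all") {
  scheme <- state$scheme
  m <- scheme$n_coupled
  idx <- if (is.numeric(selection)) {
    as.integer(selection)
  } else if (identical(selection, "all")) {
    seq_len(ncol(state$C))
  } else if (identical(selection, "frontier")) {
    reg <- scheme$region
    lo <- max(1L, scheme$n_pairs - 1L)
    hi <- min(ncol(state$C), scheme$n_subspaces + min(2L, scheme$n_basis))
    lo:hi
  } else stop("unknown orbital selection")
  nocc <- c(state$n, numeric(ncol(state$C) - m))
  geom <- state$system$atoms
  z <- element_number(geom$symbol)
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("[Molden Format]")
  wr("[Title]")
  wr("natural orbitals (per-spin occupations doubled to total)")
  wr("[Atoms] Angs")
  for (i in seq_len(nrow(geom)))
    wr("%-3s %4d %4d %15.8f %15.8f %15.8f", geom$symbol[i], i, z[i],
       geom$x[i], geom$y[i], geom$z[i])
  wr("[5D]")
  wr("[GTO]")
  bas <- state$ao$basis
  for (ia in seq_len(nrow(geom))) {
    wr("%d 0", ia)
    for (sh in bas$shells) {
      if (sh$atom != ia) next
      wr("%s %d 1.00", c("s", "p", "d")[sh$l + 1L], length(sh$exp))
      for (k in seq_along(sh$exp))
        wr("%20.10e %20.10e", sh$exp[k], sh$coef[k])
    }
    wr("")
  }
  wr("[MO]")
  for (p in idx) {
    wr(" Sym= A")
    wr(" Ene= %.6f", 0)
    wr(" Spin= Alpha")
    wr(" Occup= %.8f", 2 * nocc[p])
    for (mu in seq_len(nrow(state$C)))
      wr(" %4d %20.12e", mu, state$C[mu, p])
  }
  invisible(idx)
}

#' Read orbital coefficients back from a molden file
#'
#' Minimal reader for files written by [export_orbitals()]: returns the MO
#' coefficient matrix and total occupations.
#'
#' @param path molden file path.
#' @return list with `C` (coefficients, columns = orbitals) and `occupations`.
#' @export
read_molden_orbitals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mo_at <- grep("^\\[MO\\]", lines)
  if (length(mo_at) != 1) stop("malformed molden file: no [MO] section")
  lines <- lines[(mo_at + 1):length(lines)]
  cols <- list()
  occs <- numeric(0)
  cur <- numeric(0)
  for (ln in lines) {
    if (grepl("Occup=", ln)) {
      occs <- c(occs, as.numeric(sub(".*Occup=\\s*", "", ln)))
      if (length(cur)) cols[[length(cols) + 1L]] <- cur
      cur <- numeric(0)
    } else if (grepl("^\\s*\\d+\\s+[-0-9.eE+]+\\s*$", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur[as.integer(parts[1])] <- as.numeric(parts[2])
    }
  }
  if (length(cur)) cols[[length(cols) + 1L]] <- cur
  list(C = do.call(cbind, cols), occupations = occs)
}

#' Write a natural orbital to a Gaussian cube file
#'
#' Evaluates the orbital on a regular grid and writes the standard cube
#' layout (bohr units).
#'
#' @param state a `nof_state`.
#' @param orbital orbital index.
#' @param path output file.
#' @param npts grid points per axis.
#' @param margin box margin (bohr) beyond the nuclear extent.
#' @return invisibly, a list with the grid values (array) for reuse.
#' @export
write_cube <- function(state, orbital, path, npts = 40, margin = 4) {
  geom <- state$system$atoms
  xyz <- as.matrix(geom[, c("x", "y", "z")]) * ANGSTROM_TO_BOHR
  z <- element_number(geom$symbol)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  step <- (hi - lo) / (npts - 1)
  gx <- seq(lo[1], hi[1], length.out = npts)
  gy <- seq(lo[2], hi[2], length.out = npts)
  gz <- seq(lo[3], hi[3], length.out = npts)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  bas <- state$ao$basis
  mo <- ao_values(bas, state$ao$ao_norms, pts) %*% state$C[, orbital]
  arr <- array(mo, dim = c(npts, npts, npts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("cube file: natural orbital",
               sprintf("orbital %d", orbital)), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", nrow(geom), lo[1], lo[2], lo[3]), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", npts, step[1], 0, 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", npts, 0, step[2], 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", npts, 0, 0, step[3]), con)
  for (i in seq_len(nrow(geom)))
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z[i], as.numeric(z[i]),
                       xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
  for (ix in seq_len(npts)) for (iy in seq_len(npts)) {
    row <- arr[ix, iy, ]
    writeLines(paste(sprintf("%13.5e", row), collapse = " "), con)
  }
  invisible(list(values = arr, step = step, origin = lo))
}
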