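# ---------------------------------------------------------------------------
# basis construction: shells for the integral engine, cartesian -> spherical
# ---------------------------------------------------------------------------

.lookup_basis <- function(basis) {
  b <- .basis_library[[tolower(basis)]]
  if (is.null(b)) stop("unknown basis set: ", basis,
                       " (available: ", paste(names(.basis_library),
                                              collapse = ", "), ")")
  b
}

# assemble the shell list for a geometry; coordinates converted to bohr
build_basis <- function(geometry, basis) {
  bdef <- .lookup_basis(basis)
  shells <- list()
  shell_atom <- integer(0)
  for (ia in seq_len(nrow(geometry))) {
    el <- geometry$symbol[ia]
    eldef <- bdef[[el]]
    if (is.null(eldef))
      stop(sprintf("basis '%s' has no parameters for element %s", basis, el))
    for (sh in eldef) {
      if (sh$l > 2L)
        stop("integral engine supports s, p and d shells only")
      shells[[length(shells) + 1L]] <- list(
        l = sh$l, atom = ia,
        center = as.numeric(geometry[ia, c("x", "y", "z")]) * ANGSTROM_TO_BOHR,
        exp = sh$exp, coef = sh$coef)
      shell_atom <- c(shell_atom, ia)
    }
  }
  l <- vapply(shells, `[[`, integer(1), "l")
  n_cart <- sum(((l + 1L) * (l + 2L)) %/% 2L)
  n_sph <- sum(.n_sph(l))
  # cartesian -> spherical transformation (block diagonal over shells);
  # within-combination ratios in raw cartesians, overall norms fixed later
  Tm <- matrix(0, n_cart, n_sph)
  ao_atom <- integer(n_sph)
  ao_label <- character(n_sph)
  ic <- 0L; is <- 0L
  p_labels <- c("px", "py", "pz")
  d_labels <- c("dz2", "dxz", "dyz", "dx2y2", "dxy")
  for (k in seq_along(shells)) {
    lk <- l[k]
    if (lk == 0L) {
      Tm[ic + 1L, is + 1L] <- 1
      lab <- "s"
    } else if (lk == 1L) {
      Tm[ic + 1:3, is + 1:3] <- diag(3)
      lab <- p_labels
    } else {
      # cart order: xx, xy, xz, yy, yz, zz
      blk <- matrix(0, 6, 5)
      blk[6, 1] <- 1; blk[1, 1] <- -0.5; blk[4, 1] <- -0.5  # z2
      blk[3, 2] <- 1                                        # xz
      blk[5, 3] <- 1                                        # yz
      blk[1, 4] <- 1; blk[4, 4] <- -1                       # x2-y2
      blk[2, 5] <- 1                                        # xy
      Tm[ic + 1:6, is + 1:5] <- blk
      lab <- d_labels
    }
    m <- .n_sph(lk)
    ao_atom[is + seq_len(m)] <- shells[[k]]$atom
    ao_label[is + seq_len(m)] <- paste0(geometry$symbol[shells[[k]]$atom], lab)
    ic <- ic + ((lk + 1L) * (lk + 2L)) %/% 2L
    is <- is + m
  }
  cpp <- list(
    l = l,
    center = do.call(rbind, lapply(shells, `[[`, "center")),
    exponents = lapply(shells, `[[`, "exp"),
    coefficients = lapply(shells, `[[`, "coef"))
  list(shells = shells, cpp = cpp, cart_to_sph = Tm,
       n_cart = n_cart, n_basis = n_sph,
       ao_atom = ao_atom, ao_label = ao_label)
}

#' Count spatial basis functions for a system
#'
#' Uses spherical-harmonic (pure) angular functions throughout. For basis sets
#' whose exponents are bundled the count comes from the shell list; otherwise
#' the published contracted shell composition is used (this is how the
#' 465-function count of the FeN4C20H12 / cc-pVDZ combination is obtained).
#'
#' @param system a [molecular_system()].
#' @param basis basis set name (e.g. `"sto-3g"`, `"6-31g"`, `"cc-pvdz"`).
#' @return integer number of spherical basis functions N_B.
#' @export
count_basis_functions <- function(system, basis) {
  stopifnot(inherits(system, "molecular_system"))
  key <- tolower(basis)
  bdef <- .basis_library[[key]]
  comp <- .basis_compositions[[key]]
  total <- 0L
  for (el in system$atoms$symbol) {
    if (!is.null(bdef) && !is.null(bdef[[el]])) {
      total <- total + sum(.n_sph(vapply(bdef[[el]], `[[`, integer(1), "l")))
    } else if (!is.null(comp) && !is.null(comp[[el]])) {
      cnt <- comp[[el]]
      total <- total + sum(cnt * .n_sph(seq_along(cnt) - 1L))
    } else {
      stop(sprintf("basis '%s' not available for element %s", basis, el))
    }
  }
  total
}

# evaluate all (normalized, spherical) AOs at points (bohr); rows = points
ao_values <- function(bas, norms, points) {
  points <- matrix(points, ncol = 3)
  np <- nrow(points)
  vals <- matrix(0, np, bas$n_cart)
  ic <- 0L
  for (sh in bas$shells) {
    l <- sh$l
    dx <- points[, 1] - sh$center[1]
    dy <- points[, 2] - sh$center[2]
    dz <- points[, 3] - sh$center[3]
    r2 <- dx^2 + dy^2 + dz^2
    radial <- rep(0, np)
    dfact <- if (l > 0) prod(seq(2 * l - 1, 1, by = -2)) else 1
    for (k in seq_along(sh$exp)) {
      a <- sh$exp[k]
      pn <- (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(dfact)
      radial <- radial + sh$coef[k] * pn * exp(-a * r2)
    }
    comps <- switch(l + 1L,
      list(c(0L, 0L, 0L)),
      list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
      list(c(2L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L),
           c(0L, 2L, 0L), c(0L, 1L, 1L), c(0L, 0L, 2L)))
    for (cc in comps) {
      ic <- ic + 1L
      vals[, ic] <- radial * dx^cc[1] * dy^cc[2] * dz^cc[3]
    }
  }
  sweep(vals %*% bas$cart_to_sph, 2, norms, `*`)
}
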