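# ---------------------------------------------------------------------------
# molecular system: electron-count bookkeeping for the spin multiplet
# ---------------------------------------------------------------------------

#' Build a molecular system with multiplet electron bookkeeping
#'
#' A state with total spin S is treated as a mixed state (multiplet) of highest
#' multiplicity 2S + 1. `N_I = multiplicity - 1` electrons are single
#' (spin-defining) electrons; the remaining `N_II = N - N_I` electrons are spin
#' paired.
#'
#' @param geometry geometry data.frame (`symbol`, `x`, `y`, `z` in Angstrom) as
#'   from [read_xyz()], or a character vector of element symbols when only
#'   electron counting is needed (no coordinates; the nuclear repulsion energy
#'   is then `NA`).
#' @param charge total molecular charge.
#' @param multiplicity spin multiplicity 2S + 1 (>= 1).
#' @return an object of class `"molecular_system"` with fields `atoms`,
#'   `charge`, `multiplicity`, `n_electrons`, `n_single` (N_I), `n_paired`
#'   (N_II) and `e_nuclear` (hartree).
#' @examples
#' molecular_system(c("O", "H", "H"), charge = 0, multiplicity = 1)
#' @export
molecular_system <- function(geometry, charge = 0, multiplicity = 1) {
  if (is.character(geometry)) {
    geometry <- data.frame(symbol = geometry, x = NA_real_, y = NA_real_,
                           z = NA_real_, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(geometry), nrow(geometry) >= 1)
  z <- element_number(geometry$symbol)
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  n <- sum(z) - charge
  n_single <- multiplicity - 1
  n_paired <- n - n_single
  if (n < 1) stop("system has no electrons")
  if (n_paired < 0 || n_paired %% 2 != 0) {
    stop(sprintf(
      "charge %d and multiplicity %d are inconsistent with %d electrons (N_II = %d must be even and >= 0)",
      charge, multiplicity, n, n_paired))
  }
  e_nuc <- if (anyNA(geometry$x)) NA_real_ else nuclear_repulsion(geometry)
  structure(list(atoms = geometry, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 n_electrons = as.integer(n),
                 n_single = as.integer(n_single),
                 n_paired = as.integer(n_paired),
                 e_nuclear = e_nuc),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf(
    "Molecular system: %d atoms, charge %d, multiplicity %d\n  N = %d electrons (N_I = %d single, N_II = %d paired)\n",
    nrow(x$atoms), x$charge, x$multiplicity, x$n_electrons, x$n_single,
    x$n_paired))
  if (!is.na(x$e_nuclear))
    cat(sprintf("  nuclear repulsion: %.9f hartree\n", x$e_nuclear))
  invisible(x)
}

# ---------------------------------------------------------------------------
# pairing scheme: partition Omega = Omega_I (+) Omega_II
# ---------------------------------------------------------------------------

#' Partition the orbital space into pairing subspaces
#'
#' Orbitals are indexed 1..N_B in blocks: strongly occupied paired orbitals
#' (1..N_II/2, region `"strong"`), single-electron orbitals (..N_Omega, region
#' `"single"`), weakly occupied partners (..N_Omega + N_II/2 * N_g, region
#' `"weak"`), and a frozen-empty remainder (region `"frozen"`). Each paired
#' subspace couples one strong orbital g with its `N_g` weak partners
#' `N_Omega + (g-1)*N_g + 1 .. N_Omega + g*N_g`; each single-electron subspace
#' holds one orbital with fixed occupation 1/2.
#'
#' @param system a [molecular_system()].
#' @param n_basis number of spatial basis functions N_B.
#' @param coupling `"perfect"` (N_g = 1), `"extended"` (maximum N_g allowed by
#'   the basis, `floor((N_B - N_Omega) / (N_II/2))`), or an explicit integer.
#' @return an object of class `"pairing_scheme"` with the subspace and region
#'   maps.
#' @export
pairing_scheme <- function(system, n_basis, coupling = "perfect") {
  stopifnot(inherits(system, "molecular_system"))
  n_basis <- as.integer(n_basis)
  n_pairs <- system$n_paired %/% 2L
  n_single <- system$n_single
  n_omega <- n_pairs + n_single
  if (n_basis < n_omega)
    stop(sprintf("basis too small: N_B = %d < N_Omega = %d", n_basis, n_omega))
  if (is.character(coupling)) {
    coupling <- match.arg(coupling, c("perfect", "extended"))
    if (coupling == "perfect") {
      n_g <- 1L
    } else {
      if (n_pairs == 0)
        stop("extended coupling undefined for a system without paired electrons")
      n_g <- (n_basis - n_omega) %/% n_pairs
      if (n_g < 1)
        stop("basis too small for extended coupling (no room for weak partners)")
    }
  } else {
    n_g <- as.integer(coupling)
    if (n_g < 1) stop("explicit N_g must be >= 1")
  }
  if (n_pairs > 0 && n_omega + n_pairs * n_g > n_basis)
    stop(sprintf(
      "N_g = %d infeasible: need %d orbitals but basis has only %d",
      n_g, n_omega + n_pairs * n_g, n_basis))
  if (n_pairs == 0) n_g <- 1L  # vacuous

  n_coupled <- n_pairs * (1L + n_g) + n_single
  subspace <- integer(n_basis)
  region <- rep("frozen", n_basis)
  if (n_pairs > 0) {
    subspace[seq_len(n_pairs)] <- seq_len(n_pairs)
    region[seq_len(n_pairs)] <- "strong"
    for (g in seq_len(n_pairs)) {
      w <- n_omega + (g - 1L) * n_g + seq_len(n_g)
      subspace[w] <- g
      region[w] <- "weak"
    }
  }
  if (n_single > 0) {
    s <- n_pairs + seq_len(n_single)
    subspace[s] <- n_pairs + seq_len(n_single)
    region[s] <- "single"
  }
  structure(list(n_basis = n_basis, n_g = n_g, n_pairs = n_pairs,
                 n_single = n_single, n_subspaces = n_omega,
                 n_coupled = as.integer(n_coupled),
                 subspace = subspace, region = region),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat(sprintf(
    "Pairing scheme: N_B = %d, N_g = %d\n  %d paired subspaces + %d single-electron subspaces (N_Omega = %d)\n  %d coupled orbitals (%d variably occupied), %d frozen empty\n",
    x$n_basis, x$n_g, x$n_pairs, x$n_single, x$n_subspaces, x$n_coupled,
    variably_occupied_orbital_count(x), x$n_basis - x$n_coupled))
  invisible(x)
}

#' Number of orbitals whose occupations are optimization variables
#'
#' Paired strong and weak orbitals carry variable occupations; single-electron
#' orbitals are fixed at occupation 1/2 and frozen-empty orbitals at 0. For a
#' 186-electron system this gives 184 (triplet) and 182 (quintet) orbitals
#' under perfect pairing.
#'
#' @param scheme a [pairing_scheme()].
#' @return integer count `N_II/2 * (1 + N_g)`.
#' @export
variably_occupied_orbital_count <- function(scheme) {
  stopifnot(inherits(scheme, "pairing_scheme"))
  scheme$n_pairs * (1L + scheme$n_g)
}
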