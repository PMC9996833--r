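# ---------------------------------------------------------------------------
# occupation states under the electron-pairing sum rules
# ---------------------------------------------------------------------------

#' Construct a valid occupation state
#'
#' Occupations are per-spin: `n_p` in `[0, 1]`, total occupancy `2 n_p`.
#' Single-electron orbitals carry exactly `n = 1/2`; each paired subspace
#' satisfies the sum rule `sum(n) = 1` so the 1RDM trace equals the electron
#' count by construction.
#'
#' @param scheme a [pairing_scheme()].
#' @param n numeric vector of per-spin occupations over the coupled orbital
#'   set (`scheme$n_coupled`).
#' @param tol validation tolerance for the sum rules.
#' @return object of class `"occupation_state"` with `n`, `h = 1 - n` and the
#'   scheme.
#' @export
occupation_state <- function(scheme, n, tol = 1e-10) {
  stopifnot(inherits(scheme, "pairing_scheme"))
  m <- scheme$n_coupled
  if (length(n) != m)
    stop(sprintf("expected %d occupations, got %d", m, length(n)))
  if (any(n < -tol | n > 1 + tol))
    stop("occupations must lie in [0, 1]")
  reg <- scheme$region[seq_len(m)]
  sub <- scheme$subspace[seq_len(m)]
  if (scheme$n_single > 0 && any(abs(n[reg == "single"] - 0.5) > tol))
    stop("single-electron orbitals must have occupation exactly 1/2")
  if (scheme$n_pairs > 0) {
    sums <- tapply(n[reg != "single"], sub[reg != "single"], sum)
    if (any(abs(sums - 1) > tol))
      stop("paired-subspace sum rule violated: sum(n) over each subspace must be 1")
  }
  structure(list(n = pmin(pmax(n, 0), 1), h = 1 - pmin(pmax(n, 0), 1),
                 scheme = scheme),
            class = "occupation_state")
}

# reference integer-occupation pattern, optionally perturbed into the interior
# (delta spread uniformly over the weak partners of each subspace)
occupation_pattern <- function(scheme, delta = 0) {
  m <- scheme$n_coupled
  reg <- scheme$region[seq_len(m)]
  n <- numeric(m)
  n[reg == "strong"] <- 1 - delta
  n[reg == "single"] <- 0.5
  if (scheme$n_g > 0) n[reg == "weak"] <- delta / scheme$n_g
  occupation_state(scheme, n)
}

# region/subspace helpers over the coupled set
occ_region <- function(occ) occ$scheme$region[seq_len(occ$scheme$n_coupled)]
occ_subspace <- function(occ) occ$scheme$subspace[seq_len(occ$scheme$n_coupled)]

#' Parameters of the dynamic-occupation model
#'
#' The dynamic part of an occupation is gated by the hole `h_g` of the
#' subspace's strongly occupied orbital through `exp(-(h_g/h_c)^2)`. The
#' hole cutoff `h_c = 0.02 * sqrt(2)` makes the maximum attainable dynamic
#' part of a weakly occupied orbital about 0.012, in line with the Pulay
#' criterion that deviations of roughly 0.01 from integer occupation mark
#' dynamic correlation.
#'
#' @param h_c hole cutoff.
#' @param cap diagnostic maximum for the weak-orbital dynamic part.
#' @export
dyn_params <- function(h_c = 0.02 * sqrt(2), cap = 0.012) {
  list(h_c = h_c, cap = cap)
}

#' Dynamic parts of the occupation numbers
#'
#' For every orbital `p` in a paired subspace `Omega_g`,
#' `n_p^d = min(n_p, h_p) * exp(-(h_g / h_c)^2)` where `h_g` is the hole of
#' the subspace's strongly occupied orbital: the dynamic part of a weakly
#' occupied orbital is its occupation, that of a strongly occupied orbital
#' its hole, both damped once the subspace hole leaves the Pulay (~0.01)
#' regime. The maximum attainable value is about 0.012 for every orbital.
#' Single-electron orbitals do not participate in dynamic correlation and
#' get `n^d = 0`.
#'
#' @param occ an [occupation_state()].
#' @param params a [dyn_params()] list.
#' @return numeric vector of `n_p^d` over the coupled orbitals.
#' @export
dynamic_occupations <- function(occ, params = dyn_params()) {
  stopifnot(inherits(occ, "occupation_state"))
  scheme <- occ$scheme
  m <- scheme$n_coupled
  nd <- numeric(m)
  if (scheme$n_pairs == 0) return(nd)
  reg <- occ_region(occ)
  sub <- occ_subspace(occ)
  strong_idx <- which(reg == "strong")
  for (g in seq_len(scheme$n_pairs)) {
    hg <- occ$h[strong_idx[g]]
    gate <- exp(-(hg / params$h_c)^2)
    idx <- which(sub == g)
    nd[idx] <- pmin(occ$n[idx], occ$h[idx]) * gate
  }
  nd
}

#' Maximum attainable dynamic occupation of a weakly occupied orbital
#'
#' Scans the perfect-pairing relation (weak occupation equals the strong
#' orbital's hole, `n_p = h_g`) over a dense grid of occupations and returns
#' the maximum of `n_p^d = n_p * exp(-(n_p/h_c)^2)`.
#'
#' @param params a [dyn_params()] list.
#' @param step grid spacing on `[0, 1]`.
#' @export
dynamic_occupation_max <- function(params = dyn_params(), step = 1e-5) {
  n <- seq(0, 1, by = step)
  max(pmin(n, 1 - n) * exp(-(n / params$h_c)^2))
}

#' Static-correlation coupling amplitudes Phi
#'
#' `Phi_p` vanishes at integer occupations and is largest at `n = 1/2`. The
#' `"gnof_pnof7"` variant is `sqrt(n_p h_p)` (used by PNOF7 and GNOF); the
#' `"pnof7s"` variant is `2 n_p h_p`.
#'
#' @param occ an [occupation_state()].
#' @param variant `"gnof_pnof7"` or `"pnof7s"`.
#' @return numeric vector of `Phi_p` over the coupled orbitals.
#' @export
phi_values <- function(occ, variant = c("gnof_pnof7", "pnof7s")) {
  stopifnot(inherits(occ, "occupation_state"))
  variant <- match.arg(variant)
  nh <- pmax(occ$n * occ$h, 0)
  if (variant == "gnof_pnof7") sqrt(nh) else 2 * nh
}
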