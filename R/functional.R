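# ---------------------------------------------------------------------------
# functional core: PNOF5 / PNOF7s / PNOF7 / GNOF energy expressions
#
# All double sums over orbital pairs follow the ordered-pair convention of the
# energy expressions (each unordered pair counted in both orders), with
# real-orbital L = K throughout.
# ---------------------------------------------------------------------------

NOF_FUNCTIONALS <- c("PNOF5", "PNOF7s", "PNOF7", "GNOF")

# signed pair amplitudes c_p: +sqrt(n) in the strongly occupied block,
# -sqrt(n) above N_Omega, 0 for singles
.signed_sqrt_n <- function(n, region) {
  s <- ifelse(region == "strong", 1, ifelse(region == "weak", -1, 0))
  s * sqrt(pmax(n, 0))
}

# intersubspace mask over coupled orbitals (TRUE for p, q in different
# subspaces)
.inter_mask <- function(scheme) {
  sub <- scheme$subspace[seq_len(scheme$n_coupled)]
  outer(sub, sub, `!=`)
}

#' Pair-coupling matrix Pi
#'
#' `Pi_qp = c_q c_p` with signed amplitudes `c_p = +sqrt(n_p)` for strongly
#' occupied orbitals and `-sqrt(n_p)` for weakly occupied ones. `kind =
#' "intrapair"` restricts it to off-diagonal same-subspace pairs (the pair
#' energy coupling); `kind = "dynamic"` evaluates it on the dynamic parts
#' `n^d` over intersubspace pairs excluding strong-strong ones.
#'
#' @param occ an [occupation_state()].
#' @param kind `"intrapair"` or `"dynamic"`.
#' @param params dynamic-occupation parameters (used for `kind = "dynamic"`).
#' @return symmetric matrix over the coupled orbitals.
#' @export
pi_matrix <- function(occ, kind = c("intrapair", "dynamic"),
                      params = dyn_params()) {
  stopifnot(inherits(occ, "occupation_state"))
  kind <- match.arg(kind)
  reg <- occ_region(occ)
  if (kind == "intrapair") {
    cc <- .signed_sqrt_n(occ$n, reg)
    P <- outer(cc, cc)
    same <- !.inter_mask(occ$scheme)
    P[!same] <- 0
    diag(P) <- 0
  } else {
    nd <- dynamic_occupations(occ, params)
    cc <- .signed_sqrt_n(nd, reg)
    P <- outer(cc, cc)
    P[!.dyn_mask(occ$scheme)] <- 0
  }
  P
}

# pairs eligible for the interspace dynamic term: different subspaces and not
# both in the strongly occupied block Omega_II^b
.dyn_mask <- function(scheme) {
  reg <- scheme$region[seq_len(scheme$n_coupled)]
  strong <- reg == "strong"
  .inter_mask(scheme) & !outer(strong, strong, `&`)
}

#' Intrapair energy plus single-electron one-body energies
#'
#' Sum over paired subspaces of the exact pair energies
#' `sum_p n_p (2 H_pp + J_pp) + sum'_{q,p} Pi_qp L_qp`, plus `H_gg` for each
#' single-electron orbital (occupation 1/2 for each spin).
#'
#' @param occ an [occupation_state()].
#' @param ints a `no_integrals` object from [transform_to_no_basis()].
#' @param Pi optional precomputed intrapair [pi_matrix()].
#' @return energy in hartree.
#' @export
intrapair_energy <- function(occ, ints, Pi = NULL) {
  .check_dims(occ, ints)
  reg <- occ_region(occ)
  paired <- reg %in% c("strong", "weak")
  e <- 0
  if (any(paired)) {
    if (is.null(Pi)) Pi <- pi_matrix(occ, "intrapair")
    e <- sum(occ$n[paired] * (2 * ints$Hd[paired] + diag(ints$J)[paired])) +
      sum(Pi * ints$L)
  }
  e + sum(ints$Hd[reg == "single"])
}

#' Intersubspace Hartree-Fock-like energy
#'
#' `sum'_{q,p} n_q n_p (2 J_qp - K_qp)` restricted to orbital pairs in
#' different subspaces.
#'
#' @inheritParams intrapair_energy
#' @export
hf_inter_energy <- function(occ, ints) {
  .check_dims(occ, ints)
  mask <- .inter_mask(occ$scheme)
  nn <- outer(occ$n, occ$n)
  sum((nn * (2 * ints$J - ints$K))[mask])
}

#' Intersubspace static-correlation energy
#'
#' `- sum'_{q,p} Phi_q Phi_p L_qp` over intersubspace pairs, with `Phi` per
#' the chosen variant (see [phi_values()]).
#'
#' @inheritParams intrapair_energy
#' @param variant `"gnof_pnof7"` (PNOF7/GNOF, `sqrt(n h)`) or `"pnof7s"`
#'   (`2 n h`).
#' @export
static_inter_energy <- function(occ, ints, variant = "gnof_pnof7") {
  .check_dims(occ, ints)
  phi <- phi_values(occ, variant)
  mask <- .inter_mask(occ$scheme)
  -sum((outer(phi, phi) * ints$L)[mask])
}

#' Intersubspace dynamic-correlation energy
#'
#' `sum'_{q,p} [ Pi(n_q^d, n_p^d) L_qp - n_q^d n_p^d (2 J_qp - K_qp) ]` over
#' intersubspace pairs, excluding pairs with both orbitals in the strongly
#' occupied block and any pair involving a single-electron orbital (whose
#' dynamic part is zero). When `n ~ n^d` the ON-product part cancels the
#' HF-like term, so the Pi-proportional part carries the dynamic correlation.
#'
#' @inheritParams intrapair_energy
#' @param params a [dyn_params()] list.
#' @param parts if `TRUE`, return a list with the `pi` and `on_product`
#'   contributions alongside the total.
#' @export
dynamic_inter_energy <- function(occ, ints, params = dyn_params(),
                                 parts = FALSE) {
  .check_dims(occ, ints)
  nd <- dynamic_occupations(occ, params)
  mask <- .dyn_mask(occ$scheme)
  cd <- .signed_sqrt_n(nd, occ_region(occ))
  e_pi <- sum((outer(cd, cd) * ints$L)[mask])
  e_on <- -sum((outer(nd, nd) * (2 * ints$J - ints$K))[mask])
  if (parts) list(total = e_pi + e_on, pi = e_pi, on_product = e_on)
  else e_pi + e_on
}

.check_dims <- function(occ, ints) {
  if (occ$scheme$n_coupled != ints$n_coupled)
    stop(sprintf("dimension mismatch: %d occupations vs %d coupled integrals",
                 occ$scheme$n_coupled, ints$n_coupled))
}

#' Total NOF energy with its component breakdown
#'
#' Assembles the functional from its components: GNOF keeps all four terms;
#' PNOF7 drops the interspace dynamic term; PNOF7s additionally uses
#' `Phi = 2 n h` in the static term; PNOF5 drops both intersubspace
#' correlation terms. Excluded terms are reported as 0.
#'
#' @param functional one of `"PNOF5"`, `"PNOF7s"`, `"PNOF7"`, `"GNOF"`.
#' @inheritParams intrapair_energy
#' @param params dynamic-occupation parameters.
#' @param e_nuclear nuclear repulsion energy added to form `e_total`.
#' @return object of class `"energy_breakdown"` with fields `e_intra`,
#'   `e_hf_inter`, `e_sta_inter`, `e_dyn_inter`, `e_elec`, `e_total`.
#' @export
total_energy <- function(functional, occ, ints, params = dyn_params(),
                         e_nuclear = 0) {
  functional <- match.arg(functional, NOF_FUNCTIONALS)
  e_intra <- intrapair_energy(occ, ints)
  e_hf <- hf_inter_energy(occ, ints)
  e_sta <- switch(functional,
    PNOF5 = 0,
    PNOF7s = static_inter_energy(occ, ints, "pnof7s"),
    static_inter_energy(occ, ints, "gnof_pnof7"))
  e_dyn <- if (functional == "GNOF")
    dynamic_inter_energy(occ, ints, params) else 0
  e_elec <- e_intra + e_hf + e_sta + e_dyn
  structure(list(functional = functional, e_intra = e_intra,
                 e_hf_inter = e_hf, e_sta_inter = e_sta, e_dyn_inter = e_dyn,
                 e_elec = e_elec, e_nuclear = e_nuclear,
                 e_total = e_elec + e_nuclear),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("%s energy breakdown (hartree)\n", x$functional))
  cat(sprintf("  E_intra     %18.9f\n", x$e_intra))
  cat(sprintf("  E_HF^inter  %18.9f\n", x$e_hf_inter))
  cat(sprintf("  E_sta^inter %18.9f\n", x$e_sta_inter))
  cat(sprintf("  E_dyn^inter %18.9f\n", x$e_dyn_inter))
  cat(sprintf("  E_elec      %18.9f\n", x$e_elec))
  cat(sprintf("  E_nuc       %18.9f\n", x$e_nuclear))
  cat(sprintf("  E_total     %18.9f\n", x$e_total))
  invisible(x)
}

#' Serialize an energy breakdown
#'
#' @param x an `energy_breakdown`.
#' @param path optional output path; with extension `.json` a JSON report is
#'   written, otherwise plain text (9 decimal places).
#' @return the report as a character string (invisibly when written to file).
#' @export
format_energy_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "energy_breakdown"))
  if (!is.null(path) && grepl("\\.json$", path)) {
    txt <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  } else {
    txt <- paste(utils::capture.output(print(x)), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(as.character(txt), path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

# ---------------------------------------------------------------------------
# coefficient matrices: E_2e = sum_pq CJ_pq J_pq + CK_pq K_pq (ordered pairs)
# used by the orbital-rotation gradient; must agree with the term functions
# ---------------------------------------------------------------------------
build_cj_ck <- function(functional, occ, params = dyn_params()) {
  functional <- match.arg(functional, NOF_FUNCTIONALS)
  scheme <- occ$scheme
  m <- scheme$n_coupled
  reg <- occ_region(occ)
  inter <- .inter_mask(scheme)
  CJ <- matrix(0, m, m)
  CK <- matrix(0, m, m)
  paired <- reg %in% c("strong", "weak")
  dj <- numeric(m)
  dj[paired] <- occ$n[paired]
  diag(CJ) <- dj
  CK <- CK + pi_matrix(occ, "intrapair")
  nn <- outer(occ$n, occ$n)
  CJ <- CJ + 2 * nn * inter
  CK <- CK - nn * inter
  if (functional != "PNOF5") {
    phi <- phi_values(occ, if (functional == "PNOF7s") "pnof7s" else "gnof_pnof7")
    CK <- CK - outer(phi, phi) * inter
  }
  if (functional == "GNOF") {
    nd <- dynamic_occupations(occ, params)
    cd <- .signed_sqrt_n(nd, reg)
    mask <- .dyn_mask(scheme)
    CJ <- CJ - 2 * outer(nd, nd) * mask
    CK <- CK + (outer(cd, cd) + outer(nd, nd)) * mask
  }
  list(CJ = CJ, CK = CK)
}

# energy from coefficient matrices and NO-basis J/K/H (must equal the
# term-function assembly)
energy_from_cjck <- function(occ, ints, cjck) {
  sum(2 * occ$n * ints$Hd) + sum(cjck$CJ * ints$J) + sum(cjck$CK * ints$K)
}
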