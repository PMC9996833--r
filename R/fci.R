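# ---------------------------------------------------------------------------
# determinant full configuration interaction (validation oracle)
# ---------------------------------------------------------------------------

# spin orbitals are numbered 2*spatial-1 (alpha) and 2*spatial (beta);
# determinants are sorted integer vectors of occupied spin orbitals

.spatial <- function(so) (so + 1L) %/% 2L
.is_alpha <- function(so) so %% 2L == 1L

# permutation sign for single excitation i -> a within det (occupied list)
.exc_sign <- function(det, i, a) {
  # count occupied spin orbitals strictly between i and a
  lo <- min(i, a); hi <- max(i, a)
  nbetween <- sum(det > lo & det < hi)
  if (nbetween %% 2L == 0L) 1 else -1
}

# antisymmetrized two-electron integral <ij||kl> over spin orbitals,
# from spatial chemist ERIs: <ij|kl> = (ik|jl) * d(si,sk) * d(sj,sl)
.so_coulomb <- function(eri, i, j, k, l) {
  v <- 0
  if (.is_alpha(i) == .is_alpha(k) && .is_alpha(j) == .is_alpha(l))
    v <- eri[.spatial(i), .spatial(k), .spatial(j), .spatial(l)]
  v
}

.so_anti <- function(eri, i, j, k, l) {
  .so_coulomb(eri, i, j, k, l) - .so_coulomb(eri, i, j, l, k)
}

#' Full configuration interaction in a molecular-orbital basis
#'
#' Exact diagonalization over all determinants with the multiplet's
#' `S_z = S` projection. Intended as a validation oracle for small systems
#' (at most about 12 spin orbitals occupied-virtual combinatorics permitting).
#'
#' @param ao an [ao_integrals()] object.
#' @param system the [molecular_system()] (electron counts and multiplicity).
#' @param C molecular-orbital coefficients (default: mean-field orbitals).
#' @return list with `e_total`, `e_elec`, ground-state vector, the determinant
#'   list, and per-spin natural occupations `occupations` (sorted decreasing).
#' @export
fci <- function(ao, system, C = NULL) {
  n_orb <- ao$n_basis
  n <- system$n_electrons
  n_a <- (n + system$n_single) %/% 2L
  n_b <- n - n_a
  if (choose(n_orb, n_a) * max(1, choose(n_orb, n_b)) > 20000)
    stop("FCI oracle limited to small determinant spaces")
  if (is.null(C)) {
    scheme <- pairing_scheme(system, n_orb, "perfect")
    C <- mean_field_orbitals(ao, scheme)
  }
  h <- crossprod(C, ao$Hcore %*% C)
  eri <- contract4(ao$eri, C)

  occ_a <- if (n_a > 0) utils::combn(n_orb, n_a, simplify = FALSE) else list(integer(0))
  occ_b <- if (n_b > 0) utils::combn(n_orb, n_b, simplify = FALSE) else list(integer(0))
  dets <- list()
  for (oa in occ_a) for (ob in occ_b)
    dets[[length(dets) + 1L]] <- sort(c(2L * oa - 1L, 2L * ob))
  nd <- length(dets)

  Hm <- matrix(0, nd, nd)
  for (I in seq_len(nd)) {
    dI <- dets[[I]]
    # diagonal
    e <- sum(diag(h)[.spatial(dI)])
    if (n > 1) {
      for (ii in seq_len(n - 1)) for (jj in seq(ii + 1, n))
        e <- e + .so_anti(eri, dI[ii], dI[jj], dI[ii], dI[jj])
    }
    Hm[I, I] <- e
    if (I < nd) {
      for (J in seq(I + 1, nd)) {
        dJ <- dets[[J]]
        only_I <- setdiff(dI, dJ)
        ndiff <- length(only_I)
        if (ndiff > 2) next
        only_J <- setdiff(dJ, dI)
        common <- intersect(dI, dJ)
        if (ndiff == 1) {
          i <- only_I; a <- only_J
          if (.is_alpha(i) != .is_alpha(a)) next
          sg <- .exc_sign(dI, i, a)
          v <- h[.spatial(i), .spatial(a)] * (if (.is_alpha(i)) 1 else 1)
          for (k in common) v <- v + .so_anti(eri, i, k, a, k)
          Hm[I, J] <- sg * v
        } else {
          i <- only_I[1]; j <- only_I[2]
          a <- only_J[1]; b <- only_J[2]
          # match spins: pair i with the same-spin target
          if (.is_alpha(i) != .is_alpha(a)) { tmp <- a; a <- b; b <- tmp }
          if (.is_alpha(i) != .is_alpha(a) || .is_alpha(j) != .is_alpha(b))
            next
          # sign via sequential single excitations
          d1 <- sort(c(setdiff(dI, i), a))
          sg <- .exc_sign(dI, i, a) * .exc_sign(d1, j, b)
          Hm[I, J] <- sg * .so_anti(eri, i, j, a, b)
        }
        Hm[J, I] <- Hm[I, J]
      }
    }
  }
  ev <- eigen(Hm, symmetric = TRUE)
  e_elec <- ev$values[nd]
  v0 <- ev$vectors[, nd]

  # spin-summed 1RDM in the MO basis
  gam <- matrix(0, n_orb, n_orb)
  for (I in seq_len(nd)) {
    dI <- dets[[I]]
    for (p in .spatial(dI)) gam[p, p] <- gam[p, p] + v0[I]^2
    for (J in seq_len(nd)) {
      if (I == J) next
      dJ <- dets[[J]]
      only_I <- setdiff(dI, dJ)
      if (length(only_I) != 1) next
      only_J <- setdiff(dJ, dI)
      i <- only_I; a <- only_J
      if (.is_alpha(i) != .is_alpha(a)) next
      sg <- .exc_sign(dI, i, a)
      gam[.spatial(i), .spatial(a)] <-
        gam[.spatial(i), .spatial(a)] + sg * v0[I] * v0[J]
    }
  }
  occ_no <- sort(eigen((gam + t(gam)) / 2, symmetric = TRUE)$values,
                 decreasing = TRUE) / 2
  e_nuc <- if (is.na(system$e_nuclear)) 0 else system$e_nuclear
  list(e_total = e_elec + e_nuc, e_elec = e_elec,
       vector = v0, determinants = dets, occupations = occ_no,
       rdm1 = gam)
}
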