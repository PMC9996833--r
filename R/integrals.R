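# ---------------------------------------------------------------------------
# AO integrals and transformation to the natural-orbital basis
# ---------------------------------------------------------------------------

#' Compute atomic-orbital integrals
#'
#' Evaluates overlap, core-Hamiltonian (kinetic + nuclear attraction) and
#' electron-repulsion integrals over spherical-harmonic contracted Gaussians.
#' With `ri = TRUE` the ERI tensor is additionally factorized by pivoted
#' Cholesky decomposition into three-index factors `B` with
#' `(pq|rs) = sum_x B[x, pq] B[x, rs]`, accurate to `ri_tol` on the diagonal.
#'
#' @param system a [molecular_system()] with coordinates.
#' @param basis basis set name.
#' @param ri logical; factorize the ERIs.
#' @param ri_tol pivoted-Cholesky truncation tolerance (hartree).
#' @return object of class `"ao_integrals"`: `S`, `Hcore`, `T`, `V`
#'   (`n_basis` x `n_basis`), `eri` (4-index array, chemist convention
#'   `(pq|rs)`), optional `ri_b` factor matrix, plus basis metadata.
#' @export
ao_integrals <- function(system, basis, ri = FALSE, ri_tol = 1e-6) {
  stopifnot(inherits(system, "molecular_system"))
  if (anyNA(system$atoms$x))
    stop("system has no coordinates; integrals require a full geometry")
  bas <- build_basis(system$atoms, basis)
  xyz <- as.matrix(system$atoms[, c("x", "y", "z")]) * ANGSTROM_TO_BOHR
  z <- element_number(system$atoms$symbol)
  one <- .cpp_one_electron(bas$cpp, xyz, as.numeric(z))
  Tm <- bas$cart_to_sph
  S <- crossprod(Tm, one$S %*% Tm)
  norms <- 1 / sqrt(diag(S))
  Dn <- diag(norms, nrow = length(norms))
  S <- Dn %*% S %*% Dn
  Tk <- Dn %*% crossprod(Tm, one$T %*% Tm) %*% Dn
  V <- Dn %*% crossprod(Tm, one$V %*% Tm) %*% Dn
  eri <- .cpp_eri(bas$cpp)
  eri <- contract4(eri, sweep(Tm, 2, norms, `*`))
  out <- structure(list(
    S = S, Hcore = Tk + V, T = Tk, V = V, eri = eri,
    n_basis = bas$n_basis, basis = bas, basis_name = basis, ao_norms = norms,
    e_nuclear = system$e_nuclear, ri = ri), class = "ao_integrals")
  if (ri) {
    fac <- ri_factorize(eri, tol = ri_tol)
    out$ri_b <- fac$b
    out$ri_rank <- fac$rank
    out$eri <- ri_reconstruct(fac$b, bas$n_basis)
  }
  out
}

#' @export
print.ao_integrals <- function(x, ...) {
  cat(sprintf("AO integrals: %d basis functions (%s)%s\n", x$n_basis,
              x$basis_name,
              if (isTRUE(x$ri)) sprintf(", RI rank %d", x$ri_rank) else ""))
  invisible(x)
}

# contract each of the four ERI indices with the columns of M
contract4 <- function(eri, M) {
  n <- dim(eri)[1]
  m <- ncol(M)
  G <- eri
  for (k in 1:4) {
    dm <- dim(G)
    G <- matrix(G, nrow = dm[1])
    G <- crossprod(M, G)               # first index -> m
    dim(G) <- c(m, dm[2], dm[3], dm[4])
    G <- aperm(G, c(2, 3, 4, 1))       # rotate indices
  }
  G
}

# pivoted Cholesky factorization of the ERI matrix (mu nu | la si)
ri_factorize <- function(eri, tol = 1e-6) {
  n <- dim(eri)[1]
  Emat <- matrix(eri, n * n, n * n)
  ch <- suppressWarnings(chol(Emat, pivot = TRUE, tol = tol))
  rank <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  b <- matrix(0, rank, n * n)
  b[, piv] <- ch[seq_len(rank), , drop = FALSE]
  list(b = b, rank = rank)
}

ri_reconstruct <- function(b, n) {
  E <- crossprod(b)
  array(E, dim = c(n, n, n, n))
}

#' Transform integrals into the current natural-orbital basis
#'
#' Produces the one-electron matrix and the Coulomb `J_pq = <pq|pq>`,
#' exchange `K_pq = <pq|qp>` and exchange-time-inversion `L_pq = <pp|qq>`
#' matrices over the coupled orbital set. For real orbitals `L = K`
#' elementwise, which is the convention used throughout.
#'
#' @param ao an [ao_integrals()] object.
#' @param C AO-to-NO coefficient matrix with S-orthonormal columns.
#' @param scheme a [pairing_scheme()]; integrals are restricted to its
#'   `n_coupled` leading orbitals.
#' @param tol orthonormality tolerance.
#' @return object of class `"no_integrals"` with `H` (full NO one-electron
#'   matrix), `Hd` (its diagonal), `J`, `K`, `L` over coupled orbitals.
#' @export
transform_to_no_basis <- function(ao, C, scheme, tol = 1e-8) {
  stopifnot(inherits(ao, "ao_integrals"), inherits(scheme, "pairing_scheme"))
  dev <- max(abs(crossprod(C, ao$S %*% C) - diag(ncol(C))))
  if (dev > tol)
    stop(sprintf("orbital coefficients not S-orthonormal (deviation %.2e)", dev))
  m <- scheme$n_coupled
  Cc <- C[, seq_len(m), drop = FALSE]
  H <- crossprod(C, ao$Hcore %*% C)
  G <- contract4(ao$eri, Cc)
  J <- matrix(0, m, m)
  K <- matrix(0, m, m)
  for (p in seq_len(m)) {
    for (q in seq_len(m)) {
      J[p, q] <- G[p, p, q, q]
      K[p, q] <- G[p, q, p, q]
    }
  }
  structure(list(H = H, Hd = diag(H)[seq_len(m)], J = J, K = K, L = K,
                 n_coupled = m, n_basis = ao$n_basis),
            class = "no_integrals")
}
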