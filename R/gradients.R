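# ---------------------------------------------------------------------------
# analytic occupation-number gradients of the electronic energy
# ---------------------------------------------------------------------------

# electronic energy and dE/dn over coupled orbitals at fixed NO integrals
occ_energy_grad <- function(functional, occ, ints, params = dyn_params()) {
  functional <- match.arg(functional, NOF_FUNCTIONALS)
  scheme <- occ$scheme
  m <- scheme$n_coupled
  n <- occ$n
  h <- occ$h
  reg <- occ_region(occ)
  sub <- occ_subspace(occ)
  paired <- reg %in% c("strong", "weak")
  inter <- .inter_mask(scheme)
  J <- ints$J; K <- ints$K; Hd <- ints$Hd

  grad <- numeric(m)
  # intrapair: n (2H + J_pp) and Pi coupling
  grad[paired] <- 2 * Hd[paired] + diag(J)[paired]
  cc <- .signed_sqrt_n(n, reg)
  same_nodiag <- !inter
  diag(same_nodiag) <- FALSE
  Ksame <- K * same_nodiag
  sumcK <- as.numeric(Ksame %*% cc)
  safe_n <- pmax(n, 1e-30)
  grad[paired] <- grad[paired] + sumcK[paired] * cc[paired] / safe_n[paired]
  e_intra <- sum(n[paired] * (2 * Hd[paired] + diag(J)[paired])) +
    sum(outer(cc, cc) * Ksame) + sum(Hd[reg == "single"])

  # interspace HF
  JKh <- (2 * J - K) * inter
  e_hf <- sum(outer(n, n) * JKh)
  grad <- grad + 2 * as.numeric(JKh %*% n)

  # interspace static
  e_sta <- 0
  if (functional != "PNOF5") {
    variant <- if (functional == "PNOF7s") "pnof7s" else "gnof_pnof7"
    phi <- phi_values(occ, variant)
    Kin <- K * inter
    sphi <- as.numeric(Kin %*% phi)
    e_sta <- -sum(phi * sphi)
    dphi <- if (variant == "pnof7s") 2 - 4 * n
            else (1 - 2 * n) / (2 * pmax(phi, 1e-30))
    grad <- grad - 2 * dphi * sphi
  }

  # interspace dynamic
  e_dyn <- 0
  if (functional == "GNOF" && scheme$n_pairs > 0) {
    nd <- dynamic_occupations(occ, params)
    cd <- .signed_sqrt_n(nd, reg)
    mask <- .dyn_mask(scheme)
    Kd <- K * mask
    JKd <- (2 * J - K) * mask
    sumcdK <- as.numeric(Kd %*% cd)
    sumndJK <- as.numeric(JKd %*% nd)
    e_dyn <- sum(cd * sumcdK) - sum(nd * sumndJK)
    safe_nd <- pmax(nd, 1e-150)
    dEdnd <- sumcdK * cd / safe_nd - 2 * sumndJK
    dEdnd[nd < 1e-150] <- -2 * sumndJK[nd < 1e-150]
    # chain rule through n^d = min(n, h) * gate(h_g)
    strong_idx <- which(reg == "strong")
    dmin <- ifelse(n < 0.5, 1, -1)
    for (g in seq_len(scheme$n_pairs)) {
      gs <- strong_idx[g]
      hg <- h[gs]
      gate <- exp(-(hg / params$h_c)^2)
      idx <- which(sub == sub[gs])
      grad[idx] <- grad[idx] + dEdnd[idx] * dmin[idx] * gate
      grad[gs] <- grad[gs] +
        sum(dEdnd[idx] * pmin(n[idx], h[idx])) * gate * 2 * hg / params$h_c^2
    }
  }

  list(energy = e_intra + e_hf + e_sta + e_dyn, grad = grad,
       components = c(intra = e_intra, hf = e_hf, sta = e_sta, dyn = e_dyn))
}

# ---------------------------------------------------------------------------
# softmax (interior) parametrization of the subspace simplices
# ---------------------------------------------------------------------------

# x -> n: each paired subspace's occupations are softmax(x_block); singles
# fixed at 1/2
softmax_to_occ <- function(scheme, x) {
  m <- scheme$n_coupled
  reg <- scheme$region[seq_len(m)]
  sub <- scheme$subspace[seq_len(m)]
  n <- numeric(m)
  n[reg == "single"] <- 0.5
  off <- 0L
  for (g in seq_len(scheme$n_pairs)) {
    idx <- which(sub == g)
    xb <- x[off + seq_along(idx)]
    xb <- xb - max(xb)
    ex <- exp(xb)
    n[idx] <- ex / sum(ex)
    off <- off + length(idx)
  }
  n
}

occ_to_softmax <- function(scheme, n, floor = 1e-12) {
  m <- scheme$n_coupled
  sub <- scheme$subspace[seq_len(m)]
  x <- numeric(0)
  for (g in seq_len(scheme$n_pairs)) {
    idx <- which(sub == g)
    x <- c(x, log(pmax(n[idx], floor)))
  }
  x
}

# dE/dx from dE/dn (softmax Jacobian per subspace block)
softmax_chain <- function(scheme, n, grad_n) {
  sub <- scheme$subspace[seq_len(scheme$n_coupled)]
  gx <- numeric(0)
  for (g in seq_len(scheme$n_pairs)) {
    idx <- which(sub == g)
    nb <- n[idx]
    gb <- grad_n[idx]
    gx <- c(gx, nb * (gb - sum(nb * gb)))
  }
  gx
}
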