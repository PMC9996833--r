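# ---------------------------------------------------------------------------
# alternated occupation-number / natural-orbital optimization
# ---------------------------------------------------------------------------

# matrix exponential of a (small-norm) skew-symmetric matrix by
# scaling-and-squaring with a truncated Taylor series
expm_skew <- function(X) {
  nrm <- max(abs(X))
  if (nrm == 0) return(diag(nrow(X)))
  s <- max(0L, ceiling(log2(nrm / 0.25)))
  Y <- X / 2^s
  E <- diag(nrow(X))
  term <- diag(nrow(X))
  for (k in 1:14) {
    term <- term %*% Y / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Loewdin symmetric orthonormalization of C with respect to S
lowdin <- function(C, S) {
  M <- crossprod(C, S %*% C)
  e <- eigen(M, symmetric = TRUE)
  M_isqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-14)),
                                length(e$values)) %*% t(e$vectors)
  C %*% M_isqrt
}

# inverse square root of a symmetric positive definite matrix
mat_isqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-14)),
                     length(e$values)) %*% t(e$vectors)
}

# cache the two ERI matricizations used for Coulomb/exchange builds
eri_mats <- function(ao) {
  n <- ao$n_basis
  list(coul = matrix(ao$eri, n * n, n * n),
       exch = matrix(aperm(ao$eri, c(1, 3, 2, 4)), n * n, n * n),
       n = n)
}

# mean-field orbital guess: damped SCF with the multiplet's reference
# (fractional) occupation pattern
mean_field_orbitals <- function(ao, scheme, maxit = 200, conv = 1e-9) {
  n <- ao$n_basis
  em <- eri_mats(ao)
  X <- mat_isqrt(ao$S)
  npat <- numeric(n)
  npat[scheme$region == "strong"] <- 1
  npat[scheme$region == "single"] <- 0.5
  Fm <- ao$Hcore
  D_old <- matrix(0, n, n)
  C <- NULL
  for (it in seq_len(maxit)) {
    Ft <- crossprod(X, Fm %*% X)
    ev <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    C <- X %*% ev$vectors[, rev(seq_len(n)), drop = FALSE]  # ascending
    D <- C %*% (2 * npat * t(C))
    if (it > 1 && max(abs(D - D_old)) < conv) break
    if (it > 1) D <- 0.6 * D + 0.4 * D_old
    D_old <- D
    Jm <- matrix(em$coul %*% as.numeric(D), n, n)
    Km <- matrix(em$exch %*% as.numeric(D), n, n)
    Fm <- ao$Hcore + Jm - 0.5 * Km
  }
  C
}

# NO-basis H diagonal, J and K over coupled orbitals from cached ERI forms
no_jk <- function(ao, em, C, m) {
  Cc <- C[, seq_len(m), drop = FALSE]
  n <- em$n
  Dmat <- matrix(0, n * n, m)
  for (p in seq_len(m)) Dmat[, p] <- as.numeric(tcrossprod(Cc[, p]))
  J <- crossprod(Dmat, em$coul %*% Dmat)
  K <- crossprod(Dmat, em$exch %*% Dmat)
  Hd <- colSums(Cc * (ao$Hcore %*% Cc))
  list(Hd = Hd, J = (J + t(J)) / 2, K = (K + t(K)) / 2, L = (K + t(K)) / 2,
       n_coupled = m, Dmat = Dmat)
}

# ---------------------------------------------------------------------------
# solver state
# ---------------------------------------------------------------------------

new_nof_state <- function(system, scheme, ao, C, n, functional,
                          params = dyn_params()) {
  state <- structure(list(
    system = system, scheme = scheme, ao = ao, C = C, n = n,
    functional = match.arg(functional, NOF_FUNCTIONALS), params = params,
    energy = NULL, history = NULL, converged = FALSE,
    grad_occ = NA_real_, grad_orb = NA_real_), class = "nof_state")
  refresh_energy(state)
}

refresh_energy <- function(state) {
  ints <- transform_to_no_basis(state$ao, state$C, state$scheme)
  occ <- occupation_state(state$scheme, state$n)
  state$ints <- ints
  state$energy <- total_energy(state$functional, occ, ints,
                               params = state$params,
                               e_nuclear = state$system$e_nuclear)
  state
}

#' Initialize a NOF solver state
#'
#' `strategy = "hf_guess"` takes orbitals from a converged mean-field
#' calculation with the multiplet's reference occupation pattern, then
#' perturbs the integer occupations into the feasible interior (`delta`
#' spread over the weak partners, sum rules exact). `strategy =
#' "warm_start"` copies the donor state's orbitals and occupations.
#'
#' @param system a [molecular_system()].
#' @param scheme a [pairing_scheme()].
#' @param ao an [ao_integrals()] object.
#' @param functional target functional label.
#' @param strategy `"hf_guess"` or `"warm_start"`.
#' @param donor donor `nof_state` for warm starts.
#' @param delta interior perturbation of the integer start.
#' @param mix_angle deterministic strong/weak mixing rotation (radians)
#'   applied to the mean-field guess; breaks symmetric saddle points (e.g.
#'   degenerate localized orbitals at homolytic dissociation) that have an
#'   exactly zero rotation gradient.
#' @param params dynamic-occupation parameters.
#' @return an object of class `"nof_state"`.
#' @export
init_state <- function(system, scheme, ao, functional = "GNOF",
                       strategy = c("hf_guess", "warm_start"), donor = NULL,
                       delta = 1e-2, mix_angle = 0.05, params = dyn_params()) {
  strategy <- match.arg(strategy)
  if (strategy == "warm_start") {
    if (is.null(donor) || !inherits(donor, "nof_state"))
      stop("warm_start requires a donor nof_state")
    ok <- donor$system$n_electrons == system$n_electrons &&
      donor$system$n_single == system$n_single &&
      donor$scheme$n_basis == scheme$n_basis &&
      donor$scheme$n_coupled == scheme$n_coupled
    if (!ok) stop("donor state incompatible with the requested system/scheme")
    # re-orthonormalize under the (possibly different) overlap metric
    C <- lowdin(donor$C, ao$S)
    return(new_nof_state(system, scheme, ao, C, donor$n, functional, params))
  }
  C <- mean_field_orbitals(ao, scheme)
  if (mix_angle != 0 && scheme$n_pairs > 0) {
    reg <- scheme$region
    sub <- scheme$subspace
    for (g in seq_len(scheme$n_pairs)) {
      gs <- which(reg == "strong" & sub == g)
      for (w in which(reg == "weak" & sub == g)) {
        th <- mix_angle
        cg <- C[, gs]; cw <- C[, w]
        C[, gs] <- cos(th) * cg + sin(th) * cw
        C[, w] <- -sin(th) * cg + cos(th) * cw
      }
    }
  }
  occ <- occupation_pattern(scheme, delta = delta)
  new_nof_state(system, scheme, ao, C, occ$n, functional, params)
}

# ---------------------------------------------------------------------------
# occupation optimization (BFGS in the interior softmax variables)
# ---------------------------------------------------------------------------

#' Optimize occupation numbers at fixed orbitals
#'
#' BFGS on the interior (softmax) parametrization of the subspace simplices,
#' so bounds and per-subspace sum rules hold exactly at every evaluation.
#' Iterates until the gradient infinity-norm in the free variables is below
#' `gtol`.
#'
#' @param state a `nof_state`.
#' @param functional functional label (defaults to the state's).
#' @param gtol gradient tolerance.
#' @param max_rounds maximum BFGS restarts.
#' @return updated `nof_state` (with `grad_occ` set).
#' @export
optimize_occupations <- function(state, functional = state$functional,
                                 gtol = 1e-4, max_rounds = 12) {
  scheme <- state$scheme
  if (scheme$n_pairs == 0) {
    state$grad_occ <- 0
    return(refresh_energy(state))
  }
  ints <- state$ints
  if (is.null(ints)) {
    state <- refresh_energy(state)
    ints <- state$ints
  }
  params <- state$params
  fn <- function(x) {
    n <- softmax_to_occ(scheme, x)
    occ <- occupation_state(scheme, n)
    occ_energy_grad(functional, occ, ints, params)$energy
  }
  gr <- function(x) {
    n <- softmax_to_occ(scheme, x)
    occ <- occupation_state(scheme, n)
    g <- occ_energy_grad(functional, occ, ints, params)$grad
    softmax_chain(scheme, n, g)
  }
  x <- occ_to_softmax(scheme, state$n)
  gmax <- max(abs(gr(x)))
  round <- 0L
  while (gmax > gtol && round < max_rounds) {
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    x <- opt$par
    gmax <- max(abs(gr(x)))
    round <- round + 1L
  }
  state$n <- softmax_to_occ(scheme, x)
  state$grad_occ <- gmax
  refresh_energy(state)
}

# ---------------------------------------------------------------------------
# orbital optimization (rotation gradient + Armijo backtracking)
# ---------------------------------------------------------------------------

# electronic energy and rotation gradient at orbitals C
orbital_energy_grad <- function(ao, em, C, occ, functional, params,
                                want_grad = TRUE) {
  scheme <- occ$scheme
  m <- scheme$n_coupled
  nb <- em$n
  jk <- no_jk(ao, em, C, m)
  cjck <- build_cj_ck(functional, occ, params)
  e <- sum(2 * occ$n * jk$Hd) + sum(cjck$CJ * jk$J) + sum(cjck$CK * jk$K)
  if (!want_grad) return(list(energy = e))
  # generalized Fock per coupled orbital: F_p = n_p h + sum_q CJ_pq J^AO(q)
  # + CK_pq K^AO(q); Lambda_qp = <q|F_p|p>; gradient = 4 (Lambda - Lambda^T)
  JAO <- em$coul %*% jk$Dmat
  KAO <- em$exch %*% jk$Dmat
  Fcols <- JAO %*% t(cjck$CJ) + KAO %*% t(cjck$CK)
  Cc <- C[, seq_len(m), drop = FALSE]
  FC <- matrix(0, nb, m)
  hC <- ao$Hcore %*% Cc
  for (p in seq_len(m)) {
    FC[, p] <- matrix(Fcols[, p], nb, nb) %*% Cc[, p] + occ$n[p] * hC[, p]
  }
  Lam <- matrix(0, ncol(C), ncol(C))
  Lam[, seq_len(m)] <- crossprod(C, FC)
  G <- 2 * (Lam - t(Lam))
  list(energy = e, grad = G)
}

#' Optimize natural orbitals at fixed occupations
#'
#' Exponential orbital-rotation descent on the anti-symmetrized generalized
#' Fock (Lagrangian) gradient, with Armijo backtracking and a
#' Barzilai-Borwein initial step. At most `n_inner` accepted steps are taken;
#' S-orthonormality is restored after every step.
#'
#' @param state a `nof_state`.
#' @param functional functional label (defaults to the state's).
#' @param n_inner inner iteration budget.
#' @param gtol gradient tolerance on the rotation gradient.
#' @param step0 initial step size.
#' @return updated `nof_state` (with `grad_orb` set).
#' @export
optimize_orbitals <- function(state, functional = state$functional,
                              n_inner = 30, gtol = 1e-5, step0 = 0.05) {
  ao <- state$ao
  if (is.null(state$em)) state$em <- eri_mats(ao)
  em <- state$em
  scheme <- state$scheme
  occ <- occupation_state(scheme, state$n)
  C0 <- state$C
  nb <- ncol(C0)
  m <- scheme$n_coupled
  # rotation parameters: pairs (p < q) with at least one coupled orbital
  pairs <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] <= m | pairs[, 2] <= m, , drop = FALSE]
  if (nrow(pairs) == 0) {
    state$grad_orb <- 0
    return(refresh_energy(state))
  }
  to_skew <- function(x) {
    X <- matrix(0, nb, nb)
    X[pairs] <- x
    X - t(X)
  }
  rotate <- function(x) lowdin(C0 %*% expm_skew(to_skew(x)), ao$S)
  fn <- function(x) orbital_energy_grad(ao, em, rotate(x), occ, functional,
                                        state$params, want_grad = FALSE)$energy
  gr <- function(x) {
    G <- orbital_energy_grad(ao, em, rotate(x), occ, functional,
                             state$params)$grad
    G[pairs]
  }
  x0 <- numeric(nrow(pairs))
  g0 <- gr(x0)
  if (max(abs(g0)) >= gtol) {
    opt <- stats::optim(x0, fn, gr, method = "BFGS",
                        control = list(maxit = n_inner, reltol = 1e-15))
    if (opt$value <= state$energy$e_elec + 1e-12) {
      state$C <- rotate(opt$par)
    }
  }
  state$em <- em
  Gf <- orbital_energy_grad(ao, em, state$C, occ, functional,
                            state$params)$grad
  state$grad_orb <- max(abs(Gf))
  refresh_energy(state)
}

# ---------------------------------------------------------------------------
# outer loop
# ---------------------------------------------------------------------------

#' Solve the NOF equations for a prepared state
#'
#' Alternates [optimize_occupations()] and [optimize_orbitals()] until the
#' outer-iteration energy change falls below `etol` and both gradient
#' criteria are met.
#'
#' @param state an initialized `nof_state`.
#' @param gtol occupation-gradient tolerance (default `1e-4`).
#' @param otol orbital-gradient tolerance.
#' @param etol outer-iteration energy tolerance (hartree).
#' @param n_inner inner orbital iterations per outer iteration.
#' @param max_outer maximum outer iterations.
#' @param verbose print a log line per outer iteration.
#' @return converged (or flagged non-converged) `nof_state` with a `history`
#'   data.frame.
#' @export
solve_state <- function(state, gtol = 1e-4, otol = 1e-4, etol = 1e-8,
                        n_inner = 30, max_outer = 1000, verbose = FALSE) {
  hist <- data.frame(iter = integer(0), e_total = numeric(0),
                     delta_e = numeric(0), grad_occ = numeric(0),
                     grad_orb = numeric(0))
  e_prev <- state$energy$e_total
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    state <- optimize_occupations(state, gtol = gtol)
    state <- optimize_orbitals(state, n_inner = n_inner, gtol = otol)
    e <- state$energy$e_total
    de <- e - e_prev
    hist <- rbind(hist, data.frame(iter = it, e_total = e, delta_e = de,
                                   grad_occ = state$grad_occ,
                                   grad_orb = state$grad_orb))
    if (verbose)
      message(sprintf("outer %3d  E = %.10f  dE = %+.3e  |g_occ| = %.2e  |g_orb| = %.2e",
                      it, e, de, state$grad_occ, state$grad_orb))
    if (abs(de) < etol && state$grad_occ <= gtol && state$grad_orb <= otol) {
      converged <- TRUE
      e_prev <- e
      break
    }
    e_prev <- e
  }
  # restore the slot convention (strong slot holds the subspace's largest
  # occupation; a pure relabeling) and polish occupations at the final
  # orbitals
  state <- canonicalize_slots(state)
  state <- optimize_occupations(state, gtol = gtol)
  state$history <- hist
  state$converged <- converged
  state
}

# swap orbital columns/occupations so each paired subspace's strong slot
# carries its largest occupation
canonicalize_slots <- function(state) {
  scheme <- state$scheme
  reg <- scheme$region[seq_len(scheme$n_coupled)]
  sub <- scheme$subspace[seq_len(scheme$n_coupled)]
  changed <- FALSE
  for (g in seq_len(scheme$n_pairs)) {
    gs <- which(reg == "strong" & sub == g)
    w <- which(reg == "weak" & sub == g)
    if (!length(w)) next
    wm <- w[which.max(state$n[w])]
    if (state$n[wm] > state$n[gs] + 1e-12) {
      state$n[c(gs, wm)] <- state$n[c(wm, gs)]
      state$C[, c(gs, wm)] <- state$C[, c(wm, gs)]
      changed <- TRUE
    }
  }
  if (changed) state <- refresh_energy(state)
  state
}

#' Fit an electron-pairing natural orbital functional
#'
#' The main entry point: builds the pairing partition and AO integrals,
#' initializes from a mean-field guess (or a donor solution) and solves the
#' NOF equations by alternating occupation and orbital optimization.
#'
#' @param system a [molecular_system()] with coordinates.
#' @param basis basis set name (e.g. `"sto-3g"`).
#' @param functional `"PNOF5"`, `"PNOF7s"`, `"PNOF7"` or `"GNOF"`.
#' @param coupling `"perfect"`, `"extended"`, or an explicit integer `N_g`.
#' @param ri use Cholesky-factorized ERIs.
#' @param warm_from optional donor `nof_state` (same system dimensions) whose
#'   orbitals and occupations seed the optimization.
#' @param gtol,otol,etol,n_inner,max_outer,delta solver controls, see
#'   [solve_state()] and [init_state()].
#' @param params dynamic-occupation parameters ([dyn_params()]).
#' @param verbose print per-iteration log lines.
#' @return an object of class `"nof"` (also a `nof_state`) with the orbitals,
#'   occupations, energy breakdown and convergence history.
#' @examples
#' \donttest{
#' h2 <- make_fixture("H2", R = 0.74)
#' fit <- nof(h2$system, h2$basis, functional = "PNOF5", coupling = "perfect")
#' summary(fit)
#' }
#' @export
nof <- function(system, basis, functional = "GNOF", coupling = "perfect",
                ri = FALSE, warm_from = NULL, gtol = 1e-4, otol = 1e-4,
                etol = 1e-8, n_inner = 30, max_outer = 1000, delta = 1e-2,
                params = dyn_params(), verbose = FALSE) {
  functional <- match.arg(functional, NOF_FUNCTIONALS)
  ao <- if (inherits(basis, "ao_integrals")) basis
        else ao_integrals(system, basis, ri = ri)
  scheme <- pairing_scheme(system, ao$n_basis, coupling)
  state <- if (is.null(warm_from)) {
    init_state(system, scheme, ao, functional, "hf_guess", delta = delta,
               params = params)
  } else {
    init_state(system, scheme, ao, functional, "warm_start",
               donor = warm_from, params = params)
  }
  state <- solve_state(state, gtol = gtol, otol = otol, etol = etol,
                       n_inner = n_inner, max_outer = max_outer,
                       verbose = verbose)
  state$basis_name <- if (is.character(basis)) basis else ao$basis_name
  state$coupling <- coupling
  class(state) <- c("nof", class(state))
  state
}

#' Chain functionals through warm starts
#'
#' Solves the same system with a sequence of functionals, each warm-started
#' from the previous solution (e.g. `c("PNOF7s", "GNOF")`, the protocol used
#' to reach GNOF solutions from PNOF7s ones).
#'
#' @inheritParams nof
#' @param functionals character vector of functional labels, applied in order.
#' @param ... further arguments passed to [nof()].
#' @return named list of `nof` fits, one per functional.
#' @export
nof_chain <- function(system, basis, functionals = c("PNOF7s", "GNOF"),
                      coupling = "perfect", ...) {
  fits <- list()
  donor <- NULL
  ao <- if (inherits(basis, "ao_integrals")) basis
        else ao_integrals(system, basis)
  for (f in functionals) {
    fits[[f]] <- nof(system, ao, functional = f, coupling = coupling,
                     warm_from = donor, ...)
    fits[[f]]$warm_from_functional <-
      if (is.null(donor)) NA_character_ else donor$functional
    donor <- fits[[f]]
  }
  fits
}

#' Multi-start search for distinct stationary solutions
#'
#' Runs a mean-field-guess start plus warm-start chains and reports every
#' distinct stationary point found, ranked by energy. Mirrors the caution
#' that single-start NOF solutions can be local minima.
#'
#' @inheritParams nof
#' @param chains list of functional chains; each chain is run with
#'   [nof_chain()] and its final state (for the target functional) collected.
#' @param functional target functional for the reported solutions.
#' @param dedup_tol energies within this tolerance (hartree) count as the same
#'   solution.
#' @param ... further arguments passed to [nof()].
#' @return list with `solutions` (list of `nof` fits sorted by energy) and
#'   `energies`.
#' @export
nof_multistart <- function(system, basis, functional = "GNOF",
                           coupling = "perfect",
                           chains = list(functional,
                                         c("PNOF7s", functional)),
                           dedup_tol = 1e-6, ...) {
  ao <- if (inherits(basis, "ao_integrals")) basis
        else ao_integrals(system, basis)
  sols <- list()
  for (ch in chains) {
    fits <- nof_chain(system, ao, functionals = ch, coupling = coupling, ...)
    sols[[length(sols) + 1L]] <- fits[[length(fits)]]
  }
  e <- vapply(sols, function(s) s$energy$e_total, numeric(1))
  ord <- order(e)
  sols <- sols[ord]
  e <- e[ord]
  keep <- c(TRUE, diff(e) > dedup_tol)
  list(solutions = sols[keep], energies = e[keep])
}
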