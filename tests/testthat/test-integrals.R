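test_that("engine matches closed-form s-Gaussian integrals on an H4 chain", {
  fx <- make_fixture("H4_chain", R = 0.9)
  ao <- ao_integrals(fx$system, "sto-3g")
  xyz <- as.matrix(fx$system$atoms[, c("x", "y", "z")]) * pnof:::ANGSTROM_TO_BOHR
  hdef <- pnof:::.basis_library[["sto-3g"]]$H[[1]]
  shells <- lapply(1:4, function(i) list(atom = i, exp = hdef$exp,
                                         coef = hdef$coef))
  orc <- s_oracle_integrals(xyz, rep(1, 4), shells)
  expect_lt(max(abs(ao$S - orc$S)), 1e-10)
  expect_lt(max(abs(ao$T - orc$T)), 1e-10)
  expect_lt(max(abs(ao$V - orc$V)), 1e-10)
  expect_lt(max(abs(ao$Hcore - orc$Hcore)), 1e-10)
  expect_lt(max(abs(ao$eri - orc$eri)), 1e-10)
})

test_that("AO matrices satisfy their structural invariants", {
  w <- h2o_631g()
  ao <- w$ao
  expect_equal(ao$Hcore, t(ao$Hcore), tolerance = 1e-12)
  expect_gt(min(eigen(ao$S, symmetric = TRUE)$values), 0)
  expect_equal(diag(ao$S), rep(1, ao$n_basis), tolerance = 1e-12)
  # 8-fold permutational symmetry, spot checks
  set.seed(7)
  for (k in 1:20) {
    i <- sample(ao$n_basis, 4, replace = TRUE)
    v <- ao$eri[i[1], i[2], i[3], i[4]]
    expect_equal(ao$eri[i[2], i[1], i[3], i[4]], v, tolerance = 1e-10)
    expect_equal(ao$eri[i[3], i[4], i[1], i[2]], v, tolerance = 1e-10)
    expect_equal(ao$eri[i[4], i[3], i[2], i[1]], v, tolerance = 1e-10)
  }
  # overlap bounds on a bonded pair
  h2 <- h2_ao(0.74)
  expect_gt(h2$S[1, 2], 0)
  expect_lt(h2$S[1, 2], 1)
})

test_that("total energies are invariant under rigid rotation (p shells)", {
  fx <- make_fixture("H2O", basis = "6-31g")
  geom <- fx$system$atoms
  th <- 0.73
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rot <- geom
  rot[, c("x", "y", "z")] <- as.matrix(geom[, c("x", "y", "z")]) %*% t(Rz)
  sys2 <- molecular_system(rot, 0, 1)
  e_mf <- function(sys) {
    ao <- if (identical(sys, fx$system)) h2o_631g()$ao
          else ao_integrals(sys, "6-31g")
    scheme <- pairing_scheme(sys, ao$n_basis, "perfect")
    C <- pnof:::mean_field_orbitals(ao, scheme)
    npat <- numeric(ao$n_basis)
    npat[scheme$region == "strong"] <- 1
    D <- C %*% (2 * npat * t(C))
    em <- pnof:::eri_mats(ao)
    Jm <- matrix(em$coul %*% as.numeric(D), ao$n_basis, ao$n_basis)
    Km <- matrix(em$exch %*% as.numeric(D), ao$n_basis, ao$n_basis)
    sum(D * (ao$Hcore + 0.5 * (Jm - 0.5 * Km))) + sys$e_nuclear
  }
  expect_equal(e_mf(fx$system), e_mf(sys2), tolerance = 1e-8)
})

test_that("optimized transform equals the explicit-loop oracle", {
  fx <- make_fixture("H2O")
  ao <- ao_integrals(fx$system, "sto-3g")   # 7 basis functions
  set.seed(11)
  C <- pnof:::lowdin(matrix(rnorm(ao$n_basis^2), ao$n_basis), ao$S)
  m <- 4
  G_fast <- pnof:::contract4(ao$eri, C[, seq_len(m), drop = FALSE])
  G_slow <- naive_transform(ao$eri, C, m)
  expect_lt(max(abs(G_fast - G_slow)), 1e-10)

  fx <- make_fixture("H4_chain", R = 1.0)
  ao <- h4_ao(1.0)
  scheme <- pairing_scheme(fx$system, ao$n_basis, "perfect")
  set.seed(12)
  C <- pnof:::lowdin(matrix(rnorm(ao$n_basis^2), ao$n_basis), ao$S)
  ints <- transform_to_no_basis(ao, C, scheme)
  Gc <- pnof:::contract4(ao$eri, C[, seq_len(scheme$n_coupled), drop = FALSE])
  for (p in 1:3) for (q in 1:3) {
    expect_equal(ints$J[p, q], Gc[p, p, q, q], tolerance = 1e-12)
    expect_equal(ints$K[p, q], Gc[p, q, p, q], tolerance = 1e-12)
  }
  expect_equal(ints$L, ints$K)       # real orbitals
  expect_equal(ints$J, t(ints$J), tolerance = 1e-12)

  # trace of the one-electron matrix is invariant under orthogonal rotation
  Q <- qr.Q(qr(matrix(rnorm(ao$n_basis^2), ao$n_basis)))
  ints2 <- transform_to_no_basis(ao, C %*% Q, scheme)
  expect_equal(sum(diag(ints$H)), sum(diag(ints2$H)), tolerance = 1e-10)

  # non-orthonormal coefficients are rejected
  expect_error(transform_to_no_basis(ao, C * 1.01, scheme), "orthonormal")
})

test_that("Cholesky-factorized ERIs reproduce the full tensor", {
  fx <- make_fixture("H2O")
  ao_full <- ao_integrals(fx$system, "6-31g(d)")
  ao_ri <- ao_integrals(fx$system, "6-31g(d)", ri = TRUE, ri_tol = 1e-6)
  expect_lt(max(abs(ao_ri$eri - ao_full$eri)), 1e-4)
  expect_lt(ao_ri$ri_rank, ao_full$n_basis^2)
  # factors are genuinely three-index: B^T B reassembles the matrixized ERI
  n <- ao_full$n_basis
  E <- matrix(ao_full$eri, n * n, n * n)
  expect_lt(max(abs(crossprod(ao_ri$ri_b) - E)), 1e-4)
})

test_that("RI and full-ERI NOF energies agree", {
  w <- h2o_631g()
  ao_ri <- ao_integrals(w$fx$system, "6-31g", ri = TRUE, ri_tol = 1e-8)
  e_full <- nof(w$fx$system, w$ao, functional = "PNOF5",
                coupling = "extended")$energy$e_total
  e_ri <- nof(w$fx$system, ao_ri, functional = "PNOF5",
              coupling = "extended")$energy$e_total
  expect_lt(abs(e_full - e_ri), 1e-3)
})

test_that("basis-function counting reproduces published compositions", {
  fep <- molecular_system(c("Fe", rep("N", 4), rep("C", 20), rep("H", 12)),
                          0, 3)
  expect_equal(count_basis_functions(fep, "cc-pvdz"), 465L)
  h <- molecular_system("H", 0, 2)
  expect_equal(count_basis_functions(h, "sto-3g"), 1L)
  # independent per-element spherical count: H [2s1p] = 5, O [3s2p1d] = 14
  h2o <- molecular_system(c("O", "H", "H"), 0, 1)
  expect_equal(count_basis_functions(h2o, "cc-pvdz"), 14L + 2L * 5L)
  expect_error(count_basis_functions(h2o, "no-such-basis"), "not available")
})
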