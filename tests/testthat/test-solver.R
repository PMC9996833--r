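test_that("mean-field starts are feasible and warm starts are faithful", {
  ao <- h2_ao(0.74)
  sys <- make_fixture("H2")$system
  scheme <- pairing_scheme(sys, 2, "perfect")
  st <- init_state(sys, scheme, ao, "PNOF5", delta = 1e-2)
  expect_equal(st$n, c(1 - 1e-2, 1e-2))
  expect_equal(sum(st$n), 1, tolerance = 1e-14)
  # warm start re-evaluates to the donor energy with the donor functional
  solved <- solve_state(st)
  st2 <- init_state(sys, scheme, ao, "PNOF5", "warm_start", donor = solved)
  expect_equal(st2$energy$e_total, solved$energy$e_total, tolerance = 1e-10)
  # incompatible donors are rejected
  sys4 <- make_fixture("H4_chain")$system
  ao4 <- h4_ao(1.2)
  s4 <- pairing_scheme(sys4, 4, "perfect")
  expect_error(init_state(sys4, s4, ao4, "PNOF5", "warm_start",
                          donor = solved), "incompatible")
})

test_that("occupation optimization reproduces FCI natural occupations on H2", {
  ao <- h2_ao(0.74)
  fx <- make_fixture("H2")
  fit <- nof(fx$system, ao, functional = "PNOF5", gtol = 1e-6)
  orc <- fci(ao, fx$system)
  expect_lt(max(abs(sort(fit$n, decreasing = TRUE) - orc$occupations)), 1e-4)
  # idempotence: re-optimizing a converged state leaves it unchanged
  n_before <- fit$n
  fit2 <- optimize_occupations(fit)
  expect_equal(fit2$n, n_before, tolerance = 1e-8)
  expect_equal(fit2$energy$e_total, fit$energy$e_total, tolerance = 1e-10)
})

test_that("occupations leave integers on a dynamically correlated system", {
  fit <- h2o_gnof_fit()
  reg <- fit$scheme$region[seq_len(fit$scheme$n_coupled)]
  expect_gt(max(fit$n[reg == "weak"]), 1e-3)
  expect_lt(max(fit$n[reg == "weak"]), 0.1)   # dynamic, not static
  nd <- dynamic_occupations(occupation_state(fit$scheme, fit$n))
  expect_gt(max(nd), 1e-4)
})

test_that("orbital optimization respects its contracts", {
  # H atom: single basis function, orbitals invariant
  h <- make_fixture("H")
  aoh <- ao_integrals(h$system, "sto-3g")
  sh <- pairing_scheme(h$system, 1, "perfect")
  st <- init_state(h$system, sh, aoh, "PNOF5")
  st2 <- optimize_orbitals(st)
  expect_equal(abs(st2$C), matrix(1, 1, 1), tolerance = 1e-10)

  # H2: converges onto the FCI natural orbitals (gerade/ungerade pair)
  ao <- h2_ao(0.74)
  fx <- make_fixture("H2")
  fit <- nof(fx$system, ao, functional = "PNOF5")
  orc <- fci(ao, fx$system)
  scheme <- pairing_scheme(fx$system, 2, "perfect")
  Cmf <- pnof:::mean_field_orbitals(ao, scheme)
  no_mo <- eigen(orc$rdm1, symmetric = TRUE)$vectors  # MO-basis NOs
  C_fci <- Cmf %*% no_mo
  ov <- abs(crossprod(fit$C[, 1], ao$S %*% C_fci))
  expect_gt(max(ov), 0.9999)

  # orthonormality restored tightly after optimization
  dev <- max(abs(crossprod(fit$C, ao$S %*% fit$C) - diag(2)))
  expect_lt(dev, 1e-10)
})

test_that("outer iterations descend and the solver is deterministic", {
  fx <- make_fixture("H4_chain", R = 1.2)
  ao <- h4_ao(1.2)
  for (f in c("PNOF5", "GNOF")) {
    fit <- nof(fx$system, ao, functional = f, coupling = "extended")
    expect_true(all(fit$history$delta_e <= 1e-8))
    expect_true(fit$converged)
  }
  f1 <- nof(fx$system, ao, functional = "PNOF7", coupling = "extended")
  f2 <- nof(fx$system, ao, functional = "PNOF7", coupling = "extended")
  expect_identical(f1$history$e_total, f2$history$e_total)
  expect_identical(f1$energy$e_total, f2$energy$e_total)
})

test_that("pair functional matches FCI for two-electron systems", {
  for (R in c(0.74, 1.5, 3.0, 6.0)) {
    fx <- make_fixture("H2", R = R)
    ao <- h2_ao(R)
    fit <- nof(fx$system, ao, functional = "PNOF5")
    orc <- fci(ao, fx$system)
    expect_lt(abs(fit$energy$e_total - orc$e_total), 1e-6)
    expect_true(fit$converged)
  }
})

test_that("homolytic dissociation is size consistent", {
  h <- make_fixture("H")
  e_h <- nof(h$system, h$basis, functional = "PNOF5")$energy$e_total
  fx <- make_fixture("H2", R = 100)
  e_h2 <- nof(fx$system, h2_ao(100), functional = "PNOF5")$energy$e_total
  expect_lt(abs(e_h2 - 2 * e_h), 1e-4)
})

test_that("analytic occupation gradients agree with central differences", {
  fit <- h2o_gnof_fit()
  scheme <- fit$scheme
  ints <- fit$ints
  x <- pnof:::occ_to_softmax(scheme, fit$n)
  for (f in c("PNOF5", "PNOF7s", "PNOF7", "GNOF")) {
    fn <- function(xx) {
      occ <- occupation_state(scheme, pnof:::softmax_to_occ(scheme, xx))
      pnof:::occ_energy_grad(f, occ, ints)$energy
    }
    nn <- pnof:::softmax_to_occ(scheme, x)
    occ <- occupation_state(scheme, nn)
    ga <- pnof:::softmax_chain(scheme, nn,
                               pnof:::occ_energy_grad(f, occ, ints)$grad)
    gn <- vapply(seq_along(x), function(i) {
      h <- 1e-5
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (fn(xp) - fn(xm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga - gn)), 1e-6)
  }
})

test_that("multi-start reports distinct stationary solutions ranked by energy", {
  fx <- make_fixture("H4_chain", R = 1.6)
  ao <- ao_integrals(fx$system, "sto-3g")
  ms <- nof_multistart(fx$system, ao, functional = "GNOF",
                       coupling = "extended")
  expect_gte(length(ms$solutions), 1)
  expect_true(all(diff(ms$energies) >= 0))
  for (s in ms$solutions) expect_lte(s$grad_occ, 1e-4)
})

test_that("single-electron occupations never drift from one half", {
  g <- pnof:::as_geometry(c("H", "H"), rbind(c(0, 0, -0.4), c(0, 0, 0.4)))
  sys <- molecular_system(g, 0, 3)      # triplet: two single electrons
  ao <- ao_integrals(sys, "sto-3g")
  fit <- nof(sys, ao, functional = "GNOF")
  reg <- fit$scheme$region[seq_len(fit$scheme$n_coupled)]
  expect_identical(fit$n[reg == "single"], c(0.5, 0.5))
  # the multiplet treatment is exact for two high-spin electrons
  orc <- fci(ao, sys)
  expect_lt(abs(fit$energy$e_total - orc$e_total), 1e-8)
})
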