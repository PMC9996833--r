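# The energy terms are cross-checked against independently transcribed
# plain-loop oracles (helper-oracles.R) on deterministic occupation states.

scheme_of <- function(ao, sys, coupling = "extended")
  pairing_scheme(sys, ao$n_basis, coupling)

test_that("dynamic occupation parts behave as specified", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  # zero occupation -> zero dynamic part
  occ0 <- pnof:::occupation_pattern(scheme, delta = 0)
  nd0 <- dynamic_occupations(occ0)
  expect_equal(nd0[scheme$region[seq_along(nd0)] == "weak"],
               rep(0, sum(scheme$region[seq_along(nd0)] == "weak")))
  # maximum over the dense grid sits at the Pulay scale
  expect_lt(abs(dynamic_occupation_max() - 0.012), 0.002)
  # double-transcription oracle on a deterministic state
  occ <- random_occupation(scheme, seed = 4, concentrate = 5)
  m <- scheme$n_coupled
  expect_equal(dynamic_occupations(occ),
               oracle_dynamic_occ(occ$n, scheme$subspace[1:m],
                                  scheme$region[1:m]),
               tolerance = 1e-13)
  # never exceeds the cap (dense scan via many states)
  for (s in 1:5) {
    o <- random_occupation(scheme, seed = s, concentrate = 4)
    expect_true(all(dynamic_occupations(o) <= 0.012131 + 1e-9))
  }
})

test_that("Phi amplitudes vanish at integer occupations and peak at 1/2", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  occ0 <- pnof:::occupation_pattern(scheme, delta = 0)
  expect_equal(phi_values(occ0, "gnof_pnof7"),
               ifelse(scheme$region[seq_len(scheme$n_coupled)] == "single",
                      0.5, 0))
  expect_equal(phi_values(occ0, "pnof7s"),
               ifelse(scheme$region[seq_len(scheme$n_coupled)] == "single",
                      0.5, 0))
  occ <- random_occupation(scheme, seed = 2)
  expect_equal(phi_values(occ, "pnof7s"), 2 * occ$n * (1 - occ$n))
  expect_equal(phi_values(occ, "gnof_pnof7"), sqrt(occ$n * (1 - occ$n)),
               tolerance = 1e-12)
})

test_that("pair-coupling matrix carries the printed sign structure", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  occ <- random_occupation(scheme, seed = 3)
  P <- pi_matrix(occ, "intrapair")
  m <- scheme$n_coupled
  reg <- scheme$region[1:m]; sub <- scheme$subspace[1:m]
  for (g in 1:scheme$n_pairs) {
    gs <- which(reg == "strong" & sub == g)
    ws <- which(reg == "weak" & sub == g)
    expect_true(all(P[gs, ws] < 0))               # strong-weak negative
    if (length(ws) > 1)
      expect_true(all(P[ws, ws][upper.tri(diag(length(ws)))] > 0))
  }
  expect_true(all(P[sub == 1, sub == 2] == 0))    # intrapair only
  expect_equal(diag(P), rep(0, m))
})

test_that("intrapair energy reproduces its closed-shell and one-electron limits", {
  # closed-shell pair: n = (1, 0) on minimal-basis H2 -> 2 H_11 + J_11
  ao <- h2_ao(0.74)
  sys <- make_fixture("H2")$system
  scheme <- pairing_scheme(sys, 2, "perfect")
  C <- pnof:::mean_field_orbitals(ao, scheme)
  ints <- transform_to_no_basis(ao, C, scheme)
  occ1 <- occupation_state(scheme, c(1, 0))
  expect_equal(intrapair_energy(occ1, ints),
               2 * ints$Hd[1] + ints$J[1, 1], tolerance = 1e-12)
  # one-electron limit: H atom, E_intra = H_11
  h <- make_fixture("H")
  aoh <- ao_integrals(h$system, "sto-3g")
  sh <- pairing_scheme(h$system, 1, "perfect")
  Ch <- matrix(1, 1, 1)
  ih <- transform_to_no_basis(aoh, Ch, sh)
  oh <- occupation_state(sh, 0.5)
  expect_equal(intrapair_energy(oh, ih), ih$Hd[1], tolerance = 1e-12)
})

test_that("interspace HF term matches hand evaluation and the loop oracle", {
  # single subspace -> no intersubspace pairs
  ao <- h2_ao(0.74)
  sys <- make_fixture("H2")$system
  scheme <- pairing_scheme(sys, 2, "perfect")
  C <- pnof:::mean_field_orbitals(ao, scheme)
  ints <- transform_to_no_basis(ao, C, scheme)
  occ <- occupation_state(scheme, c(0.9, 0.1))
  expect_equal(hf_inter_energy(occ, ints), 0)

  # two closed pairs with integer occupations -> 4 J_12 - 2 K_12
  fx4 <- make_fixture("H4_chain", R = 1.0)
  ao4 <- h4_ao(1.0)
  s4 <- pairing_scheme(fx4$system, 4, "perfect")
  C4 <- pnof:::mean_field_orbitals(ao4, s4)
  i4 <- transform_to_no_basis(ao4, C4, s4)
  occ4 <- occupation_state(s4, c(1, 1, 0, 0))
  expect_equal(hf_inter_energy(occ4, i4),
               4 * i4$J[1, 2] - 2 * i4$K[1, 2], tolerance = 1e-12)

  # loop oracle on a general state
  occr <- random_occupation(s4, seed = 5)
  expect_equal(hf_inter_energy(occr, i4),
               oracle_hf_inter(occr$n, s4$subspace[1:4], i4$J, i4$K),
               tolerance = 1e-12)
})

test_that("static interspace term matches the loop oracle and lowers energy", {
  fx4 <- make_fixture("H4_chain", R = 1.2)
  ao4 <- h4_ao(1.2)
  s4 <- pairing_scheme(fx4$system, 4, "perfect")
  C4 <- pnof:::mean_field_orbitals(ao4, s4)
  i4 <- transform_to_no_basis(ao4, C4, s4)
  occ0 <- pnof:::occupation_pattern(s4, delta = 0)
  expect_equal(static_inter_energy(occ0, i4, "gnof_pnof7"), 0)

  occ <- random_occupation(s4, seed = 6, concentrate = 2)
  m <- s4$n_coupled
  for (v in c("gnof_pnof7", "pnof7s")) {
    expect_equal(static_inter_energy(occ, i4, v),
                 oracle_static_inter(occ$n, s4$subspace[1:m], i4$K,
                                     if (v == "pnof7s") "2nh" else "sqrt"),
                 tolerance = 1e-12)
  }
  # the static term lowers the energy relative to PNOF5 at the same state
  e5 <- total_energy("PNOF5", occ, i4)$e_elec
  e7 <- total_energy("PNOF7", occ, i4)$e_elec
  expect_lt(e7, e5)
})

test_that("dynamic interspace term matches its oracle and cancellation claim", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  sys <- w$fx$system
  C <- pnof:::mean_field_orbitals(w$ao, scheme)
  ints <- transform_to_no_basis(w$ao, C, scheme)
  m <- scheme$n_coupled

  occ0 <- pnof:::occupation_pattern(scheme, delta = 0)
  expect_equal(dynamic_inter_energy(occ0, ints), 0)

  occ <- random_occupation(scheme, seed = 8, concentrate = 5)
  expect_equal(dynamic_inter_energy(occ, ints),
               oracle_dynamic_inter(occ$n, scheme$subspace[1:m],
                                    scheme$region[1:m], ints$J, ints$K),
               tolerance = 1e-12)

  # in the n ~ n^d regime (holes well inside the Pulay scale) the ON-product
  # part is negligible next to the Pi-proportional part
  nsmall <- numeric(m)
  reg <- scheme$region[1:m]
  nsmall[reg == "strong"] <- 1 - 1e-4
  nsmall[reg == "weak"] <- 1e-4 / scheme$n_g
  occs <- occupation_state(scheme, nsmall)
  parts <- dynamic_inter_energy(occs, ints, parts = TRUE)
  expect_lt(abs(parts$on_product), 0.01 * abs(parts$pi))
})

test_that("functional reductions hold bitwise at fixed occupations", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  C <- pnof:::mean_field_orbitals(w$ao, scheme)
  ints <- transform_to_no_basis(w$ao, C, scheme)
  occ <- random_occupation(scheme, seed = 9, concentrate = 4)
  eg <- total_energy("GNOF", occ, ints)
  e7 <- total_energy("PNOF7", occ, ints)
  e7s <- total_energy("PNOF7s", occ, ints)
  e5 <- total_energy("PNOF5", occ, ints)
  # GNOF with the dynamic term removed is PNOF7, term by term, bitwise
  expect_identical(e7$e_intra, eg$e_intra)
  expect_identical(e7$e_hf_inter, eg$e_hf_inter)
  expect_identical(e7$e_sta_inter, eg$e_sta_inter)
  expect_identical(e7$e_dyn_inter, 0)
  # PNOF5 drops both intersubspace correlation terms
  expect_identical(e5$e_intra, eg$e_intra)
  expect_identical(e5$e_hf_inter, eg$e_hf_inter)
  expect_identical(e5$e_sta_inter, 0)
  expect_identical(e5$e_dyn_inter, 0)
  # PNOF7s differs from PNOF7 only through Phi
  expect_identical(e7s$e_sta_inter,
                   static_inter_energy(occ, ints, "pnof7s"))
  expect_error(total_energy("PNOF6", occ, ints), "arg")
})

test_that("coefficient-matrix energy path agrees with the term assembly", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  C <- pnof:::mean_field_orbitals(w$ao, scheme)
  ints <- transform_to_no_basis(w$ao, C, scheme)
  for (f in c("PNOF5", "PNOF7s", "PNOF7", "GNOF")) {
    for (s in 1:3) {
      occ <- random_occupation(scheme, seed = s, concentrate = 3)
      e1 <- total_energy(f, occ, ints)$e_elec
      e2 <- pnof:::energy_from_cjck(occ, ints, pnof:::build_cj_ck(f, occ))
      expect_equal(e1, e2, tolerance = 1e-11)
    }
  }
})

test_that("intersubspace correlation terms are non-positive on solved fixtures", {
  for (fit in h4_fits(1.2)) {
    expect_lte(fit$energy$e_sta_inter, 1e-12)
    expect_lte(fit$energy$e_dyn_inter, 1e-12)
  }
  fit <- h2o_gnof_fit()
  expect_lte(fit$energy$e_sta_inter, 0)
  expect_lte(fit$energy$e_dyn_inter, 0)
})

test_that("dimension mismatches are caught", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  C <- pnof:::mean_field_orbitals(w$ao, scheme)
  ints <- transform_to_no_basis(w$ao, C, scheme)
  h2 <- make_fixture("H2")
  other <- pairing_scheme(h2$system, 2, "perfect")
  occ <- pnof:::occupation_pattern(other, delta = 0.01)
  expect_error(intrapair_energy(occ, ints), "mismatch")
  expect_error(hf_inter_energy(occ, ints), "mismatch")
})

test_that("energy reports serialize with component terms", {
  w <- h2o_631g()
  scheme <- scheme_of(w$ao, w$fx$system)
  C <- pnof:::mean_field_orbitals(w$ao, scheme)
  ints <- transform_to_no_basis(w$ao, C, scheme)
  occ <- random_occupation(scheme, seed = 1)
  eb <- total_energy("GNOF", occ, ints, e_nuclear = w$fx$system$e_nuclear)
  txt <- format_energy_report(eb)
  expect_match(txt, "E_dyn\\^inter")
  jf <- tempfile(fileext = ".json")
  format_energy_report(eb, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$e_total, eb$e_total, tolerance = 1e-12)
})
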