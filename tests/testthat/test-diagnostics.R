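fake_state <- function(scheme, n, system = NULL) {
  list(scheme = scheme, n = n, system = system)
}

test_that("M diagnostic reproduces its limiting values", {
  w <- h2o_631g()
  scheme <- pairing_scheme(w$fx$system, w$ao$n_basis, "extended")
  occ0 <- pnof:::occupation_pattern(scheme, delta = 0)
  expect_equal(m_diagnostic(fake_state(scheme, occ0$n))$M, 0)

  # stretched H2 diradical under perfect pairing: M = 1.00
  fx <- make_fixture("H2", R = 6.0)
  fit <- nof(fx$system, h2_ao(6.0), functional = "PNOF5")
  expect_equal(m_diagnostic(fit)$M, 1.00, tolerance = 1e-3)
  expect_equal(m_diagnostic(fit)$regime, "static-dominated")
})

test_that("M diagnostic agrees with the exhaustive-scan oracle", {
  w <- h2o_631g()
  scheme <- pairing_scheme(w$fx$system, w$ao$n_basis, "extended")
  m <- scheme$n_coupled
  for (s in 1:6) {
    occ <- random_occupation(scheme, seed = s, concentrate = s %% 3)
    got <- m_diagnostic(fake_state(scheme, occ$n))
    expect_equal(got$M, oracle_m(occ$n, scheme$region[1:m]),
                 tolerance = 1e-12)
    expect_lte(got$lsono_index, scheme$n_pairs)
    expect_gt(got$lwono_index, scheme$n_subspaces)
  }
})

test_that("M is invariant under relabeling weak partners within a subspace", {
  fx <- make_fixture("H4_chain", R = 1.0)
  sys <- fx$system
  scheme <- pairing_scheme(sys, 8, 3)   # explicit N_g = 3
  occ <- random_occupation(scheme, seed = 12)
  n2 <- occ$n
  reg <- scheme$region[seq_len(scheme$n_coupled)]
  sub <- scheme$subspace[seq_len(scheme$n_coupled)]
  w1 <- which(reg == "weak" & sub == 1)
  n2[w1] <- n2[rev(w1)]
  expect_equal(m_diagnostic(fake_state(scheme, occ$n))$M,
               m_diagnostic(fake_state(scheme, n2))$M)
})

test_that("regime classification follows the 0.1 threshold exactly", {
  sys <- molecular_system(c("H", "H", "H", "H"), 0, 1)
  scheme <- pairing_scheme(sys, 4, "perfect")
  # manufacture M exactly 0.1: LSONO hole 0.05, LWONO occupation 0.05
  n <- c(0.95, 0.96, 0.04, 0.05)
  md <- m_diagnostic(fake_state(scheme, n))
  expect_equal(md$M, 0.1)
  expect_equal(md$regime, "static-dominated")
  md2 <- m_diagnostic(fake_state(scheme, c(0.951, 0.96, 0.04, 0.049)))
  expect_equal(md2$regime, "dynamic-dominated")
})

test_that("M diagnostic refuses systems without a paired block", {
  h <- make_fixture("H")
  scheme <- pairing_scheme(h$system, 1, "perfect")
  expect_error(m_diagnostic(fake_state(scheme, 0.5)), "N_II = 0")
})

test_that("gap tables convert and sign as printed", {
  mk <- function(mult, e) {
    s <- fake_state(NULL, NULL)
    s$system <- list(multiplicity = mult)
    s$energy <- list(e_total = e)
    s$converged <- TRUE
    s
  }
  g0 <- gap_table(list(mk(1L, -10), mk(3L, -10), mk(5L, -10)))
  expect_equal(g0$st_gap, 0)
  expect_equal(g0$qt_gap, 0)
  g1 <- gap_table(list(mk(1L, -9.9), mk(3L, -10)))
  expect_equal(g1$st_gap, 62.7509, tolerance = 1e-6)
  expect_true(is.na(g1$qt_gap))
  expect_error(gap_table(list(mk(1L, -9.9), mk(5L, -10))), "triplet")
})

test_that("1RDM trace check is exact by construction and detects corruption", {
  fit <- h2o_gnof_fit()
  tc <- trace_check(fit)
  expect_true(tc$pass)
  expect_lt(tc$deviation, 1e-12)
  bumped <- fit
  bumped$n[2] <- bumped$n[2] + 1e-3
  tc2 <- trace_check(bumped)
  expect_false(tc2$pass)
  expect_equal(tc2$deviation, 2e-3, tolerance = 1e-10)
  # FeP reference arithmetic: the pattern traces to 186
  fep <- molecular_system(c("Fe", rep("N", 4), rep("C", 20), rep("H", 12)),
                          0, 3)
  sch <- pairing_scheme(fep, 465, "perfect")
  occ <- pnof:::occupation_pattern(sch, delta = 0.01)
  expect_equal(sum(2 * occ$n), 186, tolerance = 1e-10)
})

test_that("molden export round-trips the orbital coefficients", {
  fx <- make_fixture("H2")
  fit <- nof(fx$system, h2_ao(0.74), functional = "PNOF5")
  path <- tempfile(fileext = ".molden")
  export_orbitals(fit, path, selection = "all")
  back <- read_molden_orbitals(path)
  expect_lt(max(abs(back$C - fit$C)), 1e-8)
  # per-spin occupations sum to one electron pair
  expect_equal(sum(back$occupations) / 2, 1, tolerance = 1e-8)
})

test_that("cube-grid quadrature normalizes the orbital density", {
  fx <- make_fixture("H2")
  fit <- nof(fx$system, h2_ao(0.74), functional = "PNOF5")
  path <- tempfile(fileext = ".cube")
  cb <- write_cube(fit, 1, path, npts = 45, margin = 6)
  vol <- prod(cb$step)
  expect_equal(sum(cb$values^2) * vol, 1, tolerance = 1e-2)
  expect_true(file.exists(path))
  first <- readLines(path, n = 3)
  expect_match(first[3], "^\\s+2\\s")   # atom count line
})
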