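# Independent oracles and shared (memoized) fixtures for the test suite.
# Oracle code deliberately avoids the package's computational paths: the
# s-Gaussian formulas, the explicit-loop transform and the energy-term loops
# below are separate transcriptions used only for cross-checking.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# ---------------------------------------------------------------------------
# closed-form integrals over contracted s-type Gaussians (textbook formulas)
# ---------------------------------------------------------------------------

.boys0 <- function(x) ifelse(x < 1e-12, 1 - x / 3,
                             0.5 * sqrt(pi / x) * erf_(sqrt(x)))
erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# geometry: matrix (atoms x 3) in bohr; basis: list per atom of list(exp, coef)
s_oracle_integrals <- function(xyz, Z, shells) {
  # shells: list of list(atom, exp, coef)
  ns <- length(shells)
  prim_norm <- function(a) (2 * a / pi)^0.75
  S <- matrix(0, ns, ns); T <- matrix(0, ns, ns); V <- matrix(0, ns, ns)
  for (i in 1:ns) for (j in 1:ns) {
    A <- xyz[shells[[i]]$atom, ]; B <- xyz[shells[[j]]$atom, ]
    AB2 <- sum((A - B)^2)
    for (ip in seq_along(shells[[i]]$exp)) for (jp in seq_along(shells[[j]]$exp)) {
      a <- shells[[i]]$exp[ip]; b <- shells[[j]]$exp[jp]
      cc <- shells[[i]]$coef[ip] * shells[[j]]$coef[jp] *
        prim_norm(a) * prim_norm(b)
      p <- a + b; q <- a * b / p
      P <- (a * A + b * B) / p
      sp <- (pi / p)^1.5 * exp(-q * AB2)
      S[i, j] <- S[i, j] + cc * sp
      T[i, j] <- T[i, j] + cc * q * (3 - 2 * q * AB2) * sp
      for (ic in seq_len(nrow(xyz))) {
        PC2 <- sum((P - xyz[ic, ])^2)
        V[i, j] <- V[i, j] - cc * Z[ic] * 2 * pi / p * exp(-q * AB2) *
          .boys0(p * PC2)
      }
    }
  }
  eri <- array(0, dim = rep(ns, 4))
  for (i in 1:ns) for (j in 1:ns) for (k in 1:ns) for (l in 1:ns) {
    A <- xyz[shells[[i]]$atom, ]; B <- xyz[shells[[j]]$atom, ]
    Cc <- xyz[shells[[k]]$atom, ]; D <- xyz[shells[[l]]$atom, ]
    AB2 <- sum((A - B)^2); CD2 <- sum((Cc - D)^2)
    acc <- 0
    for (ip in seq_along(shells[[i]]$exp)) for (jp in seq_along(shells[[j]]$exp))
      for (kp in seq_along(shells[[k]]$exp)) for (lp in seq_along(shells[[l]]$exp)) {
        a <- shells[[i]]$exp[ip]; b <- shells[[j]]$exp[jp]
        c <- shells[[k]]$exp[kp]; d <- shells[[l]]$exp[lp]
        cc <- shells[[i]]$coef[ip] * shells[[j]]$coef[jp] *
          shells[[k]]$coef[kp] * shells[[l]]$coef[lp] *
          prim_norm(a) * prim_norm(b) * prim_norm(c) * prim_norm(d)
        p <- a + b; q <- c + d
        P <- (a * A + b * B) / p; Q <- (c * Cc + d * D) / q
        alpha <- p * q / (p + q)
        acc <- acc + cc * 2 * pi^2.5 / (p * q * sqrt(p + q)) *
          exp(-a * b / p * AB2 - c * d / q * CD2) *
          .boys0(alpha * sum((P - Q)^2))
      }
    eri[i, j, k, l] <- acc
  }
  # normalize contracted functions to unit overlap diagonal
  nrm <- 1 / sqrt(diag(S))
  Dn <- diag(nrm, ns)
  S <- Dn %*% S %*% Dn; T <- Dn %*% T %*% Dn; V <- Dn %*% V %*% Dn
  for (d1 in 1:4) eri <- sweep(eri, d1, nrm, `*`)
  list(S = S, T = T, V = V, Hcore = T + V, eri = eri)
}

# ---------------------------------------------------------------------------
# naive explicit-loop four-index transform (O(N^8) oracle)
# ---------------------------------------------------------------------------
naive_transform <- function(eri, C, m) {
  n <- dim(eri)[1]
  G <- array(0, dim = rep(m, 4))
  for (p in 1:m) for (q in 1:m) for (r in 1:m) for (s in 1:m) {
    acc <- 0
    for (mu in 1:n) for (nu in 1:n) for (la in 1:n) for (si in 1:n)
      acc <- acc + C[mu, p] * C[nu, q] * C[la, r] * C[si, s] *
        eri[mu, nu, la, si]
    G[p, q, r, s] <- acc
  }
  G
}

# ---------------------------------------------------------------------------
# independently transcribed energy-term loops (double-transcription oracles)
# ---------------------------------------------------------------------------

# interspace HF-like term, plain loops
oracle_hf_inter <- function(n, sub, J, K) {
  m <- length(n)
  e <- 0
  for (q in 1:m) for (p in 1:m)
    if (sub[q] != sub[p])
      e <- e + n[q] * n[p] * (2 * J[q, p] - K[q, p])
  e
}

# interspace static term, plain loops
oracle_static_inter <- function(n, sub, K, variant = "sqrt") {
  m <- length(n)
  phi <- if (variant == "sqrt") sqrt(n * (1 - n)) else 2 * n * (1 - n)
  e <- 0
  for (q in 1:m) for (p in 1:m)
    if (sub[q] != sub[p])
      e <- e - phi[q] * phi[p] * K[q, p]
  e
}

# dynamic occupations, plain loops (subspace hole gate, capped part)
oracle_dynamic_occ <- function(n, sub, region, h_c = 0.02 * sqrt(2)) {
  m <- length(n)
  nd <- numeric(m)
  for (p in 1:m) {
    if (region[p] == "single") next
    g <- sub[p]
    strong <- which(region == "strong" & sub == g)
    hg <- 1 - n[strong]
    nd[p] <- min(n[p], 1 - n[p]) * exp(-(hg / h_c)^2)
  }
  nd
}

# interspace dynamic term, plain loops
oracle_dynamic_inter <- function(n, sub, region, J, K, h_c = 0.02 * sqrt(2)) {
  m <- length(n)
  nd <- oracle_dynamic_occ(n, sub, region, h_c)
  sgn <- ifelse(region == "strong", 1, ifelse(region == "weak", -1, 0))
  cd <- sgn * sqrt(nd)
  e <- 0
  for (q in 1:m) for (p in 1:m) {
    if (sub[q] == sub[p]) next
    if (region[q] == "strong" && region[p] == "strong") next
    e <- e + cd[q] * cd[p] * K[q, p] - nd[q] * nd[p] * (2 * J[q, p] - K[q, p])
  }
  e
}

# exhaustive-scan M diagnostic oracle
oracle_m <- function(n, region) {
  strong <- which(region == "strong")
  weak <- which(region == "weak")
  worst_s <- strong[1]
  for (i in strong) if (abs(1 - n[i]) > abs(1 - n[worst_s])) worst_s <- i
  worst_w <- weak[1]
  for (i in weak) if (abs(n[i]) > abs(n[worst_w])) worst_w <- i
  (1 - n[worst_s]) + n[worst_w]
}

# ---------------------------------------------------------------------------
# shared fixtures (memoized; built once per test run)
# ---------------------------------------------------------------------------

h2_ao <- function(R = 0.74) cached(paste0("h2_ao_", R), {
  fx <- make_fixture("H2", R = R)
  ao_integrals(fx$system, "sto-3g")
})

h2o_631g <- function() cached("h2o_631g", {
  fx <- make_fixture("H2O", basis = "6-31g")
  list(fx = fx, ao = ao_integrals(fx$system, "6-31g"))
})

h2o_gnof_fit <- function() cached("h2o_gnof_fit", {
  w <- h2o_631g()
  nof(w$fx$system, w$ao, functional = "GNOF", coupling = "extended")
})

h4_ao <- function(R = 1.2) cached(paste0("h4_ao_", R), {
  fx <- make_fixture("H4_chain", R = R)
  ao_integrals(fx$system, "sto-3g")
})

h4_fits <- function(R = 1.2) cached(paste0("h4_fits_", R), {
  fx <- make_fixture("H4_chain", R = R)
  ao <- h4_ao(R)
  fits <- list()
  donor <- NULL
  for (f in c("PNOF5", "PNOF7s", "PNOF7", "GNOF"))
    fits[[f]] <- nof(fx$system, ao, functional = f, coupling = "extended")
  fits
})

# a deterministic valid occupation state on a given scheme
random_occupation <- function(scheme, seed = 1, concentrate = 0) {
  set.seed(seed)
  m <- scheme$n_coupled
  sub <- scheme$subspace[seq_len(m)]
  reg <- scheme$region[seq_len(m)]
  n <- numeric(m)
  n[reg == "single"] <- 0.5
  for (g in seq_len(scheme$n_pairs)) {
    idx <- which(sub == g & reg != "single")
    x <- rnorm(length(idx))
    x[1] <- x[1] + concentrate
    ex <- exp(x - max(x))
    n[idx] <- ex / sum(ex)
  }
  occupation_state(scheme, n)
}

# synthetic FeP-like geometry (correct composition and Fe-N distances only;
# carbon/hydrogen placement is schematic)
synthetic_fep_geometry <- function(fe_n = 1.976) {
  ang <- function(k, n, r, z = 0) {
    th <- 2 * pi * (seq_len(n) - 1) / n + k
    cbind(r * cos(th), r * sin(th), z)
  }
  xyz <- rbind(c(0, 0, 0),            # Fe
               ang(0, 4, fe_n),       # 4 N
               ang(pi / 20, 20, 3.0), # 20 C (schematic ring)
               ang(pi / 12, 12, 4.2)) # 12 H (schematic rim)
  data.frame(symbol = c("Fe", rep("N", 4), rep("C", 20), rep("H", 12)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
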