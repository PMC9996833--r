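---
title: "Electron-pairing natural orbital functionals: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-pairing natural orbital functionals: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnof)
```

## The model

Natural orbital functional (NOF) theory expresses the electronic energy as a
functional of the natural orbitals (NOs) and their occupation numbers (ONs),
the eigenvectors and eigenvalues of the one-particle reduced density matrix.
Fractional occupations give these functionals their ability to describe
static (near-degeneracy) correlation; the electron-pairing constraints give
them correct electron counts in dissociation fragments.

A state of total spin $S$ is treated as a multiplet of highest multiplicity
$2S+1$: $N_I = 2S$ single electrons occupy one orbital each with per-spin
occupation $n_g = 1/2$, and the remaining $N_{II} = N - N_I$ electrons are
spin-paired. A single set of real spatial orbitals serves both spins, so the
exchange-time-inversion integrals coincide with the exchange integrals
($L = K$); complex orbitals are typed but not implemented. The orbital space
is partitioned into $N_{II}/2$ mutually disjoint paired subspaces
$\Omega_g$, each containing one strongly occupied orbital (index
$g \le N_{II}/2$) and $N_g$ weakly occupied partners above
$N_\Omega = N_{II}/2 + N_I$, plus $N_I$ singleton subspaces. Per-spin
occupations obey $\sum_{p \in \Omega_g} n_p = 1$ in every paired subspace,
so the 1RDM trace equals $N$ identically — `trace_check()` verifies a
tautology, which is the point: the constraint is structural, not penalized.

The GNOF energy is assembled from four terms:

* **Intrapair**, $\sum_g \big[\sum_{p\in\Omega_g} n_p (2H_{pp} + J_{pp}) +
  \sum_{q \ne p} \Pi_{qp} L_{qp}\big] + \sum_{g \in \Omega_I} H_{gg}$, with
  $\Pi_{qp} = c_q c_p$ and $c_p = +\sqrt{n_p}$ in the strongly occupied
  block, $-\sqrt{n_p}$ above $N_\Omega$. For an isolated pair this is the
  exact two-electron energy in the natural expansion, which is what the FCI
  equivalence tests exercise.
* **Interspace HF**, $\sum'_{q,p} n_q n_p (2J_{qp} - K_{qp})$, the
  mean-field interaction between subspaces (the prime restricts sums to
  pairs in different subspaces).
* **Interspace static**, $-\sum'_{q,p} \Phi_q \Phi_p L_{qp}$ with
  $\Phi_p = \sqrt{n_p h_p}$, $h_p = 1 - n_p$: $\Phi$ is sizable only for
  fractional occupations, so this term switches on with near-degeneracy.
* **Interspace dynamic**, $\sum'_{q,p} \big[\Pi(n^d_q, n^d_p) L_{qp} -
  n^d_q n^d_p (2J_{qp} - K_{qp})\big]$, excluding pairs with both orbitals
  in the strongly occupied block and (because $n^d = 0$ there) all
  single-electron orbitals. The dynamic part of an occupation is
  $n_p^d = \min(n_p, h_p)\, e^{-(h_g/h_c)^2}$, gated by the hole $h_g$ of
  the subspace's strong orbital.

Reductions: dropping the dynamic term yields PNOF7; additionally taking
$\Phi_p = 2 n_p h_p$ yields PNOF7s; dropping both intersubspace correlation
terms yields PNOF5. The implementation makes these reductions definitional
— the terms are shared code — so the suite asserts them bitwise.

### Transcription of the energy expressions

The formulas above follow the published definitions of this functional
family, and the transcription is guarded by behavioural tests rather
than taken on faith: two-electron exactness against a determinant FCI oracle
(signs of $\Pi$), the $\approx 0.012$ maximum of $n^d$ (the gate constant),
bitwise reduction identities, the vanishing of $\Phi$ and $n^d$ at integer
occupations, and the cancellation of ON-product terms against the HF-like
term when $n \approx n^d$. The $\min(n_p, h_p)$ reading of the dynamic part
is forced by two constraints that a weak-orbital-only reading would violate:
the stated universal $\approx 0.012$ cap (a strongly occupied orbital's
deviation from integer occupation is its hole), and the MP2-like scale
$\sqrt{h^d_g n^d_p}$ of the resulting strong–weak amplitudes. With it, the
ON-product piece $-n^d_q n^d_p(2J-K)$ cancels the corresponding HF-like
contribution exactly in the $n = n^d$ limit, leaving the $\Pi$-proportional
coupling as the dynamic correlation — the behaviour the test suite asserts
quantitatively on the H₂O fixture.

### The M diagnostic

$M = (1 - n_{\mathrm{LSONO}}) + n_{\mathrm{LWONO}}$, where LSONO is the
orbital with ON farthest from 1 in the strongly occupied block and LWONO the
orbital with ON farthest from 0 above $N_\Omega$; ties break to the lowest
index for determinism. This form reproduces the published limits exactly:
$M = 0$ at integer occupations, $M = 1.00$ for a perfect-pairing diradical
($n = 1/2$ on both frontier NOs), and values near twice the typical hole in
the dynamic regime. The 0.1 regime boundary is applied as printed
($M \ge 0.1$ is static-dominated) and is configurable.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `h_c` | $0.02\sqrt{2}$ | occupation | hole cutoff gating $n^d$; sets the $\approx 0.012$ maximum |
| `coupling` | `"perfect"` | — | $N_g = 1$; `"extended"` takes the basis-set maximum $\lfloor (N_B - N_\Omega)/(N_{II}/2) \rfloor$ |
| `gtol` | $10^{-4}$ | hartree/var | occupation-gradient stop (BFGS) |
| `otol` | $10^{-4}$ | hartree | orbital rotation-gradient stop |
| `etol` | $10^{-8}$ | hartree | outer-iteration energy stop |
| `n_inner` | 30 | — | inner orbital iterations per outer iteration |
| `delta` | $10^{-2}$ | occupation | interior perturbation of the integer start, spread over weak partners (Pulay scale, keeps $\Phi$ and $n^d$ differentiable) |
| `mix_angle` | 0.05 | rad | deterministic strong/weak mixing of the guess (see below) |
| `threshold` | 0.1 | — | M-diagnostic regime boundary |
| — | 627.509 | kcal/mol per hartree | conversion, applied only in the reporting layer |

`gtol` and the 30-iteration inner budget follow the protocol for this family
of calculations; `etol`, the maximum of $10^3$ outer iterations and the
remaining defaults are this package's choices, made once and used for every
fixture.

## Algorithms and numerical choices

**Occupation optimization.** Each paired subspace's occupations are
parametrized as a softmax of unconstrained variables, so the bounds
$0 \le n_p \le 1$ and the sum rules hold exactly at every evaluation; BFGS
runs in the free variables with analytic gradients (chain rule through
$\Pi$, $\Phi$ and the $n^d$ gate), which a central-difference oracle checks
to $10^{-6}$. The softmax has a gauge direction per subspace; the gradient is
automatically orthogonal to it.

**Orbital optimization.** Orbitals are updated by an exponential rotation
$C \to C e^{X}$ with $X$ antisymmetric. The gradient is the anti-symmetrized
generalized-Fock (Lagrangian) matrix $2(\Lambda - \Lambda^{\mathsf T})$,
$\Lambda_{qp} = \langle q | \hat F_p | p \rangle$ — the same stationarity
condition the iterative-diagonalization schemes for these functionals solve.
The inner loop is BFGS over the rotation parameters with the expansion point
restarted at every outer iteration (the rotated-gradient approximation then
becomes exact at convergence); $S$-orthonormality is restored by symmetric
(Löwdin) orthogonalization after every step, to $10^{-10}$. The matrix
exponential uses scaling-and-squaring with a truncated Taylor series,
adequate for the small-norm rotations the line search produces.

**Saddle points and multi-starts.** At homolytic dissociation the degenerate
mean-field orbitals localize, and the localized configuration is a
stationary saddle with an exactly zero rotation gradient. The guess
therefore applies a small deterministic strong/weak mixing rotation
(`mix_angle`), which breaks such saddles without affecting well-conditioned
cases (the optimizer simply undoes it). Distinct stationary points remain a
real feature of these functionals; `nof_multistart()` runs a mean-field
start plus warm-start chains and reports all distinct solutions ranked by
energy, and `nof_chain()` implements the PNOF7s → GNOF warm-start protocol.
After convergence the strong slot of each subspace is relabeled to hold its
largest occupation (a pure relabeling for $N_g = 1$), so diagnostics read
the intended orbitals.

**Integrals.** No quantum-chemistry backend exists in R, so the package
carries a compact McMurchie–Davidson engine (Rcpp): Hermite expansion
coefficients, Boys function by downward recursion from a converged series
(upward recursion past $x = 35$), s/p/d shells, spherical harmonics
throughout. It is validated against an independent closed-form s-Gaussian
oracle, rigid-rotation invariance with p shells, and structural invariants
(symmetry, positive-definite overlap, 8-fold ERI symmetry). The
four-index transform used for $J_{pq} = \langle pq|pq \rangle$ and
$K_{pq} = \langle pq|qp \rangle$ is checked against an explicit-loop oracle
to $10^{-10}$. The RI path factorizes the computed ERI matrix by pivoted
Cholesky decomposition — an established density-fitting variant that needs
no auxiliary basis files — with the truncation tolerance controlling the
$\le 10^{-4}$ reproduction error the tests assert. Bundled basis sets:
STO-3G (H, Li, C, N, O), 6-31G and 6-31G(d) (H, C, O), cc-pVDZ exponents
for H; for heavier elements (including Fe) only published cc-pVDZ shell
compositions are stored, which is exactly what basis-function counting
needs.

**FCI oracle.** A determinant full-CI (bit-mask Slater–Condon rules, dense
diagonalization, spin-summed 1RDM) provides exact energies and natural
occupations for systems up to a few hundred determinants. It shares only
the integral engine with the NOF path and is used purely as a reference.

## What the fixtures emulate — and what they do not

The fixtures (H, H₂ at arbitrary bond length, collinear H₄ chains, LiH,
H₂O) are chosen so that every claimed property is *decidable* at desk
scale: two-electron exactness and size consistency (H₂), interpair static
correlation and the functional ordering PNOF5 ≥ PNOF7s ≥ PNOF7 ≥ GNOF
(stretched H₄), dynamic interpair correlation and the Pulay-scale
occupations (H₂O), a heteronuclear closed shell (LiH), and the multiplet
treatment (H atom, triplet H₂ — exact for two high-spin electrons).
Problem sizes were set for sub-second to few-second runs: minimal and
double-ζ bases, 2–18 basis functions, determinant spaces below ~500.

Passing these tests shows the energy expressions, constraints and
optimizers are implemented correctly. It does not show that the functionals
are accurate for transition-metal spin gaps: the iron(II) porphyrin
application (465 basis functions, 186 correlated electrons, ~10⁵
occupation variables under extended pairing) is orders of magnitude beyond
these fixtures, and its published energies are treated as reference values
only. The workflow for such a study — geometry loading with Fe–N and
electron-count sanity checks, per-multiplicity warm-start chains, adiabatic
gap tables with the printed sign convention (positive means the triplet
lies lower), M tables — is implemented and tested on the small systems. The
FeP-like structure used in tests is synthetic (correct composition and
Fe–N distance, schematic ring) and is labelled as such; real studies load
their own optimized structures.

## Known limitations

* Angular momenta up to d; no f/g integrals (counting only), no effective
  core potentials, no relativistic corrections.
* Real orbitals only ($L = K$); the complex-orbital path is not implemented.
* No perturbative (NOF-MP2-style) corrections and no PNOF6.
* No analytic nuclear gradients; geometries are inputs.
* The dynamic term omits single-electron orbitals by construction, so
  multiplet states miss part of their dynamic correlation — a known
  limitation of this functional family, visible in underestimated gaps for
  systems like molecular oxygen.
* Alternating occupation/orbital descent finds stationary points; global
  optimality is not guaranteed (hence the multi-start tooling).

## A small demonstration

```{r example, eval = FALSE}
fx <- make_fixture("H2", R = 3.0)
fit <- nof(fx$system, fx$basis, functional = "PNOF5")
fci_oracle(fx)$e_total - fit$energy$e_total   # ~1e-7 hartree or below
m_diagnostic(fit)                              # static-dominated at 3 A
```
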