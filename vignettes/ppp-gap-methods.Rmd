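---
title: "Methods: PPP singlet-triplet gaps and the dynamic-spin-polarization correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPP singlet-triplet gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pppgap)
```

## Why a pi-only model

Molecules with an inverted singlet-triplet gap (S1 below T1) are rare
and expensive to find: the inversion is a correlation effect that
single-excitation methods such as TD-DFT miss entirely, while the
double-excitation methods that capture it (ADC(2), CC2, CASPT2) cost
minutes to hours per molecule. The Pariser-Parr-Pople (PPP) model keeps
only the pi electrons in a minimal basis, parameterizes all integrals
from atom-in-molecule experimental data, and retains exactly the piece
of physics that matters here: the exchange interaction between frontier
orbitals and its competition with dynamic spin polarization. A full gap
ladder for a 13-atom heteroaromatic takes a few milliseconds.

## The Hamiltonian and its parameters

Each conjugated sp2/sp heavy atom carries one 2p orbital and donates
`n_r` electrons (sp2 C: 1; pyridine-type N: 1; pyrrole-type N: 2;
carbonyl O: 1; ether O: 2). Sigma neighbors (including hydrogens) decide
the type; saturated centers are excluded and unparameterized centers
(e.g. four-coordinate phosphorus) raise an error that batch drivers
record per molecule. Under zero differential overlap the Roothaan
equations reduce to the standard eigenvalue problem with the Fock matrix
given in the README.

All parameters derive from the valence-state ionization potential and
electron affinity of each center type (shipped as a versioned CSV in
`inst/extdata/valence_states.csv`, Hinze-Jaffe style values; only the
carbon entry, IP 11.16 / EA 0.03 eV, is locked by the benchmark systems
in the test suite):

* one-center repulsion `gamma_rr = IP - EA` (Pariser-Parr);
* two-center repulsion of Ohno form,
  `gamma_rs = 14.397 / sqrt(r^2 + a^2)` eV with
  `a = 28.794 / (gamma_rr + gamma_ss)` Angstrom. This interpolates
  smoothly between the arithmetic-mean one-center limit at r = 0 and the
  bare Coulomb law at large separation, and is strictly decreasing;
* resonance integral `beta_rs = -C S_rs (IP_r + IP_s)/2 cos(theta_rs)`
  with the single empirical constant C = 0.545. `S_rs` is the exact
  Slater 2p-2p pi overlap evaluated by the classical auxiliary-integral
  recursions; the Slater exponent of each type is
  `zeta = 2 sqrt((IP + EA)/E_h)` per Angstrom, so the whole
  parameterization needs nothing beyond IP, EA and C;
* `U_r = -IP - (n_r - 1) gamma_rr` and effective core charges
  `Z_s = n_s`.

The twist angle `theta_rs` of each bond is the average over all
dihedrals a-r-s-b formed with flanking pi neighbors, each folded to
[0, 90] degrees (only |cos theta| is physical); bonds without flanking
neighbors use theta = 0. Planar systems therefore get the untwisted
beta exactly.

Choices worth making explicit: the Slater exponents enter only through
the overlap in beta. Deriving them from the mean of IP and EA keeps the
promise that the model has no inputs besides the valence-state data,
and reproduces the published pentalene benchmark ladder within the
tolerances asserted in `test-acceptance.R`; an exponent convention
based on Slater's screening rules does not. The twist attenuation
multiplies the full beta rather than entering the overlap integral
itself.

## SCF details

Plain damped fixed-point iteration from the Hueckel guess (eigenvectors
of the core matrix): RMS density change below `tol = 1e-8` within
`max_iter = 200`, with a 0.5 linear damping engaged once the residual
stops decreasing. DIIS or level shifting would be overkill at these
sizes. Non-convergence sets a flag and is propagated as a warning, never
an exception, because a screening run must survive individual failures.

Degenerate orbital blocks (common in high-symmetry systems such as the
D3h azaphenalene skeleton) make individual coefficient vectors
arbitrary. The gauge is fixed by diagonalizing a fixed coordinate-moment
operator inside each degenerate block and sign-fixing each orbital by
its largest coefficient. All physical observables summed over a
degenerate block (DSP sums, CIS roots) are invariant under block
rotations anyway - the gauge only makes printed coefficients and
per-orbital labels reproducible across linear-algebra backends.

## The gap ladder

With x = HOMO and y = LUMO:

1. `gap_scf = 2K`, `K = (xy|yx)` in ZDO. K is a positive-semidefinite
   quadratic form, so this level can never predict inversion - it is the
   spatial HOMO-LUMO overlap `sum_r |c_rx||c_ry|` that controls how
   close to zero it gets.
2. `gap_scf_dsp = 2K + dE_DSP`. The DSP correction sums second-order
   contributions of determinants doubly excited with respect to the
   ground state: a spectator excitation i -> a (i strictly below the
   HOMO, a strictly above the LUMO) on top of x -> y. The numerators are
   exchange-operator matrix elements `K_x,ia = (ix|xa)`,
   `K_y,ia = (iy|ya)`:
   `dE_ia = -[3/2 (K_x,ia - K_y,ia)^2 - 1/2 (K_x,ia + K_y,ia)^2]/(eps_a - eps_i)`.
   The antisymmetric channel (singlet-stabilizing) carries the larger
   spin-algebra weight, which is why the correction is negative in
   practice; a pair with K_x ~ K_y of equal sign can contribute a small
   positive term (observed at the sub-meV scale on the idealized
   cyclazine fixture). Denominators below 1e-6 eV are dropped and
   counted, never silently divided by.
3. `gap_cis = E(S1) - E(T1)` from spin-adapted CIS over the full singles
   space. A brute-force determinant-basis CI with Slater-Condon rules
   and S^2 classification (`bruteForceCis()`) validates the production
   build to 1e-8 eV on every fixture with at most 10 orbitals.
4. `gap_cis_dsp = gap_cis + dE_DSP(CIS)`: the same exchange numerators
   with the doubly excited intermediates referenced to the ground
   determinant, `D = eps_a - eps_i + eps_LUMO - eps_HOMO`. Measuring the
   intermediates from the ground determinant rather than from the
   excited configuration is what distinguishes the CIS-referenced
   correction; it damps the correction relative to the SCF level, in
   line with the benchmark ladder.
5. Optionally the published linear fit `0.53 x - 0.15` (configurable via
   `pppConfig(lc = ...)`), which trades a little specificity for a
   large gain in recall when screening widely.

Oscillator strengths use `f = (2/3) dE |mu|^2` in atomic units with the
ZDO point-charge transition dipole
`mu = sqrt(2) sum_ia t_ia sum_r c_ri c_ra R_r`; an operator-algebra
oracle over determinants reproduces the production values to 1e-8. The
transition charges sum to zero, so f is origin independent.

Negative T1 (occasionally S1) CIS roots signal a restricted-unrestricted
instability of the closed-shell reference. The package takes the
pragmatic view of propagating them with `negative_T1`/`negative_S1`
warnings instead of attempting a stability analysis: the gap between
the lowest open-shell states remains indicative, and screening metrics
can always be recomputed excluding flagged molecules.

## What the fixtures do and do not show

The fixture generators are pure functions: `pentaleneD2h()` (two fused
regular pentagons, side 1.4 Angstrom - the maximally symmetric
realization of "equal bond lengths"), `ringPolygon()` (square
cyclobutadiene, benzene), `polyeneChain()`, `twistedDiene()` for the
twist-angle contract, a pyrrole pentagon for heteroatom perception, and
`cyclazineIdealized()`, a *synthetic* idealized azaphenalene stand-in
(honeycomb patch, all bonds 1.40 Angstrom). On the idealized cyclazine
the pipeline reproduces the characteristic structure of the real
molecule: doubly degenerate HOMO-1 and LUMO+1 pairs, a HOMO-LUMO
overlap near 0.14, an exchange gap of ~0.03 eV, exactly 30 DSP
excitation pairs with the two degenerate-partner pairs dominating, and
a strongly inverted gap at every correlated level. Published benchmark
values for azaphenalenes refer to DFT-optimized geometries, so the
idealized fixture is used for structural assertions, not for
numerical-agreement tests.

These fixtures exercise planar, high-symmetry, mostly alternant
systems at idealized geometries. They do not probe bond-length
alternation from real optimizations, strong twisting, exocyclic
substituents, or the sigma-framework effects the model omits by
construction - passing tests say the implementation is faithful to the
model, not that the model is accurate for arbitrary chemistry.

## Numerical choices

* Units: eV and Angstrom everywhere; the only conversions (Hartree,
  bohr, the Coulomb constant 14.397 eV Angstrom) live in
  `pppConstants`.
* Connectivity: bonded iff distance < 1.15 x sum of covalent radii;
  explicit SDF bond blocks always win. The scale keeps normal rings
  intact while still separating transannular contacts (the 1.98
  Angstrom diagonal of a 1.4 Angstrom square is correctly non-bonded).
* Overlap fast path: a natural cubic spline per exponent pair on a
  0.5-6 Angstrom grid (0.02 spacing), falling back to the exact
  recursion outside the grid. Across the fixture set the spline path
  shifts CIS+DSP gaps by well under 0.004 eV RMSE; the exact recursion
  remains the default because bit-reproducibility beats a microsecond.
* The auxiliary integral B_k(q) switches to a series expansion for
  |q| < 1e-6 to avoid catastrophic cancellation at equal exponents.
* Classification metrics display at two decimals with R's default
  round-half-even, which reproduces the published benchmark tables
  cell-for-cell from their confusion matrices; raw values are kept
  machine-readable.
* Test problem sizes: oracle equivalence runs on systems of 2-8
  orbitals where explicit determinant CI is exact and fast; the whole
  suite completes in a few seconds.

## Configuration

`pppConfig()` collects every tunable: SCF tolerance/iterations/damping,
overlap path (exact or spline), linear-correction coefficients,
classification level and threshold, connectivity cutoff scale, and an
alternative valence-table path. Configurations round-trip through YAML
(`readConfig()`/`writeConfig()`), and the CLI accepts `--config`.

## Known limitations

Pi-only (no sulfonyl-type groups without clear sigma-pi separation, no
inductive effects, no n -> pi* states); no solvation; geometries are
inputs, not outputs; closed-shell restricted references only; oscillator
strengths at this level are known to correlate poorly with higher-level
references even when gaps correlate well, so rank them with care.
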