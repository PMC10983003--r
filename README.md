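# pppgap

Ultrafast semiempirical singlet–triplet gaps for conjugated organic
molecules, aimed at virtual screening for **INVEST** candidates —
molecules whose first excited singlet lies *below* the first triplet
(ΔE_ST = E(S1) − E(T1) < 0), violating Hund's rule in the excited state.
Such emitters are of intense interest for next-generation OLEDs, but the
excited-state methods that capture gap inversion (ADC(2), CC2, CASPT2)
are far too expensive to scan large libraries. `pppgap` implements a
π-electron Pariser–Parr–Pople (PPP) treatment that runs in milliseconds
per molecule and still captures the inversion physics.

## The model

Only the π electrons are treated, one 2p orbital per conjugated center,
under zero differential overlap (ZDO). The Fock matrix is

```
F_rr = U_r − Σ_{s≠r} Z_s γ_rs + ½ P_rr γ_rr + Σ_{s≠r} P_ss γ_rs
F_rs = β_rs − ½ P_rs γ_rs
```

with every parameter derived from valence-state ionization potentials
(IP_v) and electron affinities (EA_v):

* `γ_rr = IP_v − EA_v` (Pariser–Parr),
* `γ_rs = 14.397 / sqrt(r² + a²)` eV with `a = 28.794/(γ_rr + γ_ss)`
  (Ohno-type interpolation between the one-center limit and Coulomb's law),
* `β_rs = −0.545 · S_rs · (IP_r + IP_s)/2 · cos θ_rs`, where `S_rs` is the
  exact Slater 2p–2p π overlap (Slater exponents from the mean of IP_v
  and EA_v) and `θ_rs` the twist angle between the two p orbitals,
* `U_r = −IP_v − (n_r − 1) γ_rr`.

The Roothaan equations `F C = C E` are solved self-consistently from a
Hückel guess. On top of the SCF reference the package evaluates the
singlet–triplet gap ladder:

1. **SCF**: `ΔE_ST = 2K`, twice the HOMO–LUMO exchange integral — always
   ≥ 0, so inversion cannot appear at this level;
2. **SCF + DSP**: a perturbative *dynamic spin polarization* correction
   `ΔE^DSP = −Σ_{i,a} [ (3/2)(K_x,ia − K_y,ia)² − ½(K_x,ia + K_y,ia)² ] / (ε_a − ε_i)`
   summed over spectator excitations from orbitals below the HOMO (x)
   into orbitals above the LUMO (y) — the admixture of doubly excited
   configurations that preferentially stabilizes the open-shell singlet;
3. **CIS**: spin-adapted configuration interaction singles over the full
   occ × virt space;
4. **CIS + DSP**, and optionally the published linear correction
   `ΔE_ST,LC = 0.53·ΔE_ST,CIS+DSP − 0.15`.

Oscillator strengths use the dipole-length form with ZDO point-charge
transition dipoles.

## Worked example: pentalene

Idealized D2h pentalene (two fused regular pentagons, all bonds 1.4 Å)
is the classic inverted-gap demonstration:

```r
library(pppgap)
gaps <- computeGaps(pentaleneD2h())
print(gaps)
#> <ppp_gaps>  (eV; negative = inverted singlet-triplet gap)
#>   HOMO-LUMO overlap     0.236
#>   2K        (SCF)       0.128
#>   DSP(SCF)             -0.405   -> gap SCF+DSP    -0.277
#>   S1 1.785 / T1 1.683  -> gap CIS         0.101
#>   DSP(CIS)             -0.296   -> gap CIS+DSP    -0.195
#>   linear-corrected                 -> gap CIS+DSP+LC -0.253
#>   f(S1) 0.0000
```

The small HOMO–LUMO spatial overlap (0.236) makes the exchange
interaction tiny (2K = 0.128 eV), and the DSP correction (−0.405 eV)
flips the gap negative: the vertical S1 lies below T1 at both the
SCF+DSP and CIS+DSP levels. The zero oscillator strength is the flip
side of the vanishing overlap — this state is dipole-forbidden. The
per-excitation decomposition shows which orbital pairs drive the
inversion:

```r
head(dspDecomposition(gaps$dsp$scf), 3)
#>    label i a       value
#> 1 2 -> 6 2 6 -0.23326313
#> 2 3 -> 8 3 8 -0.09867218
#> 3 1 -> 7 1 7 -0.07353041
```

## Batch screening

```r
res <- screen("manifest.csv", config = pppConfig(), out = "results.csv")
metricsReport(res, ref_col = "ref_gap_eV")
```

The manifest is a CSV with columns `id`, `structure_path` (XYZ or SDF)
and optionally `ref_gap_eV`. Each row yields one record — failures are
captured per row (`status = "failed:<reason>"`), never abort the batch —
and `metricsReport()` computes R², Spearman ρ, RMSE and the
inverted/normal confusion matrix with recall, specificity, accuracy, F1
and (for hard predictions) balanced-accuracy ROC-AUC. A thin CLI wraps
the same functions:

```sh
Rscript inst/scripts/ppp-gap.R compute molecule.xyz --decompose
Rscript inst/scripts/ppp-gap.R screen manifest.csv --out results.csv
Rscript inst/scripts/ppp-gap.R metrics results.csv --ref-col ref_gap_eV
```

## Limitations

π-only: no σ framework, no n→π* states, no solvation; geometries are
taken as given (no optimization); closed-shell references only, with
negative CIS excitation energies flagged rather than fixed. See the
vignette in `vignettes/` for the full methods discussion.
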