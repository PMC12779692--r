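---
title: "Methods: the in silico toxicological assessment chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the in silico toxicological assessment chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicotox)
```

silicotox implements the desk-computable core of a ligand- and
structure-based toxicological assessment of small-molecule cholinesterase
modulators, exemplified by six (thio)semicarbazone insecticide candidates
(TSCZ1–6: furan-bearing thiosemicarbazones and thiophene-bearing
semicarbazones, para-substituted with F, Cl or Br). The expensive engines —
DFT electronic-structure codes, docking, MD — are treated as data sources:
their outputs (orbital energies, charge populations, trajectories, energy
decompositions) are inputs here, and a seeded synthetic generator stands in
for them with known ground truth.

## Global and local reactivity descriptors

From frontier orbital energies $E_{HOMO} < E_{LUMO}$ (eV) the package
computes, under the Koopmans finite-difference approximations:

$$\Delta E = E_{LUMO} - E_{HOMO},\quad I = -E_{HOMO},\quad EA = -E_{LUMO},$$
$$\chi = \tfrac{I+EA}{2},\quad \eta = \tfrac{I-EA}{2},\quad S = 1/\eta,\quad
\omega = \chi^2/2\eta,\quad \epsilon = 1/\omega.$$

The identities $S\eta = 1$, $\omega\epsilon = 1$ and $\Delta E = 2\eta$ hold
to machine precision and are enforced by property tests. All quantities are
carried in eV without conversion; softness and nucleophilicity are
reciprocals (numerically 1/eV), though the source tables label softness in
"eV" — we report the numeric value and note both conventions. A zero
electronegativity makes the nucleophilicity undefined; it is returned as
`NA` with a classed warning rather than a silent infinity.

Reference-set detail: the reported group softness values (0.550 for the
thiosemicarbazones, 0.538 for the semicarbazones) are truncations of the
full-precision reciprocals — from the printed orbital energies TSCZ5/6
compute to 0.53850, which rounds half-up to 0.539. Comparisons against
printed values are therefore made to printed precision, $|x - x_{print}| <
10^{-3}$, never by re-rounding.

Local reactivity uses condensed Fukui functions from three-state charge
populations (Hirshfeld-style): $f^+_A = q^A_N - q^A_{N+1}$, $f^-_A =
q^A_{N-1} - q^A_N$, the dual descriptor $\Delta f = f^+ - f^-$, and the
multiphilic descriptor $\Delta\omega = \omega\,\Delta f$. Site
classification follows the joint sign rule (both positive → electrophilic,
both negative → nucleophilic) with a symmetric dead zone of `tol = 1e-6`:
the rule as stated uses strict inequalities, so a small dead zone absorbs
sign-flip noise near zero without changing any decided site. Because
$\Delta\omega$ has the sign of $\Delta f$ whenever $\omega > 0$, the joint
rule degenerates to the dual-descriptor sign for any physical molecule; the
classifier still checks both so that externally supplied profiles are
handled faithfully. Charge-difference sums that deviate from the ideal one
electron by more than 0.05 warn rather than fail, since real population
analyses deviate slightly.

## Aquatic ecotoxicity

Baseline (narcosis) toxicity of neutral organics is modelled log-linearly
in the octanol–water partition coefficient:
$\log LC_{50}\,[\text{mmol/L}] = m \log K_{ow} + b$, converted to mg/L with
the molecular weight (the band table is in mg/L while the regression is in
mmol/L — the conversion is explicit in `predict_lc50()`). The slope and
intercept are not part of this package's claims: they ship as an editable
YAML configuration with documented generic placeholder values, and no test
depends on them.

Classification bands (mg/L):

| class | acute LC50/EC50 | chronic ChV |
|---|---|---|
| not harmful | > 100 | > 100 |
| harmful | (10, 100] | (1, 10] |
| toxic | (1, 10] | (0.1, 1] |
| very toxic | (0, 1] | (0, 0.1] |

Two conventions close gaps the printed table leaves open, both signalled in
code: boundary values (exactly 1, 10, 100) are assigned to the more-toxic
adjacent class (half-open intervals closed on the toxic side), a
conservative tie-break; and chronic values in (10, 100], a band the chronic
table does not define, are assigned not-harmful with a classed warning.

Companion quantities: narcotic activity $\approx LC_{50}/C_s$ with a
supersaturation flag when the ratio exceeds 1 (effect concentration above
solubility, prediction unreliable); the community hazard concentration
$HC_5 = 10^{-(-4.52 + 1.05\log K_{ow})}$ µmol/L; the chronic value as the
geometric mean $\sqrt{NOEC \cdot LOEC}$, returned in mg/L (the printed
formula is the log of that mean, but chronic values are tabulated in mg/L,
so the concentration-scale mean is what the reported numbers are); and the
Arnot–Gobas bioconcentration factor
$$BCF = (1 - L_B) + \frac{k_1\,\phi}{k_2 + k_E + k_G + k_M}$$
with the ≥ 5000 L/kg bioaccumulation flag. A bioaccumulation factor (BAF)
is deliberately not computed: the source's BAF equation is a misprinted
duplicate of the ChV equation, so BAF values pass through as inputs rather
than being guessed. Lipophilicity flags use strict thresholds: lipophilic
at $\log K_{ow} > 3$, outside the fish/daphnia applicability domain at
$\log K_{ow} > 5.0$.

## CNS MPO score

The six-attribute desirability score sums weighted piecewise-linear
transforms $T_k \in [0,1]$ of log Kow (standing in for logP), logD, TPSA,
pKa, molecular weight and H-bond donor count; with unit weights the total
spans 0–6. Ideal bounds follow the published algorithm (logP ≤ 3, logD ≤ 2,
40 < TPSA ≤ 90 Å², pKa ≤ 8, MW ≤ 500 g/mol, HBD ≤ 1); the source prints
only those bounds (its score equation is another misprint), so the ramp
cutoffs are the conventional desirability-function defaults (logP 5, logD
4, TPSA outer bounds 20/120, pKa 10, MW 800, HBD 3.5), all configurable via
YAML, and piecewise-linear is the simplest shape consistent with an
inside/outside threshold description. TPSA is hump-shaped; all others are
monotone. The score is non-increasing as any attribute moves away from its
ideal region — a tested property.

The per-compound attribute values behind the reported 4.05–4.71 score band
are not published; `tscz_mpo_fixture_synthetic()` is a synthetic stand-in
chosen once from typical halogenated (thio)semicarbazone physicochemistry
(log Kow inside the reported 4.2–5.385 range, TPSA ≈ 70–75 Å², MW ≈
290–370 g/mol, logD ≈ 2.5–2.8, pKa ≈ 7.4–7.8, two H-bond donors). Only the
set-level band is checked; no per-compound score is claimed.

## Conformer similarity

Molecules are compared as ordered stacks of conformer descriptor vectors
via the Manhattan distance $d = \sum_s |x_s - y_s|$. The source text is
internally inconsistent about the conformer count (a sum to 18 versus "20
most stable conformations"), so the count is a parameter (default 18) and
the molecule-level distance aggregates rank-aligned conformer pairs by
their minimum — the best-conformer-match reading. The descriptor
components' identities are opaque inputs; no 3D conformers are generated.

## Trajectory metrics

RMSD between a reference and a compared frame is
$\sqrt{\frac1N \sum_i (r_{i2} - r_{i1})^2}$. The plain formula contains no
superposition step, so `align = FALSE` is the default that matches it;
`align = TRUE` applies a proper Kabsch least-squares rotation+translation
first, as MD practice requires, and both paths are tested (aligned RMSD is
rigid-motion invariant to 1e−9 Å and never exceeds unaligned). Frame 0 is
the default reference; atom subsets are the caller's choice (pass a
filtered trajectory), since the source does not state whether its curves
are backbone-only. RMSF is the per-atom fluctuation about the
trajectory-mean position with uniform frame weighting (population 1/N).

Hydrogen-bond occupancy is the percentage of frames with a donor–acceptor
distance ≤ 3.5 Å; report entries under 2 % occupancy are dropped as not
relevant to complex stabilisation. MM/GBSA binding totals sum
$E_{vdW} + E_{ele} + G_{GB} + G_{SA} - T\Delta S$ per frame and report
mean ± SD with per-term means; the entropy column stores $-T\Delta S$
directly (positive as tabulated; normal-mode entropy estimation is out of
scope), so the total is the plain five-term sum, and single-value
table-style input returns the exact sum with an `NA` SD.

## Synthetic data: what it emulates, and what it does not

Generators replace the external engines under a single integer seed:

- `gen_orbital_table()` — uniform HOMO energies (−7 to −5 eV) with strictly
  positive gaps (1.5–4.5 eV), prepending the six reference rows verbatim.
- `gen_charge_populations()` — N-state charges uniform in ±0.5 with
  one-electron differences built from Dirichlet increments, so Fukui sums
  are exactly 1 in memory (machine precision) and the planted dual signs
  are recorded ground truth.
- `gen_trajectory()` — per-atom harmonic displacement along a fixed random
  direction, $r_i(t) = r_i^0 + A_i u_i \sin(\omega_i t + \phi_i)$ with
  $\omega_i \in [0.5, 2.5]$ rad/frame: the RMSF of a densely sampled
  sinusoid converges to $A_i/\sqrt2$, the closed-form recovery target
  (recovered within 2 % at $10^4$ frames). An optional rigid drift
  (translation + slow rotation) exercises alignment.
- `gen_energy_series()` — independent Gaussian component streams with
  configured means/SDs; sample means recover the configuration within
  three standard errors at $10^4$ frames.

Text outputs are rounded to 6 significant figures for bit-identical
cross-platform reruns, and every generated file carries a
`.truth.json` sidecar of its ground-truth parameters. Consequence of the
rounding: Fukui sums recomputed from a written CSV deviate at the 1e−5
level (well inside the 0.05 sanity band) while the in-memory construction
is exact; the machine-precision conservation claim applies to constructed
populations.

These generators emulate structure, not physics: no force-field dynamics,
no real Hirshfeld charges, no coupling between components. Passing tests
demonstrate that the metrics recover known ground truth and reproduce the
tabulated worked examples — not that the upstream engines' outputs are
predicted.

## Orchestration and reproducibility

`run_assessment()` runs every stage whose inputs exist, marks the rest
`skipped` with the missing input named, records every applied threshold
(class bounds, 3.5 Å, 2 %, log Kow 3/5, BCF 5000) plus the seed and a
config hash in the report, and writes JSON/CSV/Markdown outputs with no
timestamps, so identical configuration and seed rerun byte-identically
(hash-compared in tests). Malformed configs fail with the offending key.

Problem sizes used throughout the test-suite and acceptance runs — six
reference compounds, 10–15-atom population sets, $10^4$-frame synthetic
trajectories and energy streams, 200–500-frame pipeline inputs — were
chosen so the statistical recovery bounds above are comfortably resolved;
full runs complete in seconds on one CPU.

## Known limitations

- QSAR coefficients are placeholders; absolute predicted concentrations
  are meaningless until a calibrated coefficient set is supplied.
- BAF, biomagnification (β) and trophic dilution (τ) are named in the
  source but have no printed equations; they are pass-through fields.
- The CNS MPO fixture attributes are synthetic; only the score band is
  comparable to the report.
- Trajectory tooling assumes identical atom ordering across frames and
  does no topology/PDB handling.
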