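---
title: "Models and methods behind screenval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind screenval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenval)
```

screenval covers the quantitative steps of an ensemble virtual-screening
campaign after the docking engines and instruments have produced their raw
output: template selection by enrichment, pose judging, NMR confirmation
and affinity quantification, thermal-shift confirmation, and
chemical-novelty profiling. This vignette records the models, the
parameter choices, and the numerical decisions, in that order; nothing
here states a result that the test suite or the analysis scripts do not
themselves compute.

## Enrichment metrics

A screen's score list is ranked ascending (docking convention: lower =
better). The ROC is the staircase visiting, after each distinct score
value, the cumulative false-positive and true-positive fractions; a block
of tied scores is traversed as a single diagonal segment, which makes the
curve independent of input order and puts the trapezoidal area in exact
agreement with pair counting (ties counted one half) — the suite asserts
this equivalence against a brute-force oracle on random instances.

The early-enrichment metric integrates TPR against log10(FPR) over
[λ, 1], λ = 0.001. Three choices matter:

- **Staircase, not trapezoid, on the log axis.** The ROC of a finite
  ranked list is a step function; previous-vertex integration reflects
  that. The diagonal reference value is computed analytically where
  needed.
- **Clamping, not truncation, below λ.** Vertices with FPR < λ are moved
  to λ. A perfect classifier (TPR = 1 before the first false positive)
  then attains exactly (log10(1/λ) − 0) / log10(1/λ) = 1 of the available
  area, so after subtracting the chance constant the bounds
  −0.145 … 0.855 are attained exactly, not asymptotically.
- **The chance constant 0.145** is the diagonal's normalised log-area
  ∫λ→1 x d(log10 x) / 3 = (1 − λ)/(3 ln 10) ≈ 0.1446, reported to three
  decimals. It is re-derived two ways in the tests: by quadrature and as
  the mean over label shuffles of a 33-active / 2370-decoy library.

AUC and LogAUC are surfaced as percentages. The enrichment factor is the
FPR-based ratio EF = TPR(FPR = level)/level. The alternative
database-fraction definition (top x% of all compounds) differs when
actives are a non-negligible share of the library; the FPR-based form is
the one whose worked interpretation ("ten times more actives than chance
at 1% of the false positives") is self-consistent, and it is the only
variant implemented.

`rank_ensemble()` encodes the two-stage template choice: pose fidelity
first (a structure below the ensemble-median success rate is demoted
wholesale — scores from a geometry the engine cannot reproduce are not
trusted), LogAUC second, EF1/AUC/id as tie-breaks.

## Pose evaluation

Docking reproduces a pose in the fixed receptor frame, so RMSD is
computed in place, without Kabsch superposition — superposing would hide
exactly the placement error being measured. "Heavy atoms" means all
non-hydrogen ligand atoms with positional correspondence; symmetry-aware
matching (ring flips, equivalent atoms) is deliberately not applied, as
no automorphism convention was assumed. Success is RMSD ≤ 2 Å inclusive.
Hydrogen-bond occupancy is the fraction of trajectory frames with
donor–acceptor heteroatom distance ≤ 3.5 Å; a distance-only criterion,
since an angle term requires hydrogen positions that heavy-atom distance
series do not carry.

## Chemical-shift perturbations

ΔCS = √(0.5·(ΔH² + (0.2·ΔN)²)) ppm combines the amide ¹H and ¹⁵N shift
changes, the 0.2 factor rescaling the ~5× wider ¹⁵N dispersion. Residues
are classified against thresholds computed from the mean and SD of ΔCS
over residues with ΔCS > 0 only (zero-perturbation residues would
otherwise dilute the scale): (i) ≤ mean + SD, (ii) ≤ mean + 2 SD,
(iii) above, (iv) peak disappeared, boundaries falling in the lower
class. Two open choices were resolved as follows: the SD is the sample SD
(n − 1), the conservative default, with the population variant available
via `sd_type`; and residues are matched by assignment id, peak tracking
being upstream. A mixture spectrum is called a hit when any residue is
class iii or iv — "significant change" needs an operational form, and
strong-or-disappeared is the weakest signal that would trigger a
follow-up titration in practice. Note a caveat the analysis scripts make
visible: because the thresholds are relative, a spectrum whose only
changes are sub-resolution jitter can still produce class-iii outliers if
that jitter is heavy-tailed; digitisation to the spectral resolution (so
most ΔCS are exactly zero) is the realistic regime in which the call
behaves.

## Two-site exchange and Kd fitting

Binding is 1:1; the bound fraction is the physical root of
Pt·pb² − (Pt + Lt + Kd)·pb + Lt = 0. Each residue's 1D trace is the
steady-state two-site McConnell absorption spectrum with first-order
rates k_ab = koff·pb/(1 − pb) (detailed balance) and k_ba = koff, solved
per frequency as a 2×2 complex system in closed form. Its integral is
population-independent (checked numerically), areas follow (1 − pb, pb)
in the slow limit, and the fast limit collapses to the weighted-average
frequency — both checked, plus a cross-check of the whole line shape
against an independent time-domain FID + Fourier-transform oracle.
Full 2D (¹H×¹⁵N) line-shape fitting is reduced to per-residue 1D traces;
with synthetic 1D inputs nothing is lost, and the exchange physics is
identical.

`fit_kd()` is a global fit: one (Kd, koff) shared by all residues and
titration points. Apo peak position/width come from a 1D Lorentzian
pre-fit of the ratio-0 trace; per-residue holo frequency, holo width and
amplitude are free; optimisation is Levenberg–Marquardt on the stacked
trace residuals in (log10 Kd, log10 koff) with multistart over a
log-spaced grid (Kd 10⁻³…10³ µM × koff 10¹…10³ s⁻¹; the best three grid
points by initial SSE are refined). Log-parameterisation keeps both rate
constants positive and makes the grid scale-free. A titration whose
spectra do not change between first and last point is flagged
unidentifiable rather than fitted. The fast-exchange fallback fits
δ_obs = δ_apo + pb(Kd)·(δ_holo − δ_apo) with δ_holo solved in closed form
at each candidate Kd; an estimate at the search bound or below ~Pt/100 —
the well-known identifiability floor of shift titrations — sets the
`at_boundary` flag instead of being reported as a quantitative affinity.

Default study conditions in the generator: Pt = 100 µM, ligand:protein
ratios 0…2, koff = 50 s⁻¹, two residues with 120–150 Hz apo–holo
separations and R2 of 25–30 s⁻¹ (slow-to-intermediate exchange, the
regime where line-shape fitting is informative), 512-point frequency
grids spanning ±5× the separation. Noiseless self-generated titrations
are recovered to well under 1%; at 1% of the apo peak height of additive
Gaussian noise, the mean recovery error at Kd = 0.35 µM over 20 seeds is
~1.6%, with single seeds occasionally beyond 5% — at Kd/Pt = 0.0035 the
bound-fraction curve is nearly stoichiometric and the estimator is
noise-limited, which is worth remembering when interpreting any
tight-binding titration at 100 µM protein.

## DSF melting temperatures

The melt model is a logistic transition between linear-free plateaus
(low/high baselines 0.1/1.1 RFU, width 1.5 °C) on a 30–90 °C, 0.5 °C
grid; the post-transition aggregation decay of real dye signals is not
modelled, so tests on these curves say nothing about Tm extraction under
strong signal roll-off. Tm is the maximum of the derivative, computed by
a single Savitzky–Golay pass (degree 2, window 7 points, first
derivative). The discrete argmax is refined by a least-squares parabola
over the peak's contiguous half-maximum region: a 3-point vertex is far
too noise-sensitive because the curvature signal across one ramp step is
smaller than the propagated noise, while the half-maximum window (~10
points here) averages it down and is symmetric around a symmetric peak,
so it adds no bias. Flat curves (derivative peak within 4 robust SDs of
the derivative's median) return a no-Tm flag rather than a boundary
argmax. With 2% amplitude noise this recovers planted Tm values within
0.3 °C in (measured) 100/100 seeded curves.

## Fingerprints and novelty

Synthetic bitsets give exact control: molecules draw from disjoint bit
pools, and a planted pair shares k bits with k = round(2m·Tc/(1 + Tc))
for m bits per molecule, so the achieved Tc (recorded as ground truth) is
exact whenever that expression is an integer. The SMILES route builds a
Morgan-style circular fingerprint: iterative neighbourhood rehashing of
atom invariants (element, degree, total bond order) over radius-0…2
shells, hashed onto 2048 bits. Radius 2 / 2048 bits are the de-facto
ECFP4 defaults; both are arguments. Order-independence of the invariants
makes equal molecules in different SMILES spellings collide exactly, which
the tests check on aromatic vs kekulized benzene. Tc of two empty
fingerprints is defined as 0 so unparsable molecules can never look
similar.

ΣTc sums similarities strictly above 0.3 ("greater than" is taken
literally; a boundary value is excluded) with the query removed from the
reference set — otherwise every known molecule carries ΣTc ≥ 1 from
itself. The diversity filter is a greedy first pass in input order; its
defining guarantee, every retained pair below the ceiling, is asserted
directly. Ligand efficiency uses heavy-atom count: the footnote term
"heteroatoms" is only arithmetically consistent with ~22 heavy atoms for
a 300 Da compound, so HA is read as the standard non-hydrogen count.

## Problem sizes and determinism

Every generator takes one explicit integer seed and restores the caller's
RNG stream on exit; identical spec + seed is byte-identical output.
Suite-wide sizes were chosen to keep each property informative at desk
scale: 33/2370 score libraries (the canonical benchmark shape), 200 label
shuffles for the chance constant, 2×10⁴ per class for the closed-form AUC
check, 20-seed Monte-Carlo Kd recovery, 100 noisy melts. The full test
suite runs in under a minute on one core.

## Known limitations

- Additive Gaussian noise everywhere; heavier-tailed spectral artefacts,
  baseline drift and DSF aggregation decay are not emulated, so the
  recovery numbers are upper bounds on real-data behaviour.
- No symmetry-aware RMSD; ligands with topological automorphisms will
  read high against a flipped but equivalent pose.
- The two-site exchange model assumes a single binding site and shared
  global kinetics across residues; ternary or allosteric systems are out
  of scope.
- ΣTc values depend on the fingerprint family and parameters; absolute
  values are comparable only within one configuration.
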