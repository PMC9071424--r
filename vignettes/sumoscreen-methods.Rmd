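---
title: "sumoscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sumoscreen: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoscreen)
```

This vignette is the package's own account of the statistics it
implements: the model behind each stage, the tunable parameters with
their defaults and units, what the synthetic generators do and do not
emulate, and the choices made where the underlying methodology left the
design open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Microarray screen (`arrays`)

**Model.** A proteome array is probed with fluorescent polySUMO2 chains;
a mock array sees quenched dye only. Each protein is spotted in
duplicate; spots are deposited by print-tip blocks. The analysis chain
is:

1. per-spot S/N = (fg_median − bg_median) / bg_sd (GenePix-style fields);
2. division by the median S/N of the non-flagged biological control
   spots of the same array (within-array biological normalisation);
3. arithmetic mean over non-flagged duplicates;
4. D = log2(bound) − log2(mock), A = the mean of the two log2 values;
5. robust loess of D on A within each print-tip block (stage 1), then a
   robust 2-D loess of the stage-1 residuals on spot coordinates (x, y)
   (stage 2). The stage-2 residual is the M-value;
6. hits: M ≥ mean(M) + k·SD(M) over the non-control population, sample
   (n−1) SD, default k = 1; isoforms collapsed by identifier prefix for
   the unique-candidate count.

**Open choices made here.** The S/N definition, the log2 scale, division
(rather than subtraction) by the control median, loess spans (0.75 per
print-tip group, 0.3 spatial), ≥ at the threshold, nonzero-flag
exclusion, and an epsilon floor of 1e−6 on non-positive normalised
values before log2 are all package decisions; each is a configurable
argument. Robust (`family = "symmetric"`) loess matters: spiked true
binders are outliers in D and must not be absorbed into the trend.

**What a green test establishes.** With k = 1, ~16% of null features
exceed the threshold by construction (Gaussian upper tail) — the
threshold is a candidate filter whose false-positive rate the tests
check, not a significance test. Spike recovery is tested with planted
effects of 3.5× the residual noise SD (chosen a priori, comfortably
inside the "≥ 3 SD" regime the recall benchmark assumes, because at
exactly 3 SD the expected recall of a mean+1·SD threshold is ~0.97 and a
0.95 floor over 200 spikes would hinge on luck).

**Not emulated.** Image segmentation, saturated or morphologically bad
spots beyond a flag column, dye swaps, multi-array batch effects.

## 2. Carbene footprinting (`footprint`)

**Model.** A photochemically generated carbene labels solvent-exposed
surfaces; partner binding occludes labelling. Per tryptic peptide and
replicate, fractional modification is

P = A(labelled) / (A(labelled) + A(unlabelled)),

scale-invariant in the peak areas. Apo vs bound triplicates are compared
with a two-sided Welch t-test; peptides with p < α (default 0.05) are
*masked* (mean P drops) or *unmasked* (rises), otherwise *unchanged*;
fewer than two usable replicates gives *undetected*. Residues inherit
their covering peptide's class; among overlapping peptides (missed
cleavages) significant calls beat non-significant ones and larger
|ΔP| wins; *unchanged* beats *undetected*.

**Choices.** Welch rather than pooled-variance Student (robust default
at n = 3; the method description says only "Student t-test"). The
trypsin rule is cleave after K/R except before P. No multiple-testing
correction by default, matching the per-peptide α convention of the
assay; `p_adjust = "BH"` is available. Zero-variance degenerate groups
use the convention: identical constant groups p = 1, distinct constant
groups p = 0 (this makes noise-free fixtures classify deterministically).

**Generator.** `gen_footprint()` digests a (default random, 164-residue)
sequence, gives each peptide a baseline P ~ U(0.35, 0.6), shifts
peptides overlapping planted spans by ±0.3 in the bound condition, and
emits areas with multiplicative log-normal noise (σ = 0.02). Because α
is per-peptide, a calibrated pipeline *must* produce ~5% significant
calls on null fixtures; the tests therefore check pooled false-positive
rates against a binomial envelope around α, and perfect recovery of the
planted peptides — not exact set equality, which no calibrated test
attains. The power property compares the package route against an
independently hand-coded Welch simulation: at n = 3 the pooled-df
noncentral-t formula overstates Welch power by ~10 points, so it is not
a usable oracle.

## 3. NMR titration ladders (`nmr`)

**Model.** Residues in a binding surface broaden/lose intensity as
titrant is added. For each residue, ratios I(e)/I(0) at each
molar-equivalent point e are scanned against an ordered ladder of bins
(most-affected first; first satisfied bin wins; missing points skip
their bins; nothing satisfied = unaffected). Eight titration-specific
ladders ship built-in; custom ladders load from a three-column text
file. For weak binding scored by shifts, CSP = √(Δδ_H² + (0.14·Δδ_N)²)
(0.14 is the community-standard ¹⁵N scaling; the formula itself is a
package decision) is ranked in SD multiples, with SD either supplied
(e.g. the stated 0.0012 ppm, which is below the ¹H digital resolution of
0.0078 ppm — both are exposed, neither reconciled here) or estimated
robustly as 1.4826×MAD.

**Conventions.** "<45%" is strict, interval bins are half-open
[lo, hi); printed interval labels of the SUMO2-target ladders
("21–30%", "<31–40%", "41–66%") are normalised to contiguous bins
[0,.2) [.2,.3) [.3,.4) [.4,.66). The SD-multiple top bin is inclusive,
so exactly 5 SD lands in the ">5 SD" rank. First-match-wins over bins
ordered per equivalent from zero makes classification monotone:
pointwise-smaller ratio vectors never rank less affected (property
tested over 10⁴ random vectors). Prolines and unassigned residues pass
through as a distinct grey class, never classified.

**Generator.** `gen_nmr_titration()` drops site-residue intensity by
depth·θ(e) with single-site occupancy θ(e) = e/(K_app + e)
(K_app = 0.05 equivalents, i.e. near-stoichiometric tight binding;
depth ~ U(0.85, 1)) and multiplicative Gaussian noise. It emulates
intensity loss only — no exchange-regime line-shape physics, no peak
overlap, no assignment transfer errors.

## 4. Motif scan and enrichment (`motif`)

The XRCC4-like SIM K-[SDE]-[VLI]-[DES]-[FVLI] (and any bracket-notation
pattern) is scanned with overlapping matches reported at 1-based starts;
ambiguity letters never match. Acidic context counts D/E in the 5
residues flanking each side (clipped at termini), context = count ≥ 2;
window and count are configurable, as the underlying notion
("surrounded by acidic residues") has no canonical quantification.
Enrichment of a receptor set among motif-positive proteins uses the
one-sided Fisher exact test on per-protein presence/absence (the
hypergeometric upper tail; tests verify it against direct tail summation
and a 10⁵-draw label-permutation Monte Carlo), with a Haldane-corrected
sample odds ratio. Proteome-version-dependent counts (how many human
proteins contain the motif) are deliberately not asserted anywhere.

## 5. Binding isotherms (`binding`)

Two response models, always with a fitted baseline offset:

- hyperbolic: R = offset + B_max·L/(K_D + L), for equilibrium SPR where
  the immobilised partner does not deplete the analyte;
- ligand depletion: f = ((T + L + K_D) − √((T + L + K_D)² − 4TL))/(2T),
  R = offset + B_max·f, evaluated in the cancellation-free form
  2L/(b + √(b² − 4TL)). This is the right model for MST-style data where
  the labelled target (T = 5 nM in the emulated design) is comparable to
  K_D — fitting the hyperbola to such data inflates K_D, a bias the test
  suite asserts directionally.

Fitting profiles the linear parameters (offset, B_max) over a 25-point
log-spaced K_D grid spanning the concentration range ±1 decade, then
refines with `nls` (port, parameter tolerance 1e−10); standard errors
come from the Jacobian at the optimum, and non-convergence is reported
with best-found parameters rather than an error. Kinetic rate constants
are out of scope. `normalize_repair()` implements the reporter-assay
convention GFP⁺% / (transfection efficiency %/100).

**Generator.** `gen_binding_curve()` uses the depletion isotherm at
K_D = 3.2 nM, T = 5 nM, 16 doubling dilutions from 500 nM, triplicate,
2% multiplicative noise — the emulated MST design; the acceptance script
refits it from scratch and reports the recovered K_D (target `t1`).

## 6. Reproducibility and the CLI

Every generator takes a mandatory integer seed and is a pure function of
its configuration (byte-identical outputs under a fixed seed, asserted
in the tests). The CLI (`exec/sumoscreen`, or `sumoscreen_cli()`
in-process) writes a `.manifest.json` per run — command, resolved
parameters, seed, input MD5 checksums, outputs, package version — and
uses exit codes 0 (success), 2 (validation/usage) and 3 (degenerate
data, signalled as a distinct condition class).

## 7. Known limitations

- Loess spans are fixed defaults, not cross-validated; very small
  print-tip groups (< 10 points) skip stage 1 with a warning.
- The footprinting input is a pre-integrated peak-area table; raw
  spectra, XIC extraction and multiply-labelled species are upstream.
- Ladder classification is per-residue and ignores spatial coherence of
  binding surfaces; no exchange-regime modelling.
- The enrichment universe is whatever identifier list the caller
  supplies; isoform redundancy in real proteomes is the caller's
  responsibility.
- The depletion fit assumes a single site and 1:1 stoichiometry;
  avidity effects of multivalent SUMO chains are precisely what it
  cannot represent — it recovers an apparent K_D.
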