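---
title: "Marker frequency analysis of replication termination: models, estimators and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker frequency analysis of replication termination: models, estimators and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfaterm)
```

## The model

In a steady-state exponential culture every cell carries a nested set of
partially replicated chromosomes.  A locus replicated `a` minutes after
initiation has expected copy number proportional to `2^(-a/τ)`, where `τ`
is the doubling time (Cooper–Helmstetter).  With a uniform fork speed `v`,
the replication age of position `x` on a circular replicon with origins
`o_i` firing at offsets `δ_i` is

    age(x) = min over origins and both fork directions of
             δ_i + arc(o_i → x) / v

and the log2 marker frequency is affine in position on every
origin-to-terminus arc, with slope magnitude `1/(v·τ)` per bp.  The
minimum correctly encodes fork convergence for equal speeds: the fork that
arrives first is the one that replicates the locus.  The fork convergence
point (fcp) of a segment between adjacent origins `o_L`, `o_R` is where
the arrival times are equal,

    fcp_arc = (arc + v·(δ_R − δ_L)) / 2 ,

i.e. the segment midpoint (mp) under synchronous firing, shifted by
`v·Δδ/2` toward the later origin otherwise.

**Gaussian termination zone.**  The fcp inferred from a population profile
is an average.  Let the convergence position of an individual cell be
`p ~ N(fcp, σ²)`.  A position `s` left of `p` is replicated by the left
fork (on the left log2 line `L`), otherwise by the right fork (line `R`),
so the expected linear marker frequency is the mixture

    MF(s) = Φ((fcp − s)/σ) · 2^L(s) + (1 − Φ((fcp − s)/σ)) · 2^R(s).

This is the unique two-line mixture whose weight is the probability that
the convergence point lies beyond `s`; at `σ = 0` it reduces exactly to
the piecewise model.  Note that the mixture *deepens* the valley around
the fcp (a cell whose fork already converged before `s` reached `s` with
the slower, later-arriving fork).  We report `S95 = 2 × 1.959964 × σ`,
the width of the region centred on the fcp containing 95% of convergence
events; the 1.96 convention is a choice we document rather than a value
with a field standard.

**crtS coupling.**  For two-chromosome genomes in the *V. cholerae*
style, the secondary chromosome initiates only after the chr1 locus crtS
has been replicated: `δ_oriC2 = age(crtS) + extra_delay`.  The extra
licensing delay that makes the two chromosomes co-terminate is
`(L1 − L2)/(2v) − age(crtS)` (solved, not fitted), and the package's
wild-type fixture uses exactly that value.

## From reads to profiles

Counts are read starts per fixed-width bin (not per-base depth): start
counts are independent Poisson-like draws, which is also the simulator's
sampling model.  Coordinates are 0-based half-open internally, 1-based in
reports, matching bedGraph input.  Trimming masks zero-count bins and
Tukey-fence outliers (`[Q1 − k·IQR, Q3 + k·IQR]`, default `k = 3`,
quartiles per replicon over unmasked bins); when the IQR is zero only
zero bins are masked.  The rule is deliberately parameter-light and `k`
is exposed in the run configuration.  Normalisation divides every count
by the grand total of unmasked counts across all replicons — preserving
the biologically meaningful chr2/chr1 copy ratio — and then anchors the
minimum of the reference replicon at log2 = 0.  Masked bins never enter
totals, minima or fits.

## Estimators

**Breakpoint (fcp).**  Per segment, every unmasked bin centre strictly
inside the arc is a candidate breakpoint (excluding 5 bins adjacent to
each origin, which shields origin-proximal initiation transients); log2
marker frequency is regressed on arc position by unweighted OLS
separately on the two sides (the candidate bin belongs to both), and the
candidate minimising the total SSE wins, ties broken toward the smaller
arc coordinate for determinism.  The scan is exact and O(n) via
prefix-sum OLS; a per-candidate `lm()` loop is kept as the test oracle.
Regression is unweighted because after the log transform under
near-uniform depth the variance is nearly constant.  There is no sub-bin
interpolation by default: bin noise dominates below bin scale.

**Gaussian width (σ).**  Holding the fcp fixed, σ is found by bounded
1-D least squares in *linear* marker-frequency space (the mixture is a
sum of exponentials, not log-linear) over `σ ∈ [bin/10, arc/4]`, using a
40-point geometric grid plus golden-section refinement.  The two arm
lines are nuisance parameters: for each candidate σ they are refit in
log2 space on bins farther than `3σ` from the fcp.  This exclusion
matters — lines fitted through the rounded valley are biased toward it,
and with them a noiseless σ = 50 kb dataset is "recovered" at 33 kb,
versus 0.4% error with the exclusion refit.  Fits landing at a bound are
flagged (`lower_bound`/`upper_bound`) rather than hidden.  A joint
fcp+σ refit exists behind `refit_fcp = TRUE` but the default keeps the
breakpoint fixed.

**Origin localisation.**  The same two-line machinery applied to the
coverage peak inside a window centred on the highest unmasked bin, at two
window sizes (default 400 and 600 kb), reported per window without
averaging.  The grid-argmin split is a *nonregular* estimator: its error
scales as `(σ_noise²/(ρ·Δβ²))^(1/3)` (bin density ρ, slope change Δβ) and
is window-independent — about 9 kb (0.3% of a 2.96 Mb chromosome) at
217×-equivalent depth, regardless of window.  The reported apex is
therefore the *intersection of the two refit arm lines*, a regular
estimator whose error shrinks as `1/√window`; with it, 19/20 seeded runs
localise the origin within 0.5% of the replicon length at both default
windows.  `refine = FALSE` restores the raw argmin.

**Synchrony and asymmetry.**  chr2-vs-chr1 termination synchrony is the
log2 marker-frequency difference at the two fcps; |Δ| within 0.05 log2
(≈3.5% copy number, below what profile noise at this depth can
discriminate) is "synchronous".  Arm-slope asymmetry across a shared
origin is flagged outside `[1/1.25, 1.25]` (strict), the signature of a
head-on rRNA-operon conflict on one arm.

## The simulator

`synthetic_spec()` encodes the study conditions: Cooper–Helmstetter
expectation per bin, per-segment Gaussian fcp spread, optional head-on
rrn perturbations (multiplicative depression `1 − magnitude·ramp`, linear
ramp over `extent` downstream of the locus, applied only to bins whose
replicating fork travels against transcription — the ramp shape is a
modelling choice; the source observations are qualitative), and
independent Poisson counts with mean `depth × MF/min(MF)`.

Fixture defaults, chosen once as realistic for exponential growth in
minimal medium and kept fixed: `τ = 40` min, `v = 60` kb/min (slope
`1/(v·τ) ≈ 4.2e-7` log2/bp, origin:terminus ratio ≈ 1.5, matching the
dynamic range such profiles show), 1 kb bins (resolving a 4 kb S95 while
keeping ≥100 reads/bin), 2 300 reads/bin at the profile minimum (217×
coverage with 75 bp single reads in 1 kb bins), σ = 1 kb for wild-type
termination zones and 20 kb for ectopic-origin strains.  Geometry stand-ins
(true coordinates are configurable): chr1 = 2 961 149 bp and
chr2 = 1 072 315 bp, origins at 0, dif at the antipode, crtS 690 kb up
the left replichore, ectopic origins 650 kb (left) and 1 190 kb (right)
from oriC1.  The simulator does not model GC bias, mappability,
sequencing error, fork stalling/restart dynamics or per-arm fork speeds —
passing recovery tests therefore demonstrates correctness of the
estimators under counting noise, not robustness to those artefacts.

## What is — and is not — statistically attainable

Parameter-recovery studies at 200 reads/bin (1 kb bins, slope 5e-7
log2/bp, σ = 20 kb) are reported by `scripts/acceptance.R` and run in the
test suite.  Two of their textbook targets are information-limited at
this depth, and the package reports the honest values rather than tuning
conditions:

* the grid-scan fcp has a cube-root error floor of ~20–40 kb here
  (measured median ≈ 40 kb across 20 seeds); even the Cramér–Rao bound
  for a fully regular estimator with known nuisance parameters is tens
  of kb, because the per-bin log2 noise is 0.10 while the valley
  curvature feature has amplitude ~0.004 log2;
* σ = 20 kb is likewise unidentifiable at this depth — with the fcp
  forced to truth the fit is median-unbiased but has ~78% median
  relative error; recovery within 1% is demonstrated on noiseless
  in-class data instead.

At depths where the floor permits it (the suite uses 10⁶ reads/bin for
the round-trip property) the pipeline recovers fcps within 3 bins, and
all structural properties (oracle equivalence of the scan, σ→0 mixture
limit, S95/σ ratio, rotation equivariance, midpoint law) hold to
tolerance at any depth.

## Degenerate inputs and numerical notes

Zero-IQR trimming masks only zeros; fully masked profiles raise
stage-named errors; a masked fcp bin is replaced by the nearest unmasked
bin within 5 bins for synchrony lookups; segments shorter than 10 bins or
with fewer than 5 unmasked bins per side refuse to fit; flat profiles
raise "no peak" in origin localisation; the two-piece scan centres arc
coordinates before forming moment sums to avoid cancellation; SSEs are
clamped at zero.  Problem sizes in tests and the acceptance script (1 Mb
and 2.96 Mb replicons, 20 seeds per study) keep a full run under a minute
on one CPU while leaving every estimator in its asymptotic regime.

## Known limitations

The trimming rule stands in for the original study's unavailable
supplementary procedure and is configurable; normalisation uses the grand
total across replicons (per-chromosome totals would erase the chr2/chr1
ratio); fcp−mp deviations are reported as magnitudes, not tested
hypotheses; segments too noisy to trust can be vetoed on the reported
SSE per bin, but any threshold is a package choice; linear
(non-circular) replicons are supported in the data model but the
fixtures and most validation are circular.
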