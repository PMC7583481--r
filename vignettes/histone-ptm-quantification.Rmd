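---
title: "Quantifying histone PTMs from propionylated bottom-up LC-MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone PTMs from propionylated bottom-up LC-MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneptm)
```

## The measurement problem

Histone tails carry dense, combinatorial post-translational modifications
(PTMs): lysine mono-/di-/tri-methylation (me1/me2/me3), lysine acetylation
(ac) and serine/threonine phosphorylation (ph). Bottom-up mass spectrometry
quantifies them at the peptide level, but histones are so rich in lysine and
arginine that plain tryptic digestion would shred them into uninformative
fragments. The standard workaround, which this package models, is two rounds
of propionylation: propionic anhydride alkylates the epsilon-amine of every
unmodified or monomethylated lysine (blocking trypsin there and forcing
ArgC-like cleavage after arginine only), and, after digestion, the newly
created peptide N-termini. A lysine carrying me2, me3 or ac has no reactive
amine and receives no propionyl group. Every peptide species is therefore a
*backbone* (histone, start/end coordinates, sequence) plus a set of
biological PTMs plus a deterministic set of propionyl groups.

The quantity of interest is the **relative abundance (ratio)** of each
(un)modified form of a backbone: its extracted-ion-chromatogram (XIC) area
divided by the summed areas of *all* catalog forms of that same backbone
(including, e.g., the phosphorylated series of H3 9-17, which the catalog
lists as a second row of the same backbone). Single-PTM abundances are then
the sums of the ratios of all forms carrying the mark, and histone-variant
abundance is estimated from sequence-distinct marker peptides as
`area_variant / (area_variant + area_canonical)` per aligned pair, pooled by
area-weighted mean.

## Mass engine

Monoisotopic residue masses from standard atomic composition (6 decimals),
water 18.010565 Da, proton 1.00727646 Da. Modification deltas: me1
14.015650, me2 28.031300, me3 42.046950, ac 42.010565, ph 79.966331,
propionyl 56.026215 Da. Trimethyl and acetyl differ by 0.036385 Da; whether
a me3 form and an ac form are resolvable at a given tolerance is computed
from m/z and charge, never assumed. Precursor m/z is
`(M + z * proton) / z`; fragment ions are singly charged b/y by default
(sufficient to discriminate isobaric precursors of charge <= 3), with the
N-terminal propionyl counted in b ions and the C-terminal water in y ions.
Biological-mod sites are expressed in protein coordinates exactly as in the
shipped catalog (e.g. `K9me1K14ac` on the 9-17 peptide), so output labels
match the field's conventions.

Under-propionylation is not modeled: the derivatization protocol drives the
reaction to >95% completion, and a completeness model would add a parameter
the data cannot constrain.

## The catalog

`load_catalog()` ships a machine-readable transcription of the analyzed
peptide space: 24 backbones with 195 enumerated forms, 19 targeted isobaric
groups (label, m/z, charge, retention-time window), and 10 variant-marker
peptides (H3.3, H2A.Z ortholog, H1.0). On load, every form name is parsed
and validated against its sequence, and every targeted group's printed m/z
is recomputed from the derivatization rules. Two printed values deviate by
more than 5 ppm from recomputation (528.2988, where the companion
phospho row equals the *recomputed* value plus ph/2 exactly, implicating a
typo; and the 3+ row 558.6674); they are flagged `printed_mz_discrepant`
and carried as metadata rather than force-fitted. The two 27-40 rows of the
H3.3 family are assigned to the catalog sequences that reproduce their me1
group m/z exactly (874.5251 and 851.4859 at 2+).

## Simulator: what it emulates, and what it does not

The simulator exists so that the entire pipeline can be exercised against a
known truth. `sample_ground_truth()` draws per-backbone form fractions from
a symmetric Dirichlet (concentration 1 by default: broad, occasionally
sparse compositions), per-backbone totals log-uniform over `5e8`-`5e9`
area units (typical high-abundance histone XIC areas), and apex retention
times: isobaric clusters that match a targeted-list entry elute inside that
entry's window; everything else elutes mid-gradient (5-65 min of a 70-min
gradient). Members of an isobaric cluster co-elute only approximately: they
spread uniformly over `coelution_spread = 2` min around the cluster apex,
the separation scale positional isomers show on a real gradient. Peaks are
Gaussian with sigma 0.05 min sampled every 0.02 min (>= 10 points across a
peak), with a binomial averagine-style isotope envelope of depth 3.
Targeted MS2 scans are emitted across each multi-member cluster's elution
range with fragment intensities proportional to each member's instantaneous
MS1 contribution times a per-fragment-position efficiency drawn uniformly
from [0.3, 1] once per backbone per run. Drawing efficiency per *position*
(series x cleavage index) rather than per ion reflects that backbone
cleavage propensity, not the side-chain modification, dominates
fragmentation efficiency; it also makes positionally matched ions of
isobaric members directly comparable. Optional noise is multiplicative
log-normal per centroid plus uniform ppm jitter.

Deliberately not emulated: profile-mode peaks, dynamic exclusion, real DDA
stochasticity, co-isolation interference, chemical noise and adducts,
retention-time drift between runs, and isotope fine structure. Passing
closed-loop tests therefore demonstrates correctness of the extraction,
splitting, and normalization arithmetic under controlled conditions -- not
robustness to everything real chromatography does.

Two modeling choices keep the truth self-consistent. First, the canonical
H3 marker peptide VTIMPKDIQLAR is the same physical species as the
unmodified form of the H3 117-128 backbone; when that backbone is
simulated, the marker aliases to it and its paired variant abundance is
rescaled so the pair's true variant fraction is preserved. Second,
near-m/z species from different backbones (including their isotopologues)
are pushed apart in retention time, standing in for the relative-RT
knowledge that reference implementations encode.

## Extraction and peak picking

`extract_xic()` sums centroid intensities within +/-ppm (default 10 ppm
MS1) of the theoretical m/z per MS1 scan; empty scans contribute zero.
`find_peaks()` detects contiguous regions above
`max(noise_floor, 1% of window max)`, extends them downhill to flanking
local minima, and integrates by the trapezoidal rule; the most intense peak
wins, ties broken by earlier RT. Only the monoisotopic isotopologue is
quantified; areas are divided by the modeled isotopologue-0 envelope share
so they estimate total species abundance (`envelope_correction`, on by
default). A candidate peak is vetoed when the XIC one isotope spacing
*below* carries more than half its apex intensity -- such a peak is the +1
isotopologue of a lighter species, not a monoisotopic peak. Retention-time
windows for untargeted forms default to the whole run.

## Isobaric discrimination

For a cluster of same-backbone forms whose precursor m/z agree within
tolerance, the MS1 peak area is shared and must be split using targeted MS2
evidence (MS2 tolerance 20 ppm, independent of MS1). Two regimes:

* **Unique ions.** When every member retains fragment ions no other member
  can produce, each member's weight is its pooled unique-ion intensity
  share over the qualifying scans (scans whose precursor matches the
  cluster and whose RT lies inside the integrated MS1 peak).
* **Position subgroups.** In larger acetyl-isomer groups the "middle"
  members retain *no* unique singly charged b/y ion: at every cleavage
  position their fragment mass coincides with some other member's. They
  are still separable, because at a given position the distinct fragment
  masses partition the members into subgroups, and the intensity shares of
  those mass variants estimate subgroup abundance sums (the per-position
  efficiency cancels in the ratio). A nonnegative least-squares fit on the
  simplex recovers the member weights.

Split areas always sum to the group area; a cluster with no usable MS2
evidence is reported as an `aggregate` pseudo-form flagged `unresolved`
rather than guessed. Splitting is applied *per detected MS1 peak* and the
member shares summed across peaks, which is what resolves the six-member
double-acetyl groups: fully co-eluting complementary isomer quartets (e.g.
K5acK10ac + K8acK16ac versus K5acK16ac + K8acK10ac) are a rank-deficient
system for cumulative b/y evidence and cannot be separated by any
singly-charged-fragment method; partial chromatographic separation breaks
the degeneracy, and nonnegativity resolves it whenever a boundary binds.
The residual case -- complementary isomers co-eluting exactly -- remains a
documented limitation.

## Statistics

Per mark, ordinary least squares of `log2(ratio)` on batch date and
condition (both categorical): `log2(mark) ~ date + condition`. Ratios of
zero are floored at `pseudo_ratio = 1e-6` before the log. Contrasts are
differences of condition coefficients with two-sided t p-values on the
residual degrees of freedom; in the single-batch two-condition case this
reduces exactly to the pooled-variance t-test. Multiple testing is
controlled by Benjamini-Hochberg step-up q-values (a lightweight Storey
pi0 rescaling is available behind a flag; BH is the default because pi0
estimation is unstable at the small mark counts typical here). Corrected
p-values map to the star tiers used for heatmap annotation
((0.05,0.1] -> `*` through (0,0.0001] -> `*****`). Heatmap row ordering
comes from agglomerative hierarchical clustering with complete linkage on
Euclidean distances, the referenced defaults. A design in which condition
is confounded with batch is an explicit error naming the confounded batch;
zero-variance marks are dropped with a warning. The modeling unit is a row
of the sample sheet -- whether that is an MS run or a biological replicate
is the caller's decision, and aggregation is left to the caller.

## Numerical choices and degenerate inputs

* Peak threshold 1% of window maximum: high enough to cut quadrature tails
  (a Gaussian loses ~0.25% of area beyond the 1% contour, well inside the
  2% integration tolerance), low enough to keep minor forms.
* Trapezoidal integration on the 0.02-min grid: with sigma 0.05 min a peak
  spans ~20 points, making quadrature error negligible against the 1-2%
  tolerances used in tests.
* Under per-centroid log-normal noise of sigma 0.2 the area estimator has
  about 9 effective points per peak and hence ~4% relative standard
  deviation (intensity-weighted trapezoid), which is the scale of the
  recovery bounds used for noisy closed-loop tests.
* All-zero XICs, empty backbone blocks and zero-MS2 runs degrade to
  explicit flags (`not_detected`, `no_signal`, `unresolved`), never to
  silent zeros or forced peak picks. Printed RT values for near-zero forms
  in reference output tables are not reproducible from the stated method;
  this implementation reports `not_detected` instead of forcing a pick.
* Exact area conservation in splits is enforced by assigning the rounding
  remainder to the largest member.
* `qr`-rank checking (not failure of `lm`) detects confounded designs.

## Problem sizes

Closed-loop simulations in the test suite use a seven-backbone panel
(H3 3-8, 9-17, 18-26, 27-40, 54-63, H4 20-23, H2B 31-40; 74 forms, ~3500
MS1 scans over a 70-min gradient, one noiseless and one noisy run), chosen
so that every isobaric cluster is fully identifiable from singly charged
b/y ions and no cross-backbone m/z degeneracy is present. The null
calibration of the linear model uses 1000 seeded replicates of a
two-condition, ten-sample design. Full-catalog simulations (24 backbones,
195 forms) run in a few seconds and are exercised in the examples.

## Known limitations

* One cross-backbone near-degeneracy exists in the catalog itself (an H3
  73-83 form and an H2B 31-40 form sit 2.8 ppm apart at 2+); m/z alone
  cannot separate them, and without cross-run RT calibration the most
  intense peak wins. Real deployments rely on retention-time knowledge.
* Exactly co-eluting complementary double-acetyl isomers are not
  identifiable from singly charged b/y ions (see above).
* No chromatographic alignment across runs; each run is quantified
  independently and compared at the ratio level.
* DIA acquisition, vendor raw formats and discovery of unlisted PTMs are
  out of scope; mzML (centroided) and the internal scan table are the only
  input dialects.
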