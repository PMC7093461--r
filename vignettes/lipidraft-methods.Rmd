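---
title: "Methods: lipid identification, quantification and NMR ratio profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid identification, quantification and NMR ratio profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidraft)
```

## Scope

`lipidraft` implements the post-detection computational chain of a
quantitative membrane lipidomics study comparing lipid-raft and non-raft
membrane fractions, plus the residue-resolved NMR intensity-ratio analysis
used to read out protein--membrane association. The pipeline starts from a
detected, aligned LC-MS feature table (feature detection and RT alignment
belong to upstream tools such as XCMS and are deliberately out of scope)
and ends at subclass compositions with group statistics. Every stage can
be exercised on seeded synthetic data with known ground truth.

## Identification model

A feature is identified in three stages.

**Accurate mass.** All library entries of the feature's ionization mode
whose precursor m/z lies within `precursor_tol_ppm` of the feature m/z
become candidates. The tolerance defaults to 10 ppm, a typical value for
the QTOF instrument class; it is configurable because no single value
suits all instruments. Precursor m/z values derive from neutral
monoisotopic masses and a configurable adduct table (`[M+H]+`, `[M+NH4]+`,
`[M-H]-`, `[M+HCOO]-`; proton mass 1.007276 Da); only singly charged ions
are modeled, since the lipid classes in the panel ionize predominantly
singly charged.

**Spectral similarity.** Candidates are scored with a weighted *reverse*
dot product over the library fragments:

$$
S \;=\; \frac{\sum_k (I_{D,k}^{\,n}\, mz_{D,k}^{\,m})\,(I_{E,k}^{\,n}\, mz_{E,k}^{\,m})}
       {\sqrt{\sum_k (I_{D,k}^{\,n} \,mz_{D,k}^{\,m})^2 \;\sum_k (I_{E,k}^{\,n}\, mz_{E,k}^{\,m})^2}}
$$

with $m = 1$ and $n = 0.6$ in positive mode or $n = 1$ in negative mode.
The sum runs over the library (database, $D$) fragments only — the
standard reverse-match convention: experimental peaks not near any library
fragment are ignored, which makes the score robust to co-isolation
contaminants. $I_{E,k}$ is the summed experimental intensity within
`fragment_tol_da` (default 0.02 Da) of the library fragment m/z, 0 when
none matches; $mz_{E,k}$ is the intensity-weighted mean m/z of the matched
peaks (the library m/z when none). Summing multiple in-tolerance peaks is
a deliberate, deterministic choice; alternatives (nearest peak, maximum)
are tolerance-fragile. By Cauchy--Schwarz the score lies in $[0, 1]$, is
invariant to uniform intensity scaling of either spectrum (so no base-peak
normalization is applied — it would be redundant), and equals 1 for a
self-match. Numerically the score is computed in squared-cosine form
($\sqrt{num^2/(d_D d_E)}$) so that a spectrum scored against itself yields
exactly 1 in floating point, not 1 minus an ulp.

**RT similarity.** Experimental RT is compared with the library's
predicted RT through a trapezoidal score in the absolute deviation $d$:
1 for $d \le a$, linear to 0 between $a$ and $b$, 0 beyond $b$. The
plateau and zero widths default to $a = 0.15$ and $b = 0.5$ minutes.
These two geometry parameters are package defaults chosen for a ~18-min
gradient (the plateau absorbs alignment-scale jitter, the flank spans a
plausible prediction error); they are configurable and always echoed in
the run log precisely because they are a modeling choice, not a
measurement.

**Acceptance.** Matches with spectral score $> 0.8$ are kept as
candidates; a candidate is accepted when its RT score is also $> 0.5$.
Both thresholds are strict inequalities and configurable. At most one
identification is accepted per feature: the best spectral score, ties
broken by smaller absolute mass error, then lexicographic species id —
deterministic and auditable. Whether the RT filter is applied before or
after choosing the best spectral candidate is ambiguous in principle; the
package selects the best-scoring candidate among those passing *both*
filters and returns every scored candidate (accepted or not) in the audit
table so either reading can be reconstructed. Features without an MS/MS
spectrum are never identified (no MS1-only annotation).

## Absolute quantification

Each accepted analyte is quantified against its subclass's spiked
deuterated internal standard in the same sample:
amount$_{\mu g}$ = (analyte area / IS area) × IS amount, assuming a
response factor of 1 between an analyte and its class standard (a
per-species override exists). The microgram amount converts to picomoles
with the species' average molecular weight; when not given explicitly the
package approximates it as monoisotopic mass × 1.0007, an error far below
quantification noise. The default spike panel mirrors a two-fraction
membrane study: PC 1.5, PE 0.5, PG 0.25, PS 0.5, PI 0.5, PA 0.05, Cer 0.2
(raft) / 0.02 (non-raft), SM 0.05 / 0.01, LPC 0.02, LPE 0.02, TG 10 and
cholesterol-d7 2 μg.

Cholesterol supports a second route: an external calibration curve of
response ratio versus concentration, fitted by ordinary least squares over
a declared linear range (0.5--200 μg/mL by default). Interpolations whose
*undiluted* value exceeds the upper limit are flagged out-of-range,
mirroring the re-analyze-after-dilution rule; a diluted re-analysis inside
the range is scaled back up and cleared. Values below the lower limit are
flagged but reported as-is, since only the high end has a defined rescue
procedure. In `build_quant_table()` the default route for cholesterol is
its d7 internal standard (also spiked); the calibration route is engaged
by passing a fitted curve plus the extract volume used to convert
concentration to amount. Zero or missing internal-standard areas mark the
affected amounts `NA` with a warning — recorded, never silently skipped.

## Composition and group comparison

Per sample, species amounts (pmol) are summed within subclass and divided
by the sample's total lipid moles: mol% (so compositions are computed on
mole amounts, matching the "mol%" unit, not on mass). Species absent from
a sample contribute 0 so denominators are comparable across replicates.
Chain-length and saturation profiles are mole-fraction histograms over
total acyl carbons and double bonds, restricted by default to the
glycerophospholipids (PC, PE, PS, PI, PG, PA).

Group differences per subclass use the two-sample Student's t-test on mol%
across biological replicates — pooled-variance, two-sided, the
conventional reading of "Student's t-test"; Welch is available by flag.
Significance labels follow the declared tiers: `n.s.` (p ≥ 0.05), `*`
(p < 0.05), `***` (p < 0.001); no intermediate tier is defined, and no
multiple-testing correction is applied (documented, matching the source
analysis style). With three replicates per group the test has 4 degrees
of freedom; the power claims verified in the tests refer to a 6.25-fold
effect under 10% CV, where power is essentially 1.

## NMR intensity ratios

For a perturbed condition with per-residue intensities $I$ and a reference
condition $I_0$ (VAMP2(1--96), residues 1--96):

$$Y(X) = \frac{I(X)/I_0(X)}{I(5)/I_0(5)}, \qquad Z(X) = \frac{Y(X) - Y_0(X)}{Y_0(X)}$$

Normalization by the highly flexible residue 5 (configurable) removes
spectrometer-gain differences, so $Y$ is invariant to uniform scaling of
either condition and $Y(5) = 1$ whenever defined. Unassignable residues
(prolines, T27, S61) are MISSING (`NA`) — distinct from an intensity of 0:
a peak that *disappeared* in the perturbed condition ($I = 0$, $I_0 > 0$)
gets $Y = 0$ plus an explicit `disappeared` flag, because disappearance
means maximal attenuation (membrane binding), not absence of information.
$Z$ is defined only where both profiles are defined and the control $Y_0$
is nonzero; in particular residues that disappeared in both conditions
yield `NA`, preserving both possible readings of such residues. Regional
summaries over half-open residue intervals (P-rich N-terminus [1, 29),
SNARE motif [29, 78), juxta-membrane [78, 97)) ignore MISSING residues and
report defined counts; an empty region summarizes to `NA`, not an error.
No noise-floor thresholding of raw intensities is applied by default.

## The synthetic-data generator

The generator produces everything the pipeline consumes, with ground
truth. It emulates:

* a spectral library over the 12 subclasses with masses from a per-subclass
  base + 14.01565 Da per CH2 − 2.01565 Da per double bond model (anchored
  to reference species masses), one adduct per subclass, fragments made of
  a subclass-diagnostic ion, a precursor-derived neutral loss and per-acyl
  ions with seeded intensities (fragments closer than the match tolerance
  are merged so every library spectrum has distinct fragment m/z), and a
  predicted RT that is linear in carbons (+0.15 min/C) and double bonds
  (−0.35 min/C=C) — the equivalent-carbon-number structure real RT
  predictors exhibit;
* a two-group experiment with 3 biological replicates per group. Non-raft
  subclass mole fractions are built in (SM at 0.12 mol%, cholesterol and
  PC dominant); raft fractions multiply them by configured mol%-ratio
  effects (SM 6.25, cholesterol 1.5, ceramide 2, acidic phospholipids
  depleted), with PC absorbing the compositional closure so the configured
  ratios of all other subclasses hold *exactly* — PC is the natural
  closure class, being the bulk, least group-discriminating one. The
  `chain_effect` and `saturation_effect` knobs are realized as
  within-subclass exponential abundance tilts per carbon and per double
  bond (renormalized within subclass, so subclass totals are untouched),
  because a literal shift of a discrete species grid's mean is
  ill-defined; the sign convention puts shorter, more saturated species
  in the raft;
* measurement noise: per-replicate log-normal area noise (σ = 0.1
  default, i.e. ~10% CV), Gaussian RT jitter (0.05 min), log-normal
  fragment-intensity noise (σ = 0.2) with two contaminant peaks per
  spectrum (only when fragment noise is on, so the zero-noise limit is
  exact), feature dropout (5%), 10 decoy library species and 10
  off-library unknown features (> 50 ppm from every precursor). These
  defaults are the package's realistic operating point; tests that need
  the exact zero-noise limit set them to 0 explicitly;
* internal standards spiked at the panel amounts, never dropped out
  (standards are high-abundance spiked knowns; losing one invalidates a
  whole subclass, which is a configuration error rather than a realistic
  event);
* NMR peak tables for solution, in-cell, cholesterol-up and
  cholesterol-down conditions, with region-wise attenuation (P-rich ≈ 1,
  SNARE motif 0.5, residues 78--96 disappeared) and the SNARE-motif
  attenuation scaled by ±30% in the cholesterol conditions. The
  unassignable-residue mask uses stand-in proline positions in the
  proline-rich N-terminus, not the real assignment gaps.

A single root seed derives fixed per-component streams (library +101,
truth amounts +211, responses +223, measurement noise +307, NMR +401,
calibration +503, unknowns +601), so varying a noise level never changes
the truth, and every artifact is bit-for-bit reproducible for equal seeds.
Per-feature noise draws are consumed in a fixed count regardless of
parameter values, keeping the streams aligned across configurations.

What the generator does **not** emulate — hence what passing tests do not
show about real data: chromatographic peak shapes and detection errors,
isotope envelopes and isotopic overlap between species, in-source
fragmentation, ionization suppression and non-unit response factors,
sn-position/double-bond-position isomers co-eluting at one mass, RT drift
between batches, and real fragmentation chemistry. Identification
performance on this synthetic data is therefore an upper bound for
real-world performance; the tests validate the *scoring and filtering
machinery*, not instrument realism.

## Numerical choices and degenerate inputs

* Strict inequalities at both thresholds (a score exactly at threshold is
  rejected), as stated by the acceptance contract.
* A spectral score with no matched library fragment, or an empty
  experimental weight vector, is 0; an empty reference spectrum is a
  validation error.
* Ties in the accepted-match choice break by |mass error|, then species
  id, so results never depend on library order.
* Text serialization uses 15 significant digits (`%g`), making write→read
  round trips exact to well below every tolerance used and reruns
  byte-identical.
* Identical groups in the t-test (zero variance in both, equal means)
  return t = 0, p = 1 rather than an error.
* An empty quantification table stops composition with a clear error; the
  pipeline driver writes an empty composition table and a summary instead
  of failing when a degenerate threshold accepts nothing.

## Problem sizes

The shipped tests and acceptance checks run on 5 species per subclass
(~56 analyte species, 68 library entries with standards), 2 × 3 samples
(~400 features per experiment), 1000 random spectrum pairs for the
oracle-equivalence check, 100 seeded replicate sets for the power check
and 400 null datasets for the type-I-rate check. These sizes keep the full
suite under a minute while leaving every statistical conclusion
comfortably powered; all of them scale through `sim_config()`.

## Known limitations

Single MS/MS spectrum per feature (how multiple data-dependent
acquisitions of one precursor should be merged is not specified here);
no target--decoy false-discovery-rate machinery (decoys exist in the
generator for stress-testing, not for FDR estimation); no isomer
resolution below the subclass/total-composition level; single-point
internal-standard quantification inherits the response-factor-1
assumption; and the adduct defaults are a declared configuration, not an
inference about any particular instrument's library.
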