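# lipidraft

Quantitative lipidomics and NMR ratio profiling for membrane
microdomain studies, in R.

Membrane lipid rafts — cholesterol- and sphingomyelin-enriched
microdomains — reshape how peripheral proteins such as the SNARE protein
VAMP2 engage the bilayer. Characterizing them quantitatively requires
(i) identifying and absolutely quantifying the lipid molecular species of
raft and non-raft membrane fractions from LC-MS/MS data, and
(ii) reading out protein–membrane association residue by residue from
NMR crosspeak intensities. `lipidraft` implements that computational
chain, downstream of peak detection, for analysts working with
feature-table exports (e.g. from XCMS) and an in-silico spectral library.

## What it computes

**Identification.** Features are matched to library entries by accurate
precursor mass (default ±10 ppm), then scored with a weighted *reverse*
dot-product MS/MS similarity over the library fragments

```
S = Σₖ (I_D^n mz_D^m)(I_E^n mz_E^m) / sqrt( Σₖ(I_D^n mz_D^m)² · Σₖ(I_E^n mz_E^m)² )
```

with m = 1 and n = 0.6 (positive mode) or 1 (negative mode), and a
trapezoidal retention-time similarity (plateau 0.15 min, zero at
0.5 min). Identifications need spectral score > 0.8 and RT score > 0.5;
at most one is accepted per feature, and every scored candidate is kept
for audit.

**Quantification.** Accepted species are converted to absolute amounts
(pmol, and pmol per µg protein) against per-subclass deuterated internal
standards (single-point, spiked panel), or an external calibration curve
with linear-range and dilution handling for cholesterol.

**Composition.** Species are aggregated to subclass mol% per sample,
chain-length/saturation profiles, and raft vs non-raft comparisons by
two-sided pooled-variance Student's t-test (`n.s.` / `*` / `***`).

**NMR ratios.** Per-residue `Y = [I(X)/I0(X)] / [I(5)/I0(5)]` profiles
(normalized to flexible residue 5) with explicit MISSING vs disappeared
handling, relative changes `Z = (Y − Y0)/Y0` between conditions, and
regional summaries over the VAMP2 domains.

**Synthetic data.** A seeded generator emulates the full study — spectral
library with decoys, two groups × 3 replicates with subclass/chain/
saturation effects, log-normal area noise, RT jitter, fragment noise,
dropout, spiked standards, calibration levels and NMR condition tables —
with joined ground truth, so every stage is testable offline.

## Worked example

```r
library(lipidraft)

cfg  <- sim_config(seed = 1)            # default (noisy) study conditions
libt <- generate_library(cfg)
sim  <- generate_experiment(libt, cfg)

ids <- identify_lipids(sim$features, libt$library)
evaluate_identifications(ids, sim$truth$features)
#> precision 1.000 recall 1.000 (390 accepted)

quant <- build_quant_table(ids, sim$features, sim$samples, libt$library)
comp  <- subclass_composition(quant)
grp   <- sim$samples$group[match(comp$sample_id, sim$samples$sample_id)]
compare_groups(comp[grp == "raft", ], comp[grp == "nonraft", ])
#>    subclass mean_a   sd_a mean_b   sd_b t_statistic  p_value significance_label
#> 2      Chol 44.940 1.1895 30.190 2.6206        8.88 8.90e-04                ***
#> 6        PC 26.460 0.7813 31.569 4.5644       -1.91 1.29e-01               n.s.
#> 10       PS  2.490 0.1741  5.596 0.5721       -9.00 8.45e-04                ***
#> 11       SM  0.689 0.0378  0.121 0.0249       21.71 2.66e-05                ***
```

Mean mol% per group (`mean_a` raft, `mean_b` non-raft): cholesterol and
sphingomyelin come out raft-enriched and the acidic phospholipid PS
non-raft-enriched — the directions built into the generator's effect
table — while PC, the bulk class, does not separate. Under the default
10% area noise all 390 detected features are identified correctly.

```r
nmr  <- generate_nmr_profiles(cfg)
prof <- relative_intensity_profile(nmr$tables$cell, nmr$tables$solution)
region_summary(prof)
#>        region mean min n_defined
#> 1   p_rich_nt  1.0 1.0        20
#> 2 snare_motif  0.5 0.5        47
#> 3         jmd  0.0 0.0        19
```

The in-cell profile reads: proline-rich N-terminus unattenuated (Y = 1,
no membrane contact), SNARE motif attenuated to 0.5 (transient binding),
juxta-membrane residues fully disappeared (Y = 0, tight association).

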