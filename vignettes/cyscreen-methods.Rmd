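---
title: "cyscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cyscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyscreen)
```

## The measurement model

Competitive cysteine chemoproteomics quantifies, for every probe-labeled
cysteine peptide, an MS1 intensity in a heavy (vehicle-treated) and a light
(compound-treated) channel. Both channels of a pair share one peptide row;
the competition readout is the log ratio

$$R = \log_2\!\frac{I_H}{I_L}.$$

A compound that covalently engages a cysteine blocks the pan-reactive probe
there, depletes the light channel, and drives $R$ up. $R \approx 0$ means no
engagement; $R < 0$ ("anti-ligandable") means the compound *increased* probe
labeling, usually concurrent with engagement elsewhere on the same protein.

The unit of reporting is the cysteine residue on the protein (UniProt,
1-based) coordinate frame, written `ACC_C<pos>`. Peptides containing several
cysteines without a localized modification are reported as
`ACC_C#_C#` and flagged ambiguous — they are called normally but marked in
reports, since the modification cannot be attributed to one residue.

## Pipeline stages and the parameters that matter

1. **Channel classification** (`assign_channel`). A PSM is probe-labeled when
   a cysteine modification delta matches the scheme's light or heavy label
   mass within `match_tolerance` (default 0.01 Da — upstream searches run at
   ~20 ppm, which is ≈0.01 Da at these ~500 Da label masses; an absolute
   tolerance is simpler at the delta level). Preset schemes: biotin azide
   463.2366/469.2742, isoTOP-TEV 521.3074/527.3213, sCIP 493.3007/499.3145,
   carbamidomethyl 57.02146 (all Da).
2. **Mapping** (`map_psms`). Exact substring matching of the peptide within
   its search-assigned protein (I/L distinct — this is not a homology
   search). Peptides matching more than one offset in their protein are
   excluded and tallied: their residue numbers would be ambiguous. This is a
   conservative choice we made, not a rule inherited from any upstream
   convention; the exclusion is visible in the mapping report. Peptides
   shared across proteins are trusted to the accession the search assigned
   (protein inference is upstream's job).
3. **Quantification** (`quantify_sites`). PSM ratios are capped into
   `[1/cap, cap]` with `cap = 20` (log2 ≈ 4.32) before logging: complete
   competition yields a zero light intensity and an otherwise infinite
   ratio; 20 is the customary cap in competitive isoTOP-ABPP work and is a
   parameter. Site × condition × replicate summaries use the **median** of
   PSM ratios (robust to outlier PSMs; `mean` available). Aggregation is
   PSM→site directly rather than PSM→peptide→site; site-level reporting is
   the target quantity.
4. **Replicate merging** (`merge_replicates`). A site × condition needs
   ratios in at least `required_replicates = 2` replicates ("both
   replicates"); otherwise it is unquantified. SD is the sample (n−1)
   estimator, consistent with using "SD" as a two-replicate spread gate.
5. **Calling** (`call_sites`). Liganded iff `mean >= 2` and (SD `<= 2` or
   every replicate `>= 2`). The field states two filtering criteria — a mean
   ratio threshold, and a both-replicates requirement when the SD exceeds
   2 — and we compose them with the mean threshold as the primary criterion
   and the both-replicates clause as an additional filter that activates
   only above the SD gate. Both clauses are independently configurable.
   Anti-ligandable mirrors the rule at −2; the literature describes
   anti-ligandability qualitatively without a cutoff, so the mirrored
   threshold is our default, not a community constant.
6. **Screen analytics**. Per-compound liganded fractions; screen totals with
   promiscuous compounds (e.g. SO56/SO59-like scaffolds) excluded from the
   ligandable total while still reported per compound; reference-database
   categorisation into known-ligandable / known-identified-only / novel;
   per-condition hit rates against the reference; dose-response matrices
   keyed by the condition grammar `name@<conc><unit>` (dose points are
   separate screen conditions).
7. **Stereoselectivity** (`stereo_compare`). Per shared site, the difference
   of mean log2 ratios between two conditions and a two-sample
   unequal-variance (Welch) t-test over replicate ratios. Selectivity
   defaults `|delta| >= 1`, `p < 0.05`, raw p-values; Benjamini–Hochberg
   adjustment is available but off by default since screen-scale volcano
   analyses of this kind conventionally report raw p-values. With two
   replicates per side the test has ~2 degrees of freedom; treat p-values as
   a ranking device, not calibrated error control.

## Numerical conventions and degenerate inputs

- Report rendering: log2 ratios at 4 decimals, missing ratio cells `"N.D."`.
- Even-sized PSM groups take the midpoint of the two central ratios; the
  `capped` flag follows the median-selecting values only.
- Zero-variance t-tests: identical samples give p = 1 (no evidence);
  separated constant samples give p = 0 (the limit of perfect separation).
- Rows with both intensities zero/missing are unquantified and rejected at
  read time, counted in the load report.
- Sites quantified in a single replicate keep their mean (defined from one
  replicate on) but are called unquantified under the default
  two-replicate requirement.

## The calling rule is not single-replicate monotone

Raising one replicate of a liganded site can flip it to not-liganded:
(2.5, 1.6) is liganded (mean 2.05, SD 0.64), but (7.5, 1.6) is not — the SD
now exceeds the gate and one replicate is below threshold. This is a real
property of the published two-clause rule, not an implementation artifact.
The rule *is* monotone under a common shift of all replicates, and under any
single-replicate raise that keeps the SD within the gate; the property tests
assert exactly those forms.

## What the synthetic generator emulates — and does not

`generate_screen` produces, for every mappable cysteine peptide × condition ×
replicate: a PSM count ~ Uniform{1..3}, per-PSM dropout with probability
0.10, an observed ratio `true_effect + N(0, 0.30)`, and intensities
`heavy = A`, `light = A · 2^(−observed)` with `A ~ LogNormal(ln 10^6, 1)`.
Background site effects are `N(0, 0.25)` per site × condition; planted
effects override them. Defaults were chosen once as a realistic stated
world: replicate scatter of ~0.3 log2 units and ~10% missingness make the
both-replicate requirement bind occasionally, as in real duplicate screens;
they are not tuned to any test outcome.

Design choices worth knowing:

- **Keyed RNG streams.** Every random decision is seeded by a hash of
  (seed, purpose, peptide/site, condition, replicate), so adding a condition
  leaves existing draws untouched and outputs are byte-identical for a fixed
  configuration. PSM-level draws come sequentially from their group's
  stream.
- **Localization is per peptide, not per PSM.** A multi-cysteine peptide is
  localized (probability 0.5, a generator convention — upstream localization
  rates are not published) once, by keyed RNG; all its PSMs inherit the
  decision. This makes ground-truth site identifiers equal the pipeline's by
  construction, which the recovery tests rely on.
- **Multi-locus peptides are skipped** by the generator, mirroring the
  mapper's exclusion, so "no silent loss" is a well-posed invariant.
- The peptide mass window (500–5000 Da) is applied to the unmodified
  peptide; applying search-engine windows pre-modification is a simulator
  simplification.

Not emulated: spectra, retention time, FDR/decoy structure, protein
abundance differences between conditions, plate-position batch effects,
correlated missingness. A green recovery test therefore establishes that the
*computational* pipeline recovers planted competition effects under
realistic noise — it says nothing about search-engine behaviour, interference
or batch structure in real acquisitions.

## Recovery metrics

Sensitivity and false-positive rate in the parameter-recovery test are
computed over sites that pass the two-replicate quantification requirement:
a site that the missingness model removed from a replicate is unquantifiable
by the stated rule, not a miss of the calling machinery. The no-silent-loss
invariant separately guarantees that every ground-truth site with surviving
PSMs in ≥2 replicates reaches the quantified set.

## Known limitations

- Exact substring mapping cannot place peptides across isoforms or
  post-processed termini; such PSMs land in the `peptide-not-found` tally.
- Two-replicate Welch tests are underpowered; the stereoselectivity defaults
  (|delta| ≥ 1, p < 0.05) are package defaults, not community constants.
- The reference-database comparison is identifier-based; it inherits
  whatever residue-numbering convention the reference used.
- The generator draws residues i.i.d.; real proteomes have compositional
  structure (signal peptides, low-complexity regions) that affects digest
  statistics.
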