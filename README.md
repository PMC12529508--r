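# cyscreen

Downstream analysis for competitive cysteine chemoproteomic screens
(isoTOP-ABPP style), in R.

## The problem

Cysteine chemoproteomic screens treat proteome lysate with an electrophilic
compound (light channel) or vehicle/DMSO (heavy channel), cap remaining free
cysteines with a pan-reactive probe such as iodoacetamide alkyne, and
quantify probe-labeled tryptic peptides by MS1 heavy/light intensity. A
cysteine the compound engaged loses probe labeling in the light channel, so
its competition ratio

&nbsp;&nbsp;&nbsp;&nbsp;R = log2(H / L)

is large. The field calls a cysteine **ligandable** when `log2(H/L) >= 2`,
with two replicate-level filters: a site must be quantified in both
replicates, and when the replicate SD exceeds 2 each replicate must itself
clear the threshold. Negative ratios mark **anti-ligandable** cysteines
(compound-induced increase in probe labeling, typically concurrent with a
liganding event elsewhere on the protein).

`cyscreen` implements everything downstream of the database search for a
96-well-style screen:

- **IO** — proteome FASTA, labeled-PSM TSV tables (with a column map for
  search-engine exports), reference site databases, all report TSVs.
- **Site mapping** — peptide-to-protein alignment and residue identifiers
  `ACC_C<pos>` (multi-cysteine peptides render `ACC_C#_C#` unless the search
  localized the modification); isotope-channel classification from the
  modification mass for three reagent chemistries (heavy/light biotin azide,
  TEV-cleavable isoTOP tags, sCIP tags).
- **Quantification** — capped PSM-level log2(H/L) ratios, median aggregation
  per site × condition × replicate, replicate merging with sample SD.
- **Ligandability** — the two-clause calling rule, per-compound reactivity,
  promiscuous-compound exclusion from screen totals, reference-database
  categorisation (known-ligandable / known-identified-only / novel), hit-rate
  analysis, stereoselectivity comparison (Welch t-test on replicate ratios),
  dose-response matrices.
- **Synthetic data** — a generator producing proteome + labeled-PSM tables +
  ground truth with planted per-site effects, so the whole pipeline is
  testable without raw MS data.

## Worked example

```r
library(cyscreen)

# a synthetic 20-protein screen, two compounds, effects of 3 planted on 10%
# of cysteine sites
cfg      <- sim_config(seed = 7, n_proteins = 20, conditions = c("KB2", "KB7"))
proteome <- generate_proteome(cfg)
planted  <- plant_effects(proteome, cfg, fraction = 0.10, effect = 3)
cfg      <- sim_config(seed = 7, n_proteins = 20,
                       conditions = c("KB2", "KB7"), planted = planted)
screen   <- generate_screen(proteome, cfg)

# analysis: map -> quantify -> merge -> call
mapped <- map_psms(screen$psms, proteome, label_scheme("biotin-azide"))
called <- call_sites(merge_replicates(quantify_sites(mapped)), call_config())

head(called[call == "liganded",
            .(site, condition, mean_log2, sd_log2, call)], 4)
#>            site condition mean_log2    sd_log2     call
#> 1: SYN0001_C162       KB2  3.203147 0.02614735 liganded
#> 2: SYN0001_C162       KB7  2.921649 0.19591438 liganded
#> 3: SYN0001_C340       KB2  2.974837 0.16098204 liganded
#> 4: SYN0001_C340       KB7  2.862832 0.09691425 liganded

summarize_compound(called)
#>    condition n_identified n_liganded n_anti_liganded fraction_liganded ...
#> 1:       KB2           99         10               0         0.1010101
#> 2:       KB7          100         10               0         0.1000000

screen_totals(called)
#> $n_unique_sites    103
#> $n_unique_proteins  19
#> $n_liganded_total   10
```

The planted sites (`SYN0001_C162`, `SYN0001_C340`, ...) come back with mean
ratios near the planted effect of 3 and are called liganded; the 10 liganded
sites in the totals are exactly the planted ones recovered across either
compound.

A command-line wrapper covers the same flow
(`inst/exec/cyscreen simulate|run|report`, flat `key: value` config — see
`inst/extdata/example_screen.cfg`).

## Documentation

The methods vignette (`vignettes/cyscreen-methods.Rmd`) describes the model,
the calling rule and its edge cases, what the synthetic generator does and
does not emulate, numerical conventions (ratio cap, median aggregation,
rounding), and known limitations.
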