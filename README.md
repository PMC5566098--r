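# forcensr

Curation tools for planktonic foraminifera census counts from surface
sediment samples: taxonomic harmonisation, metadata standardisation,
count quality control and duplicate-record removal across overlapping
compilations, producing a flag-annotated, audit-logged synthesis in the
ForCenS-style tab-delimited three-block layout.

The package is aimed at palaeoceanographers assembling or extending
assemblage calibration datasets, and at anyone who needs to merge legacy
census compilations (CLIMAP-methodology counts, >150 µm fraction) without
inflating them with disguised duplicates.

## What it implements

**Taxonomy.** A master scheme of 47 species, 3 multi-species and 6
morphotype categories; strict synonym resolution from a shipped table
(never fuzzy, never guessing); dataset-scoped merge rules (e.g. 'P/D
intergrades' → *N. incompta*, *G. flexuosa* → *G. menardii*,
*G. crassula* → 'unidentified'); unreported categories marked
not-available (`NA`), which is distinct from zero everywhere, including
on disk.

**Metadata and flags.** The 21 standard fields, uppercased names, metric
depths, a fixed device vocabulary, and three binary flags — `Error` (10
bits), `Database` (8 bits), `Ocean` (12 bits) — whose power-of-two values
make any combination a single integer (Database 7 = CLIMAP + BUFD +
ATL947, i.e. 1+2+4). Records are retained for analysis iff
`Error ≤ 1`.

**Count QC.** Relative data standardised to [0, 1]; stated totals
corrected against category sums; completion-by-zeros when 'unidentified'
is explicitly 0 and the category sum exceeds 1 − n·0.001/2 (the expected
rounding error of n categories at 0.1% granularity); renormalisation to
sum 1 unless |sum − 1| > 0.05 (flagged instead); exclusion filters for
counts < 150, unidentified > 5%, missing coordinates, non-standard
devices; basin endemism rules for *G. ruber* pink (Atlantic endemic) and
*G. conglomerata* / *G. hexagonus* / *G. adamsi* (Indopacific endemics):
flag above 1%, merge into 'unidentified' at or below 1%.

**Dereplication.** Basic faunal criteria for all duplicate types — max
per-category deviation < 1 percentage point over shared informative
categories, total-count deviation ≤ 3% of the pair mean — then sequential
classification: *plain* (same name, < 2.621 km), *incorrect position*
(same name, any distance), *different name* (< 0.5242 km). Distances are
haversine on a 6371 km sphere, which reproduces both printed thresholds
(the 0.5′ and 0.1′ equatorial pairs) to four significant figures.
Incorrect positions are repaired by re-interpreting decimal fractions as
untransformed minutes (accepted only if the repair moves a sample
> 3.7 km and brings the pair within 2.621 km), else by a pluggable
bathymetry cross-check. Merges keep the richest assemblage, the most
precise position, the most complete metadata, OR the provenance bits, and
leave discarded members in place flagged as duplicates. Remaining
faunally-similar pairs go to a manual review list; reviewer decisions are
consumed on a second pass.

**Synthetic corpora.** `generate_corpus()` builds multi-dataset corpora
with a ground-truth ledger — planted clones of all three duplicate types,
planted violations for every implemented Error bit, and
beyond-threshold negative controls — so the whole pipeline is testable
without downloading any archive.

## Worked example

```r
library(forcensr)

gen <- generate_corpus(corpus_config(n_datasets = 3,
                                     samples_per_dataset = 50, seed = 1))
run <- forcens_run(gen$datasets, scheme = gen$scheme,
                   bathymetry = synthetic_seafloor)
run
#> forcens_run: 150 records, 119 passing; 2 manual-review candidates
#>    step total included excluded duplicates plain position name
#>  CLIMAP    50       45        5         NA    NA       NA   NA
#>    BUFD   100       82       18          8     3        3    2
#>  ATL947   150      119       31          8     3        3    2
```

Reading the ledger: each step appends one dataset to the accumulated
corpus. After the third step the corpus holds 150 records of which 119
pass all selection criteria (`Error ≤ 1`); the `excluded` column counts
records carrying any exclusion bit — here the 5 planted quality
violations per dataset plus the 8 records per step merged away as
duplicates (3 plain, 3 incorrect-position, 2 different-name, matching the
generator's truth ledger). The two manual-review candidates are the
planted negative-control pairs with identical fauna but names and
distances beyond every automatic threshold — listed for a human, never
auto-merged. `export_run(run, "out/")` writes the full and passing-only
products, both ledgers, the candidate list and the audit log.

A thin CLI over the same functions ships in `inst/cli/curate.R`
(`synth`, `run`, `export` subcommands).

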