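---
title: "Curation methods: harmonisation, quality control and dereplication of foraminifera census counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcensr)
```

## The problem

Census counts of planktonic foraminifera in surface sediment samples are the
backbone of assemblage-based palaeoceanographic calibration. Decades of
counting by many groups produced several overlapping compilations, each
cloned in part from its predecessors, with three systematic defects:
inconsistent taxonomy (synonymy, lumping/splitting, undocumented species
lists), inconsistent metadata (units, device vocabularies, coordinate
conventions), and duplicated records whose names, positions and values have
drifted apart through rounding and transcription error. `forcensr`
implements a reproducible curation procedure that harmonises such sources
against a master taxonomy, standardises and flags their metadata, corrects
and quality-controls the count data, and dereplicates the merged corpus
under conservative similarity criteria — emitting a flag-annotated,
audit-logged synthesis in a tab-delimited three-block layout.

## Master taxonomy and synonym resolution

The master scheme holds 47 species categories, 3 multi-species categories
(historically lumped pairs such as *G. ruber* pink + white) and 6 morphotype
categories (e.g. *T. sacculifer* with/without sac-like chamber). Six of the
47 species have never been counted — four are too small for the >150 µm
fraction, two were described only in recent revisions — and are retained
with `recorded = FALSE` purely so output columns are stable. Morphotype
abundances are already contained in their parent species, so every
totalling, normalisation and similarity routine skips morphotype columns.

Synonymy is resolved strictly from a shipped table (`resolve_synonym()`
returns the sentinel `"unknown"` rather than guessing; fuzzy matching is
deliberately out of scope). Name normalisation case-folds, strips markup
and parentheses and collapses whitespace, but does not strip coiling
annotations — "sinistral"/"dextral" forms are explicit synonym rows with
different targets (*N. pachyderma* vs *N. incompta*), so generic stripping
would be destructive.

Dataset-scoped merge rules handle categories that exist only in particular
compilations: 'P/D intergrades' into *N. incompta*; *G. flexuosa* into
*G. menardii*; *G. crassula* and 'other identified' into 'unidentified';
*G. puncticulata* into *G. inflata*. One rule chains: in the CLIMAP
vocabulary 'G. pachyderma' denotes intergrade morphologies, so a
CLIMAP-scoped rule first relabels it 'P/D intergrades' before the general
rule fires; `apply_merge_rules()` iterates rules to a fixpoint. Rules are
matched against raw column labels *before* synonym resolution, otherwise
the global synonym *Globigerina pachyderma* → *N. pachyderma* would shadow
the dataset-scoped interpretation. Merges conserve the numeric abundance
sum exactly; merging a number into a not-available entry yields the number,
because not-available carries no information and is never treated as zero.

Categories a study did not report are marked not available (`NA`), never
zero: an unreported rare species was most likely absent, but the count
cannot assert it. The `NA`-versus-zero distinction is preserved through
every stage, including file round-trips (empty cell vs `"0"`).

## Metadata, flags, ocean basins

Metadata is standardised to 21 fields: names uppercased (capitalisation is
too inconsistent across sources to carry meaning), depths in metres with a
zero lower bound moved to the upper bound, the midpoint computed when both
bounds exist, devices mapped onto a fixed vocabulary (Piston, Gravity,
Trigger, Grab, Giant Box, Box, Multi, Mini, CTD; unmapped entries become
`"other"` and are caught by the device filter), and the minimum count
defaulted to the common standard of 300 individuals. 'Mini' is included in
the standard vocabulary because the device quality filter explicitly
whitelists it.

Three binary flags make every record's history queryable: `Error` (10 bits:
modified, outlier and dissolution placeholders, duplicate, taxonomically
incorrect, too many unidentified, deviating sum, too few counted,
non-standard device, no coordinates), `Database` (8 bits for the
constituent compilations) and `Ocean` (12 bits for basins and marginal
seas). Bits are powers of two so any combination is a single integer — a
`Database` value of 7 means presence in the first three compilations
(1+2+4). A record is retained for analysis iff `Error <= 1`, i.e. at most
the 'modified' bit.

Ocean assignment is a provider interface. The shipped fallback
(`basin_fallback()`) uses coarse rectangular boxes with no
shoreline-accurate boundaries; that is sufficient because only the
Atlantic+Mediterranean versus Pacific+Indian+Red Sea dichotomy feeds the
quality logic. Marginal seas do not set their parent-basin bits in the
fallback; a user-supplied gridded mask is free to use richer semantics.

## Count correction and quality filters

Relative data are standardised to the 0–1 range (percent tables are
detected by their row sums). For raw counts, a stated total that disagrees
with the category sum is replaced by the sum. Assuming a reporting
granularity of 0.1% per category, the expected total rounding error of a
sample with *n* given categories is *n*·0.001/2; when a study explicitly
reports 'unidentified' as zero and the category sum exceeds 1 minus that
error, the sample is taken to be complete and its not-available categories
are filled with zeros. Completion applies to relative-basis records only —
for raw counts the analogous inference is not described by the procedure
and is not taken.

Samples are then renormalised to sum exactly 1, unless the sum deviates
from 1 by more than 5% (bit 64, left untouched). Further filters: total
count below 150 (bit 128; relative-only records with no count information
pass, since the 300-individual default minimum implies a pass),
'unidentified' above 5% (bit 32), missing coordinates (bit 512),
non-standard device (bit 256; a missing device is conservatively flagged —
this is a deliberate choice where the procedure is silent, and it is
configurable in the sense that a device may be supplied). All threshold
comparisons are strict, exactly as stated ("below 150", "more than 5%",
">1%"). Filters accumulate by bitwise OR, so one record can be excluded for
several reasons at once and the by-reason ledger tallies may legitimately
exceed the excluded count.

The endemism rules reflect known biogeography: *G. ruber* pink is extinct
in the Indopacific since the last interglacial, while *G. conglomerata*,
*G. hexagonus* and *G. adamsi* are Indopacific endemics. Out-of-basin
abundances above 1% flag the record taxonomically incorrect (bit 16);
abundances at or below 1% are moved into 'unidentified' (mass-conserving;
the source category becomes not available); the lumped ruber pink+white
category in the Indopacific is resolved entirely into ruber white. The
wording of the source procedure flags ">1%" and merges "<1%", leaving
exactly 1% unaddressed; this implementation merges at exactly 1% so the
two branches partition the positive range. The endemism merge runs before
the unidentified filter, so a merged-in fraction can itself tip the 5%
criterion.

## Geodesy and the minutes-as-decimals repair

Distances are haversine on a sphere of radius 6371.0 km. That radius is
not negotiable here: the duplicate-detection distance limits of 2.621 km
(0.5′N 0.5′W to 0.5′S 0.5′E across the equator) and 0.5242 km (the 0.1′
analogue) are reproduced to four significant figures on this sphere and
not on the WGS84 ellipsoid, so the sphere is what defines the thresholds.

A recurring position corruption writes D degrees M minutes as the decimal
D.M. The repair reinterprets the fractional part as minutes
(D + f·100/60), is valid only when f·100 < 60, and extracts the fraction
after rounding at six decimals so binary float representation cannot
manufacture phantom minutes. For a sample pair all repair/keep
combinations of the four coordinates are enumerated, excluding
combinations with more than two repairs; a repair is accepted only if it
moves a sample by more than 3.7 km (the displacement of an
ill-transformation of at least 5 minutes at the equator — the 3.7 km
figure is used literally, not recomputed from 5′) *and* brings the pair
within 2.621 km.

## Dereplication

All duplicate types share the basic faunal criteria: maximum per-category
deviation of corrected relative abundances below 1 percentage point,
ignoring categories with no information in either record, and a total-count
deviation of at most 3% of the pair average (vacuous when either total is
unknown). Pairs passing these are classified sequentially, first match
winning: **plain** (identical name, distance < 2.621 km), **incorrect
position** (identical name, any distance), **different name**
(distance < 0.5242 km; no name-distance ceiling). Name identity is
Levenshtein distance zero on the uppercased names. Stages run strictly in
that order — the incorrect-position pass only sees pairs that survived the
plain pass — and clusters are the transitive closure of pairwise matches,
so three mutually similar same-name records merge once.

Merging maximises retained information: the assemblage with the most
numeric categories is carried; the position with the highest printed
precision wins (incorrect-position clusters first attempt the
minutes repair, then fall back to the bathymetry provider — the member
whose stated water depth best matches the provider depth at its position —
then to the older publication's position); the most complete sediment-depth
set wins; for all other metadata existence beats absence and conflicts
resolve to the older publication. The `Database` flag of the merged record
is the bitwise OR over members, so provenance is never lost; discarded
members remain in the corpus with the duplicate bit (value 8) and a
comment naming the merged record. Ties anywhere (category counts,
precision, equal or missing years) break to the lexicographically smaller
sample id, making the whole procedure deterministic and
order-of-input-invariant.

Datasets are dereplicated individually first, then folded sequentially in
their known order of cloning (CLIMAP, BUFD, ATL947, MARGO, additions by
default), with a per-step ledger of totals and stepwise duplicate counts
by type. After the automatic stages, remaining pairs satisfying only the
faunal criteria are emitted for manual review; nothing is auto-merged, and
a reviewer decisions table is consumed on a second pass (merges applied
with type `manual`).

## The synthetic corpus: what it emulates, and what it does not

Because the real constituent archives are external downloads, validation
uses `generate_corpus()`: 5 datasets × 200 samples, 15% overlap,
Dirichlet-distributed assemblages (concentration 0.3 over the 41
recordable species — chosen once to mimic the skewed dominance structure
of real assemblages), totals of 250–350 individuals, relative values at
the 0.1% granularity, clone total-count jitter within 1%, and position
jitter under half the relevant stage threshold. Planted clones carry the
three corruption modes (rounding + jitter; a latitude minutes-corruption
whose minute value is chosen so the displacement exceeds twice the plain
threshold and lands isolated from all other samples; a punctuation name
mutation within the different-name distance), and each is validated
against the same similarity predicate the detector uses. Planted QC
violations cover every implemented Error bit; negative controls exceed
each violated criterion by at least a factor of two.

Two constructions make ground truth exact rather than probable: base
positions sit on a jittered half-degree grid (tens of kilometres of
separation) and base names are unique, so no *unplanted* pair can satisfy
any automatic stage's criteria, whatever the faunal similarity. This is
the main idealisation: real compilations contain near-coincident distinct
stations, true replicates and technical replicates, so perfect recall and
zero false merges on the synthetic corpus demonstrate correctness of the
decision logic, not expected field performance. Other idealisations:
compositions are exchangeable across space (no species–environment
coupling), endemic-sensitive categories are zeroed outside violations, and
dissolution is not simulated. Outlier detection and dissolution screening
are likewise not implemented in the pipeline itself, mirroring the
procedure it reproduces; the corresponding Error bits (2 and 4) are
reserved placeholders.

Reference problem sizes used by the shipped validation: the end-to-end
checks run the 5 × 200 configuration (about a thousand records), smaller
unit fixtures are built in code. These sizes were chosen as the smallest
at which every stage (multi-step folding, all three duplicate types,
internal duplicates, every violation kind, negative controls) is exercised
with double-digit counts per cell.

## Numerical and format choices

* Exports are UTF-8 tab-delimited with two header rows (names, units), 21
  metadata columns and three abundance blocks (original, corrected
  absolute, corrected relative), each block ending with the six morphotype
  columns. The full variant keeps *every* record — excluded and merged-away
  ones included — so any processing state can be reconstituted from flags;
  the passing-only variant keeps `Error <= 1` records and the relative
  block.
* Not available is an empty cell; zero is `"0"`. Relative values are
  written at 6 decimal places, lossless at the 0.1% granularity the counts
  carry; coordinates are written at their recorded precision, which is
  re-derived from the text on reading, making write∘read∘write a byte-level
  fixed point.
* Renormalisation divides by the category sum, so retained samples sum to
  1 within 1e-9; merges and endemism moves conserve mass within 1e-12.
* Every value-altering operation sets the modified bit, appends to the
  record comment and writes an audit entry (sample id, stage, field,
  before, after); reproduction of outputs is guaranteed by determinism of
  the whole pipeline (identical inputs give byte-identical exports) rather
  than by replaying the log.

## A small worked run

```{r example, eval = FALSE}
gen <- generate_corpus(corpus_config(n_datasets = 3,
                                     samples_per_dataset = 50, seed = 1))
run <- forcens_run(gen$datasets, scheme = gen$scheme,
                   bathymetry = synthetic_seafloor)
run$step_ledger
```

## Known limitations

* The fallback basin provider is rectangle-coarse; records near basin
  boundaries can be mis-grouped, which matters only for the endemism rules.
  Supply a gridded mask provider for basin-accurate flags.
* Manual-stage duplicates (different name *and* distant position) are only
  listed, never auto-merged — by design, but it means recall on such cases
  is the reviewer's responsibility.
* The audit log records modifications but is not an executable replay
  script; recovery relies on the full export plus determinism.
* Synonym coverage is exactly the shipped table; extending a source with
  new vocabulary requires extending the table (unknown labels are kept raw
  and reported, never silently dropped).
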