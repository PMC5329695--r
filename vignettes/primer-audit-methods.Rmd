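---
title: "Methods: auditing 16S primers against central-pseudoknot pairing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing 16S primers against central-pseudoknot pairing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoprimer)
```

## The model

A PCR amplicon carries the primer's sequence, not the template's, over
both primer footprints. For most applications this is harmless; for
*functional* cloning of 16S rRNA genes it is not, because two variable
template positions sit inside the classic universal primer footprints:

* **position 19** (inside Bac8f, footprint 8–27), which base-pairs with
  **position 916** in helix h2 of the central pseudoknot. Gamma-like
  lineages carry 19A–916U, beta-like lineages 19C–916G.
* **position 1527** (inside UN1541r, footprint 1525–1541), variable C/U
  but probably not functionally coupled — it is modelled as a *lone*
  variable site.

A primer with a fixed base over position 19 converts half the templates
to a *non-native* pair. Growth-complementation experiments established
which pairs support ribosome function, and the package encodes exactly
that rule table (`classify_pair()`): A–U and C–G native functional, A–G
non-native functional, C–U non-native defective, everything else
`unknown`. The `unknown` outcome is deliberate: the table is an
experimental result, and combinations never assayed (e.g. G·U wobble)
are not extrapolated from RNA chemistry. Temperature-dependent severity
of the C–U defect is likewise out of computational scope; the classifier
is binary.

Everything else in the package exists to put that rule table to work on
arbitrary sequence collections: a coordinate frame (so "position 19"
means the same thing on every template), composition/coverage profiling
(to find which footprint positions are actually polymorphic in a given
collection), amplicon prediction (to turn a primer choice into predicted
pair-state changes), and library tabulation.

## Coordinate anchoring instead of multiple alignment

The original analysis used a multiple sequence alignment to place all
templates in *E. coli* numbering (1–1542). The only alignment products
the downstream analysis consumes, however, are per-column base counts in
that fixed frame and the states at a handful of positions. A pairwise
**semi-global alignment** of each template to a single reference
(Biostrings `pairwiseAlignment`, type `"overlap"`: free end gaps on both
sequences) reproduces these products without an external MSA binary, and
each template's map is independent of which other templates are present.

Scoring defaults are match +2, mismatch −3, gap open 5, gap extend 2 —
ordinary DNA alignment weights; nothing downstream is sensitive to the
exact values because templates are ≥ 94 % identical to the reference in
the regions that matter. Two guards flag a map *unanchorable*: a length
floor (200 nt, configurable) and an identity floor over the aligned span
(60 %). Unanchorable templates are excluded from profile depths and
coverage denominators but counted and reported (`n_total −
n_anchorable`); a `strict` mode counts them as uncovered instead.
Querying a position the template does not span returns an absent state
(`NA`), never an error.

One boundary case is worth knowing: when the extreme 5′ terminus is
heavily substituted (the hypervariable 1–7 run at 50 % per-position
substitution), an ends-free aligner may legitimately realign the first
few columns, because terminal gaps are free. The frame from position 8
onward — every position the audit reads — is still recovered exactly;
the test suite pins both behaviours.

## Primer placement

Primer placement is **gap-free**: primers anneal contiguously, and
footprints are treated as fixed-length windows. The placement search
scans every offset within a terminal window (default 100 nt; 5′ for
forward primers, 3′ for reverse primers, which are matched as their
reverse complement against the plus strand) and minimizes the
IUPAC-aware mismatch count, where two codes match iff their expansions
intersect and a template gap never matches. Degenerate primer positions
are therefore "free" wherever the template base falls inside the
expansion — the behaviour wobble positions are designed for.

Ties between equally good placements are broken deterministically:
first toward the placement whose mapped footprint equals the primer's
intended *E. coli* footprint, then toward the terminus. Mismatches are
counted uniformly along the primer; no position weighting is applied
because no annealing-efficiency model is available, but mismatch
positions are reported so downstream interpretation (5′-tolerant,
3′-critical) stays possible. The production scan is checked against an
independent exhaustive all-placements oracle on instances ≤ 300 nt, and
the alignment score against a brute-force affine-gap semi-global dynamic
program.

## Coverage and variable sites

"Covered" defaults to **zero** IUPAC-incompatible mismatches over the
full footprint — the strictest reading — with `max_mismatch` exposed
because no tolerance is canonical. Coverage is provably monotone in
`max_mismatch`, and per-group counts aggregate exactly to the overall
rate (both tested). An ambiguous template base (N) counts as a match
under intersection semantics; profiles tally ambiguity codes in their
own column so per-position counts always conserve.

Variable-site calls use the minor-allele frequency (1 − major-allele
fraction of unambiguous calls) with a default threshold of 0.05: the
two motivating polymorphisms (19 and 1527) are major splits, and the
threshold is configurable because none is stated anywhere. A primer's
verdict is `unsafe` iff its footprint overlaps a *registry* site
(h2 pair member or lone variable site) polymorphic at or above the
threshold — variability alone (e.g. the 1–7 run inside Bac1f) does not
make a primer unsafe, because those substitutions are not structurally
coupled.

## Amplicon prediction

`predict_amplicons()` overwrites both footprints with primer-imposed
bases. A degenerate primer position imposes nothing when the template
base is compatible; when incompatible, the lexicographically smallest
expansion member is imposed and flagged ambiguous — a deterministic
convention for a case real amplification does not reach. Pair states are
recomputed after substitution and the focus pair drives the risk flag;
prediction is idempotent (an amplicon re-predicted with the same primers
acquires no further substitutions), and a primer whose footprint avoids
every registry site can never change a pair state — both are tested
corpus-wide, including the headline property that the redesigned
Bac1f/UN1542r pair never alters any 19–916 state.

## Clone summaries

`summarize_clones()` accepts explicit 19/916 states or raw sequences;
sequence-derived states (via coordinate maps) win when both are present,
with a warning. Percentages are integers rounded **half-up**, which
reproduces the published origin percentages (52/61 → 85, 39/45 → 87,
29/44 → 66, 32/38 → 84, 25/45 → 56, 35/48 → 73). Two published
pattern percentages (48/61 printed as 78, 13/61 as 22) are inconsistent
with any consistent rounding rule (half-up gives 79/21); the package
treats the *counts* as authoritative and the acceptance machinery
compares counts, not those two percentages.

## The synthetic world

The generator (`generate_templates()`) states its world once:

| parameter | default | rationale |
|---|---|---|
| `freq_19A` | gamma-like 1.0, beta-like 0.0, other 0.5 | the class-defining states; "other" has no stated bias |
| `pair_consistency` | 1.0 | natural templates carry native pairs |
| `freq_1527_C` | 0.5 | the site is a major C/U split |
| `five_prime_variability` | 0.5 per position, 1–7 | the run is "highly variable" across bacteria |
| `core_mutation_rate` | 0.02 | typical interspecies 16S divergence scale |
| conserved blocks | 8–27, 916–918, 1525–1542 | primer sites and h2 partners are conserved |
| `flank_length` | 50 | the source dataset carried 50 nt flanks |
| `truncation_rate` | 0 (opt-in) | truncated deposits exist but are not the norm |

Truncation clips a template to an 80–190 nt terminal fragment, below the
anchoring length floor — emulating partial deposits that the real
pipeline would discard. Indels (opt-in) are confined to designated
variable-helix windows. Each run consumes a single seeded RNG stream and
restores the caller's stream afterwards; identical config + seed gives
byte-identical corpora. The packaged reference is *synthetic*: it
carries the real primer footprints, h2 partners and variable-site states
at the real coordinates, but arbitrary fixed bases elsewhere (the true
GenBank sequence is not bundled); any real reference FASTA can be
substituted.

What a green test does **not** establish: the generator has no
phylogenetic correlation structure, no chimeras, no sequencing error,
and conserves the primer sites perfectly outside the planted
polymorphisms — so coverage numbers on synthetic corpora are properties
of the stated world, not estimates for any real database snapshot.
Dataset-wide figures tied to a particular repository snapshot (e.g. a
"97 %" coverage claim) are deliberately not reproduced.

## Numerical and design choices

* Internal alphabet is DNA (T); U is accepted on input everywhere and
  shown on output only in pair-pattern labels (A–U). One convention
  avoids double bookkeeping between gene and rRNA notation.
* Coordinates are 1-based closed intervals on the plus strand.
* Non-focus h2 pairs (17–918, 18–917) are annotated geometrically
  (Watson–Crick / wobble / mispair) but never functionality-classified —
  only 19–916 was assayed.
* `classify_pair()` refuses ambiguous bases rather than guessing; the
  caller must expand them.
* Reverse-primer coverage of position 916 is structurally possible and
  handled generically, though no bundled primer reaches it.
* Degenerate-vs-union semantics for two-version primers (Bac8f(A)/(C)):
  both are supported — audit the degenerate merge or the two exact
  primers separately; the bundled set keeps them separate, as published.

## Limitations

* No thermodynamics: no Tm, ΔG, or position-weighted annealing model —
  mismatch counts only.
* The pair rule table covers four combinations; everything else is
  `unknown` by design.
* Pairwise anchoring assumes templates are 16S-like; wildly divergent
  inputs are flagged unanchorable rather than force-fitted.
* The single published C-version-library clone carrying an A–U pair has
  no modelled mechanism; it appears in summaries as data, not as a
  prediction.
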