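---
title: "Consensus disorder calling from X-ray missing residues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus disorder calling from X-ray missing residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrconsensus)
```

## The model

A deposited X-ray chain observes its construct's SEQRES positions in one of
two states: modeled (`O`) or missing (`M`, no coordinates — the
crystallographic signature of disorder or high flexibility). Mapping each
chain onto its full protein sequence through affine segments (the SIFTS
convention: 1-based inclusive intervals with equal spans on both axes)
yields, per protein, a stack of tracks over `{O, M, N}`, where `N` marks
positions outside the chain's crystallized construct. Each deposited chain
is one independent vote, even when several chains come from the same PDB
entry — an entry with four copies in the asymmetric unit contributes four
observations of the same construct under identical conditions, and treating
them separately lets within-entry disagreement (a genuinely informative
signal for flexible regions) enter the consensus.

Per position $i$, with $c_i$ covering chains ($\ne N$) and $m_i$ of them
missing:

* **majority rule**: $D$ if $m_i / c_i > 0.5$, $S$ otherwise, $U$ if
  $c_i = 0$. The threshold is strict: an exact 50/50 split is structured,
  because calling disorder requires a *majority* of the evidence.
* **zero rule**: $D$ only if $m_i = c_i$. Zero-rule $D$ positions are a
  subset of majority $D$ positions wherever coverage exists (all-missing
  implies more-than-half missing), a property the test suite checks on
  every generated dataset.

The per-position denominator is the number of *covering* chains, not all
chains of the protein: a construct that never contained a residue carries
no information about it, so uncovered positions are excluded and do not
affect either rule.

Regions are maximal runs of consecutive $D$. Both $S$ and $U$ break a run:
disorder cannot be asserted across sequence no construct ever covered, so a
region never bridges an unknown gap. This is a genuine modelling choice —
one could argue for bridging short gaps — but splitting is the conservative
option and keeps region coordinates verifiable against observations. Runs
of ≥ `ldr_min_len` (default 30) are long disordered regions (LDRs), runs of
`sdr_min_len`–29 (default 5) short ones (SDRs), shorter runs are noise and
are discarded. The 30-residue threshold separates functional long disorder
from loops missing for merely experimental reasons; the 5-residue floor
drops single-residue artifacts.

### Consensus difference

Subtracting the zero calls from a majority LDR isolates positions
disordered in most chains but ordered in at least one crystal — candidates
for fold-upon-binding or otherwise context-dependent behaviour. A majority
LDR is *confirmed* by the zero rule when a zero-consensus disordered run of
at least `ldr_min_len` lies inside its span; the package computes both
rules position-wise first and extracts regions through one shared code
path, so the confirmation logic cannot drift from the region definition.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `ldr_min_len` | 30 | residues | minimum LDR length |
| `sdr_min_len` | 5 | residues | minimum SDR length |
| `majority_fraction` | 0.5 (strict) | fraction | majority threshold |
| `tail_fraction` | 0.2 | fraction of L | N/C-tail span for localization |
| `fully_disordered_fraction` | 0.7 | fraction of L | fully-disordered call |

The fully-disordered threshold is applied inclusively (content ≥ 70%); the
boundary case is tested explicitly. Localization tails span
`ceiling(0.2 · L)` positions at each end; a non-full region touching both
tails is labelled by the tail holding the larger overlap, ties going
N-terminal — the deterministic rule matters only for regions spanning
nearly the whole protein. "Full" means covering every position; tolerating
a few structured terminal residues would blur the boundary between "full"
and "both tails", so it is not done.

## Ingest conventions

PDB parsing reads SEQRES for the construct sequence and REMARK 465 for
missing residues, first model only (the X-ray convention). REMARK 465
residue numbers are interpreted as SEQRES positions and validated against
the SEQRES residue name; records that cannot be resolved (insertion codes,
out-of-range or mismatched names) are dropped with a warning rather than
silently shifted, and an absent SEQRES is a hard error since the track
length would be undefined. Only unmodeled residues count as missing:
modeled residues with alternate conformations or zero occupancy still have
coordinates and are treated as observed. The mmCIF path reads
`_entity_poly_seq` plus `_pdbx_unobs_or_zero_occ_residues` (label
numbering preferred, auth accepted when label is absent; irreconcilable
numbering is a hard error naming the chain) and falls back to the
complement of `_atom_site` when the unobserved-residue category is absent.
Non-standard residues stay as SEQRES positions so region lengths always
match the deposited sequence.

## Downstream statistics

**Dataset accounting.** Disorder content is `missing / (missing + observed
[+ unknown])`; table percentages use half-up rounding to one decimal.
Category tables count regions under the majority rule (the zero rule gives
a region subset, and mixing rules in one table would double-count).

**Predictor evaluation.** Positives are consensus-$D$, negatives
consensus-$S$; $U$ positions are excluded from scoring. Counts are pooled
over all proteins before deriving metrics (micro-averaging), matching a
per-residue evaluation; macro-averaging would overweight short proteins.
Score-only predictions binarize at 0.5. Metrics with a zero denominator are
reported as 0 and flagged rather than dropped, keeping benchmark tables
rectangular.

**GO enrichment.** One-sided (greater) Fisher exact tests via the
hypergeometric tail; enrichment, not depletion, is the question being
asked. A term's level is the shortest `is_a` path from its namespace root
(roots at level 0), the common convention where several exist; "the upper
four levels" therefore means levels 1–4. Only `is_a` edges are used —
`part_of` crosses namespace boundaries and inflates propagation. The
Bonferroni multiplicity is the number of terms actually tested (annotating
at least one target) within each namespace, matching per-ontology
reporting; pooling namespaces would penalise small ontologies for the size
of large ones. Annotations are closed under ancestor propagation before
counting.

**Quality correlations.** Pearson r with a two-sided t-test on n−2 degrees
of freedom, pairwise deletion per metric, and an explicit `insufficient`
flag below three complete pairs. A structure's disorder fraction is the
mean of its chains' missing fractions — per-chain fractions are the
primitive, and an unweighted mean keeps one structure one unit regardless
of chain count.

## The synthetic generator

`sim_config()` / `generate_ensemble()` emulate the data-generating
situation the pipeline is built for: proteins composed of structured,
disordered and uncrystallized segments, observed by multiple independent
chains. Defaults, chosen once as a realistic benchmark condition: 50
proteins; half carry 1–2 LDRs of 30–80 residues (and 30% an extra SDR);
uncrystallized tails of 20–60 residues at each terminus with probability
0.5, emulating construct design and producing the substantial "unknown"
fraction real protein-level datasets show; 5 chains per protein; a
disordered residue is missing in a given chain with probability 0.9, a
structured one with 0.05 (crystallographic noise); constructs are trimmed
by up to 10 residues per terminus with probability 0.25. Structured gaps
between disordered segments are at least 30 residues so ground-truth
regions cannot merge. All sampling flows through per-protein substreams
derived from `(seed, protein index)`, so datasets are byte-stable under a
fixed seed and early proteins do not change when the ensemble grows.

Optional outputs couple to the same truth: predictor tracks flip the truth
with per-method false-negative/false-positive rates; quality records can
couple resolution and R-free linearly to a structure's disorder fraction
(`quality_coupling = 0` gives the null); annotations plant a level-2 GO
term into LDR-carrying proteins (p = 0.9) versus background (p = 0.05)
over a small built-in three-namespace ontology. Disordered segments are
drawn from a disorder-promoting amino-acid composition (enriched P, E, S,
K, Q, G; depleted W, C, I, F) so compositional analyses have signal.

What the generator does *not* emulate: correlated misses along the chain
(real disorder boundaries are fuzzy, not i.i.d. per residue), resolution-
dependent miss rates, inter-chain correlation within one crystal form,
non-terminal construct gaps in the default architecture (internal
uncrystallized segments are supported via explicit `segments` and produce
multi-segment mappings), and any geometry. Passing recovery tests
therefore shows the consensus arithmetic and plumbing are correct under the
stated noise model — not that real PDB data are this well behaved.

## Numerical and degenerate-input choices

Exact 50% votes are structured (strict majority). Zero-coverage positions
are `U` by definition, and `U` is equivalent to zero coverage — an
invariant, not a convention. Fisher p-values come from the hypergeometric
tail (`phyper`), exact for any table; the test suite pins them to an
independent enumeration of all tables with fixed margins at relative error
below 1e−10. Pearson p-values at |r| = 1 are 0 by convention (the t
statistic diverges). Empty region lists, empty histograms, zero-protein
summaries and zero-denominator metrics all return typed empty/zero results
rather than errors; a zero denominator in disorder content is an error
because no meaningful value exists.

Problem sizes in the tests and acceptance script — exhaustive consensus
enumeration over all vote patterns with ≤ 4 chains plus all whole stacks
with ≤ 8 cells (~16,000 stacks), 50-protein/15-chain recovery runs,
200-structure correlation simulations, 10,000-residue flip-rate checks —
were chosen as the smallest sizes at which the binomial/sampling error of
the quantity under test is comfortably below the asserted tolerance.

## Known limitations

* REMARK 465 entries with insertion codes or author numbering offset from
  SEQRES are dropped (with a warning), not reconciled via DBREF.
* The consensus never bridges unknown gaps; datasets with fragmented
  construct coverage will report split LDRs where a single biological
  region may exist.
* Whether SDR accounting should also be reported under the zero rule is a
  matter of taste; tables here count regions under the majority rule only.
* Enrichment supports Bonferroni only; FDR control is out of scope.
* The quality module consumes published validation metrics; it never
  recomputes them from coordinates.
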