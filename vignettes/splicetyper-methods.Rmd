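---
title: "Methods: detecting and typing alternative-splicing events from transcript structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and typing alternative-splicing events from transcript structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetyper)
```

## Scope and model

`splicetyper` compares observed transcript exon chains against a
reference gene annotation and emits typed alternative-splicing (AS)
events. The analysis is purely structural: it starts from coordinates
(an assembled/aligned transcript's exon chain), not from reads or
sequence. Read mapping, transcript assembly, sequence-level annotation
and expression quantification are upstream or out of scope.

All internal coordinates are 0-based half-open, so interval length is
`end - start` and adjacency/overlap tests need no off-by-one care;
GFF3/GTF readers and writers convert from/to the 1-based inclusive file
convention at the boundary and nowhere else.

An observed chain $O$ is compared against a reference isoform $R$ of the
same gene with three rules applied in precedence order:

* **Intron retention (IR).** An exon of $O$ strictly contains a whole
  intron of $R$ (and hence overlaps both flanking reference exons). One
  IR event per retained intron; the defining interval is the intron.
  Reference exons flanking a retained intron, and the merged observed
  exon, are excluded from the boundary comparison below — this
  precedence prevents an IR merge from also being scored as a spurious
  boundary event.
* **Exon skipping (ES).** A reference exon strictly inside the observed
  transcript span with zero overlap against every observed exon. The
  defining interval is the skipped reference exon. Reference exons
  *outside* the observed span are terminal truncation, not splicing, and
  are ignored.
* **Boundary events (AD / AA / AP).** Remaining exons are paired by
  maximal base overlap. Pairing is injective on reference exons: a
  reference exon claimed twice goes to the larger overlap (ties: the
  upstream observed exon), and the loser stays unmatched. For each
  matched pair the 5′ and 3′ boundaries are compared in transcript
  orientation (on the minus strand the genomic start is the 3′
  boundary). A pair sharing its 3′ boundary but differing at 5′ is an
  alternative donor site (AD); sharing 5′ and differing at 3′ is an
  alternative acceptor (AA); differing at both is an alternative
  position (AP). The defining interval is the observed exon.

Two masking rules express that transcript termini are not splice sites:
the genomic-start difference of a chain's first exon and the genomic-end
difference of its last exon are never compared (alternative
transcription start, alternative polyadenylation and assembly truncation
would otherwise masquerade as AD/AA/AP). The rule is genomically
symmetric, hence strand-independent.

### Donor/acceptor naming

The AD/AA naming above assigns AD to a 5′-side difference. The opposite
convention (donor = the 5′ splice site of the *intron*, so an exon 3′
difference) is also in circulation. The labelling is a configuration
switch, `end_convention`, defaulting to `"paper"` (5′-difference = AD);
`"conventional"` swaps the two labels and changes nothing else. Tests
pin the swap to be a pure relabelling.

Two coherent symmetry properties follow from strand-aware boundary
comparison, and both are tested: relabelling the same chains with the
opposite strand swaps AD and AA (the 5′/3′ roles of the genomic
boundaries exchange), while mirroring all coordinates *and* flipping the
strand is the identity in transcript orientation and preserves every
label.

### Reference isoform choice

Annotations carry multiple isoforms per gene, and an observed transcript
is not tagged with the isoform it derives from. The matched reference is
chosen by parsimony: the isoform minimising the event count, with ties
broken by fewer ES events, then by lexicographically smaller transcript
id. Both tie-breaks make the choice deterministic; the ES preference
encodes that a boundary re-interpretation is a smaller hypothesis than a
skipped exon.

### Conserved versus novel

An event is *conserved* when the alternative processing it describes is
already present among the gene's annotated isoforms: some isoform other
than the matched reference exhibits an event of the same type with
exactly equal defining-interval coordinates relative to that matched
reference. Anything else — including a single base of difference — is
*novel*. A single-isoform gene can never yield a conserved call.

A structural consequence of combining exact-coordinate conservation with
parsimony matching deserves note. If a gene has exactly two annotated
isoforms differing by one event, an observed chain that reproduces the
second isoform's processing at that site is, by construction, closer to
the second isoform and is matched *to* it — the would-be conserved event
is absorbed into the match and never emitted. Conserved calls therefore
require richer isoform structure (three or more isoforms, or multiple
differences between two), and with the two-isoform references the
simulator builds, end-to-end detection on simulated cohorts yields novel
events only. The conservation rule itself is exercised directly in unit
tests by classifying against an explicitly chosen reference isoform.

### Filters

Observed records with `coverage < min_coverage` (default 2) are excluded
before any comparison, dropping exactly the single-read alignments.
By default only genes annotated as AS — operationalised as "has ≥ 2
annotated isoforms" — are analysed (`restrict_to_annotated_AS = TRUE`);
transcripts of other genes are counted as skipped, not errored. The
alternative reading, a per-transcript AS flag in the annotation source,
is not available in plain GFF3 and is not implemented.

Within one variant, identical events (same gene, type and coordinates)
supported by several emissions of that variant count once; across
variants they remain distinct, so per-variant tallies and bins treat
each observed splice variant as the unit.

## The simulator and what it emulates

`simulation_config()` defaults define a cohort in the style of a
salinity-challenge gill transcriptome survey:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 120 | enough multi-isoform genes for a 500-variant cohort |
| `n_variants` | 500 | cohort size of the emulated survey's order (509) |
| `exons_per_gene` | 9–15 | room for several independent internal-exon events |
| `fraction_multi_isoform` | 0.5 | half the genes carry an annotated second isoform |
| `event_mix` | ES 51.8, AA 20.3, AD 12.0, AP 9.0, IR 6.9 | ES and IR weights follow the reported type shares; the remainder is split so AA is the second most frequent, as reported |
| `events_per_variant` | 1–4 | desk-scale stand-in for the reported 1 to ≥ 20 events per variant; capped by donor capacity |
| `coverage_model` | Poisson(λ = 30) | reported mean coverage of the low-coverage bulk is ~27; the distribution itself is unreported |
| `fraction_coverage_one_decoys` | 0.1 | exercises the single-read exclusion |
| `group_sharing` | 462:16:15:11:3:1:1 / 509 | the reported Venn partition of variants across CTRL/LS/RS |
| `prob_site_kil` | 0.5 | two sampling sites, no reported imbalance |

The reference generator gives every gene one isoform and a random half a
second isoform differing by exactly one randomly typed event — the
targets of the exact-coordinate conservation rule. Gene biotypes are
drawn with the reported protein-coding / pseudogene / non-coding split
(97.59 / 1.77 / 0.64%).

The cohort generator plants 0..k events per variant into the first
isoform. Planting inverts the detector's rules (ES removes an internal
exon; IR merges across an intron; AD/AA/AP shift internal boundaries by
1–10 bases, uniformly within the legal slack) under constraints that
keep the planted truth identifiable:

* targeted windows are ≥ 1 exon apart, so events never interact through
  pairing;
* terminal exon boundaries are never shifted and terminal exons never
  skipped, matching the detector's terminal masking;
* a double boundary shift must leave ≥ 1 base of overlap with the
  original exon, preserving the pairing anchor;
* the exons touching the gene's annotated isoform difference are not
  targeted at all, so planted events are independent of the annotated
  alternative processing and every planted event is novel (see the
  conservation note above); the per-event truth flag
  `planted_as_conserved` is accordingly `FALSE` throughout;
* non-decoy coverages are clamped to ≥ 2 — a "genuine" simulated variant
  is by definition one that survives the single-read filter, and decoys
  are forced to coverage 1 explicitly.

Each variant draws a Venn region from `group_sharing` and is emitted
once per treatment in that region; the emissions share a `variant_id`
attribute (transcript ids stay unique). Determinism: every simulator
function is a pure function of its config's single integer seed.

What the simulator does **not** emulate: read-level noise, assembly
artifacts, fuzzy splice-site calls, coverage-correlated error,
isoform-expression ratios, genuinely conserved events (above), or any
treatment-dependent event-rate shift — the group structure is sharing
only. Perfect recovery on simulated cohorts therefore demonstrates the
correctness of the interval logic and bookkeeping, not robustness to
noisy real-world structures, where upstream assembly quality dominates.

## Summaries

Percentages round half-away-from-zero at fixed decimals (2 for table
percentages, 1 for event-type shares, 0 for the novelty percentage);
this is the rule that reproduces the published-table arithmetic the
tests pin (e.g. 369/509 → 72.50). Group summary statistics use the
sample (n−1) standard deviation. Venn partitions are exact regions: a
variant labelled {LS, RS} counts in the LS∩RS-only region, and region
counts must sum to the number of labelled variants (asserted in tests on
random inputs). Cross-species sharing compares gene symbols
case-insensitively after trimming; the two-or-more-species percentage
uses the shared-with-any count as denominator, and a fully disjoint
input reports 0% with a warning rather than 0/0.

A variant is *novel* if any of its events is novel; only variants whose
events are all conserved count as conserved. This any-novel aggregation
is the conservative choice for calling a transcript a new arrangement.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ via the survival function (no normal approximation), with
term membership intersected with the background before sizing, a
minimum-overlap filter (default 4) applied *before* testing, BH
adjustment over the tested family, a p-value report cut-off (default
0.01) and a significance flag at q < 0.05. Filter-then-adjust makes the
BH family explicit and reproducible; it is recorded in the result's
`adjust_family` attribute. Only the over-representation direction is
tested. Because hypergeometric p-values are discrete, the test is
slightly conservative; in a well-populated regime (background 1000, term
sizes 150–300, query sizes 100–200) the empirical type-I rate at
α = 0.05 remains within 4σ of nominal over 1000 simulations, which the
acceptance suite checks.

## Numerical and engineering choices

* Exon chains are validated everywhere: non-empty, `start < end`,
  pairwise gap ≥ 1. Adjacent exons (gap 0) are illegal rather than
  silently merged.
* GFF3/GTF parsing is delegated to `rtracklayer`; parse errors are
  re-anchored to file line numbers by mapping feature order to
  non-comment lines. Writers are hand-formatted so reruns are
  byte-identical (no timestamp headers), which the determinism tests
  require.
* Event application (`apply_event`) is the inverse of classification and
  doubles as the reconstruction operator: a callset's events applied to
  the matched reference isoform must rebuild the observed chain exactly,
  a round-trip asserted for every variant in the test cohorts.
* Ties everywhere resolve deterministically (smaller genomic start,
  upstream exon, lexicographic transcript id), so outputs are stable
  across platforms.
* Degenerate inputs have defined behaviour: empty observed sets filter
  to empty callsets; a callset without events errors on type frequencies
  (no denominator) but summarises as zero variants elsewhere; an empty
  Venn label set and a query outside its background are errors.

## Problem sizes

The test and acceptance suites run at desk scale, chosen so the full
suite completes in about a minute: 500-variant cohorts over 120 genes
for recovery, an exhaustive single-event enumeration plus 300 seeded
multi-event chains for oracle equivalence, all hypergeometric parameter
combinations up to N = 12 against full draw enumeration, and 1000
simulations for null calibration. The headline cohort tallies of the
emulated survey (3,933 events in 509 variants) depend on unavailable
sequencing reads and are deliberately not simulation targets; the
printed-input arithmetic (group SDs, bin and sharing percentages) is
recomputed exactly instead.

## Known limitations

* Events are called per observed transcript against one chosen isoform;
  co-occurring events on one exon (e.g. an AP that is "AD + AA") are a
  single event, and mutually exclusive exons are not a separate type —
  they surface as ES pairs across variants.
* An observed exon absent from the reference (exon gain / novel exon)
  has no type in the five-class taxonomy and is deliberately not
  emitted; only reference-relative losses and boundary changes are.
* Conservation requires exact coordinates; near-miss conservation (± a
  few bases) is reported as novel by design.
* The annotated-AS restriction interprets "annotated as AS" as "≥ 2
  annotated isoforms"; transcripts of single-isoform genes are skipped
  under the default configuration.
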