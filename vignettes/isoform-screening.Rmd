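---
title: "Discriminating exon-skip isoforms by RT-PCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating exon-skip isoforms by RT-PCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopanel)
```

## The problem

Many genes express a family of splice variants that differ only by which
cassette exons are skipped. The human periostin gene (*POSTN*, 23 exons,
chromosome 13) is the motivating case: its eleven described variants
(Iso1–Iso11) all share exons 1–16 and differ only in which of exons 17, 18,
19 and 21 are removed. Which variants a given cell expresses matters —
individual isoforms behave differently in cancer invasion — yet short-read
or qPCR quantification cannot separate them, and full-length sequencing of
every sample is expensive. The classic bench answer is conventional RT-PCR:
a handful of primer pairs spanning the variable region, each producing
amplicons whose sizes depend on which cassette exons the template retains,
read out as band ladders on agarose gels.

`isopanel` turns that bench procedure into a computable model with five
parts:

1. **Gene model** (`exon_set()`, `build_isoform()`): an ordered exon
   catalogue and isoforms defined purely by skipped-exon sets, with the
   spliced transcript assembled by concatenation. Exon ids always follow
   the gene-level numbering (1..23 for POSTN) even in isoforms that skip
   exons; all coordinates are 1-based and inclusive.
2. **In-silico PCR** (`find_binding_sites()`, `predict_amplicons()`):
   primer matching on the *spliced* transcript, so a footprint straddling
   an exon–exon junction binds exactly when the fused sequence matches.
3. **Co-migration partitions** (`partition_by_size()`,
   `joint_partition()`, `select_panel()`): isoforms grouped into gel band
   classes per primer pair, combined across pairs by common refinement.
4. **Decoding** (`decode_bands()`): the screen run in reverse, from an
   observed band pattern to every isoform subset that could explain it.
5. **Specificity search** (`containing_isoforms()`,
   `design_discriminating_target()`): which isoforms contain a nucleotide
   or peptide target, and which k-mers are unique to one isoform among a
   co-expressed set — the isoform-specific siRNA and antibody-epitope
   problem.

## Amplicon prediction and its assumptions

A forward primer binds where its sequence matches the transcript; a
reverse primer binds where its reverse complement does. Matching is exact
by default (the screening primers are designed as perfect matches to the
reference); an optional mismatch allowance exists, but the final 5 nt at
the primer 3' end must always match exactly — polymerase extension is
intolerant of 3' mismatches, so this anchor is enforced even in relaxed
mode. Primers shorter than 15 nt trigger a warning rather than an error.

All (sense forward site, downstream antisense site) combinations with a
product of at least the two footprints and at most `max_product` (default
3000 bp) are reported. Multi-site binding is first-class: in the POSTN
panel the reverse complement of R1 overlaps the F2 binding locus
(`revcomp(R1)[2..21] == F2[1..20]`), so any logic assuming one site per
primer would be wrong from the start. Thermodynamics, secondary structure
and amplification efficiency are out of scope — the model predicts which
products *can* form and their exact spliced lengths, nothing about yield.

## The co-migration model

Two products look like one band when the gel cannot separate them. We
model this by single-linkage clustering of predicted sizes under a merge
tolerance with two presets:

* `"standard"` — 1.2% agarose; sizes merge when they differ by less than
  5% of the larger size;
* `"fine"` — 3.0% agarose; merge below 1.5%;

both with an absolute 4 bp floor. The gel percentages are the ones the
screening protocol actually uses; the merge fractions are engineering
estimates of what those gels resolve, deliberately exposed as
configuration rather than constants, since no resolution figures are
published. A plain numeric tolerance (absolute bp, merge at `diff <= t`)
is also accepted; `tolerance = 0` reduces classes to exact distinct sizes.

Single linkage is chosen deliberately although it is not transitive-safe:
a ladder of bands, each pair barely unresolvable, chains into one class,
which is how a smear reads on a gel. Isoforms with no product form their
own `"none"` class and never merge with sized bands. Running several
primer pairs together corresponds to the **common refinement** of their
partitions: two isoforms stay indistinguishable jointly iff they share a
band class under every pair.

Panel selection searches candidate pair subsets for the maximal joint
class count — exhaustively up to 12 candidates (smaller panels and earlier
candidates win ties), greedily beyond that. Residual non-singleton joint
classes are flagged `"gel-resolvable at high percentage"` when the fine
preset separates them, otherwise `"requires sequencing"`.

On the packaged POSTN model the three-pair screening panel (F1/R1, F1/R2,
F2/R2) yields 4, 5 and 2 band classes respectively and a joint partition
of 8 classes; the residual ambiguities {Iso3, Iso9}, {Iso5, Iso10} and
{Iso2, Iso11} each pair isoforms whose skip sets swap equal-length
cassettes, which no gel can separate — exactly the situation the bench
protocol resolves by sequencing gel-extracted products, and the decoder
therefore flags rather than guesses.

## Decoding band patterns

`decode_bands()` enumerates all subsets of the candidate universe (bounded
at 24 isoforms; the eleven-isoform POSTN lattice has 2048 subsets and
decodes in milliseconds after a one-off signature precomputation) and
keeps those whose predicted pattern matches the observation. Matching is
set equality under tolerance: each observed band is assigned to the
nearest predicted band class within tolerance, and the class sets must
agree — presence only, because gels do not report multiplicity. All
consistent subsets are returned ordered by size then lexicographically,
together with the inclusion-minimal ones (the parsimony calls). When
several minimal explanations exist they are interchangeable up to
co-migration and the result says so explicitly; the package never
silently picks one. A naive reference decoder (`oracle_decode()`, no
pruning, no caching, bounded at 12 isoforms) exists purely as an
independent cross-check in the test suite.

## Specificity search

Target containment is exact substring matching — on transcripts for
nucleotide targets (RNA input is normalized U→T) and on the translated
CDS for peptides, using the single reading frame of the full-length
reference; frame-shifting isoforms are excluded from peptide containment
with a warning. No seed-region rules or off-target thermodynamics are
modelled.

`design_discriminating_target()` reports every k-mer (default 21, the
classic siRNA duplex length) of the target isoform absent from all other
expressed isoforms. Skipping an exon removes sequence but also *creates*
a novel junction k-mer in the shorter isoform; both kinds of uniqueness
fall out of the same scan and are annotated (exons covered,
junction-spanning flag). On the POSTN model this reproduces both
directions: Iso5-vs-Iso3 candidates all touch exon 21 (including the
published exon-21 siRNA sequence), while Iso4-vs-Iso3 candidates all span
the exon 16|19 junction that only the additional skip creates.

## The idealized POSTN model

Reference exon lengths are not published in any form the package may
ship, so the default fixture is an **idealized** model, constructed
deterministically and labelled as such:

* 23 exons; cassettes 17, 18, 19 and 21 all 84 bp. Equal lengths are the
  weakest assumption consistent with the published band groupings, which
  merge isoforms whose skip sets differ only by *which* of 17/18/19 is
  missing; 84 is divisible by 3, so every skip combination preserves
  frame, as the protein-level evidence (C-terminally truncated but
  readable isoforms) requires.
* constitutive exons 201 bp (exon 1), 162 bp (exons 2–16), 99 bp (exon
  20), 150 bp (exon 22) and 240 bp (exon 23) — round, intron-free filler
  values giving a 3456 nt full-length transcript, close to the ~3.2 kb
  reference mRNA, and placing reference positions 2397–2417 (the
  pan-isoform siRNA site) inside constitutive exon 15 so the site is
  retained in all eleven isoforms.
* the published primer sequences embedded once each at their anchor
  sites: F1 in exon 16, the shared F2/R1 locus in exon 20, R2 in exon
  22. Anchors are implied by the published band groupings (products
  insensitive to exon-21 skipping under F1/R1 put R1 upstream of exon 21
  but downstream of exon 19, i.e. in exon 20) and verified by tests, not
  assumed.
* exon 21 carries a CDS segment encoding the published antibody epitope
  GHLFEDEEIKRLLQGC, with codons chosen so its EDEEIKR core is spelled by
  exactly the published exon-21 siRNA 21-mer.
* a CDS from position 1 (ATG) to a stop codon early in exon 22; all
  filler codons are drawn from the 61 sense codons so the frame runs
  uninterrupted through the variable region.
* filler sequence comes from a fixed internal seed, rejection-sampled
  until every embedded site is unique on the transcript — the fixture is
  byte-identical across builds and does not touch the caller's RNG.

With these choices the model reproduces the published screen exactly:
four F1/R1 bands with the published memberships, five F1/R2 bands, and
F2/R2 separating exon-21 retention. One published detail is *not*
reproducible under any consistent size model: the reported F1/R2
membership lists place Iso4 and Iso7 in one band although their products
must differ by a cassette length, and omit three isoforms; we treat the
five-band *count* as the reproducible quantity and document the
membership discrepancy rather than tuning lengths to mimic it. Likewise,
separating Iso3 from Iso9 on a 3.0% gel relies on real exons 17 and 18
differing slightly in length; with idealized equal-length cassettes those
classes are flagged `"requires sequencing"` instead.

A **reference** mode accepts true exon lengths and sequences from a local
cache built once by `scripts/fetch_reference.R` (network required); the
package never ships or downloads reference records at test time, and all
shipped checks run on the idealized model.

## What the synthetic generator does and does not emulate

`synth_gene()` builds seeded random cassette-exon genes with primer
anchor sites in the constitutive exons flanking (and, when present,
inside) the cassette span, rejection-sampling until the anchors are
unique. It emulates the *combinatorial* structure of a splice screen —
skip sets, junction creation, size arithmetic — which is what the
partition, decoder and specificity logic consume. It does not emulate
real exon length distributions, GC/codon structure beyond a GC fraction,
paralogous off-target loci, heteroduplex artefacts or band intensities;
green tests on synthetic genes therefore validate the combinatorics and
coordinate bookkeeping, not wet-lab primer performance.

## Numerical and degenerate-input choices

* Coordinates 1-based inclusive everywhere; the inclusive length of the
  published interval 2397–2417 is 21 nt, which pins the convention.
* Translation snaps a region to whole codons of the CDS frame with a
  warning; ambiguity codons render as `X`, stops as `*`.
* Class ordering is deterministic (ascending representative size, `"none"`
  last); joint classes order by the first input partition, then
  lexicographically; decoder output orders by subset size then name.
* Panel-selection ties prefer fewer pairs, then earlier candidates; the
  greedy path stops when no single addition refines the joint partition —
  at that point no set of additions can, so greedy and exhaustive agree
  whenever the pair budget is not binding (the test suite checks this on
  random candidate sets).
* Empty binding-site lists, `"none"` bands and the empty subset/pattern
  are ordinary values, not errors; a pattern matching *no* subset raises
  an error naming the likely causes (wrong universe, tolerance, or
  contamination).

## Problem sizes in the shipped checks

The test suite and acceptance script run entirely offline on the
idealized model: the full 2^11-subset decode round trip, 100
random-partition refinement cross-checks against a brute-force oracle,
200 decoder-vs-oracle draws on miniature synthetic genes, and
1000-position coordinate round trips per isoform. All of it completes in
well under a minute on one CPU.

## Known limitations

* Whole-exon skipping only — no intron retention, no alternative 5'/3'
  splice sites, matching the isoform catalogue's definition.
* Gel resolution is a two-parameter caricature; quantitative band
  intensity and mixture proportions are out of scope.
* Specificity is exact-match containment; siRNA efficacy, seed-region
  off-targets and epitope accessibility are not modelled.
* Exhaustive decoding is exponential in the universe size; it is bounded
  at 24 isoforms by design because splice-variant universes in this
  setting are tiny.
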