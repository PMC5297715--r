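---
title: "Methods: somatic filtering, indel impact and exome homozygosity mapping in spex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering, indel impact and exome homozygosity mapping in spex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spex)
```

`spex` models the downstream half of a small paired tumor–normal
whole-exome study: it starts from called and annotated variants and ends
at cohort-level statistics. This vignette records the models, the
parameters that matter, and the design decisions taken where more than
one reasonable implementation existed.

## The somatic filtering cascade

The tumor-specific variant set for a patient is defined by three
predicates applied in a fixed order:

1. **Matched-normal subtraction.** A tumor call is somatic when its
   identity tuple — by default `(chromosome, position, ref_allele,
   alt_allele)` — does not occur in the same patient's normal tissue.
   Matching is exact allele identity; no indel left-alignment or
   normalization is attempted, because normalization is the calling
   pipeline's responsibility and re-normalizing here could silently
   change identities the caller already fixed. Inputs are therefore
   assumed normalized consistently across the pair.
2. **Consequence filter.** Synonymous and non-coding records are
   removed (`drop_consequences`, settable).
3. **Population-frequency filter.** Records with a *known* population
   frequency strictly greater than `max_population_freq = 0.005` are
   removed. Two boundary decisions follow the rule's wording
   ("higher frequency (>0.5%)") literally: a frequency of exactly 0.5%
   is kept, and an unknown frequency is kept — a variant absent from
   dbSNP/1000 Genomes/HapMap is novel, which is evidence of rarity, not
   of commonness.

The three predicates are independent, so the final retained set does not
depend on their order; the order matters only for the removal
*attribution* in the `FilterReport`, where a record failing several
filters is counted at the first stage that removes it. This makes the
four report counts an exact partition of the input, a property asserted
in the report constructor itself.

## Indel functional categories

Indels are classified against a transcript model — ordered,
non-overlapping CDS intervals on one chromosome plus the canonical 2-bp
splice windows (the GT/AG dinucleotides) flanking each internal exon
boundary. Alleles are VCF-anchored: the shared prefix (at least the
first base) is an anchor, a deletion occupies positions
`position + k … position + |ref| − 1` and an insertion lands between
`position + k − 1` and the next base, where `k` is the common prefix
length.

Classification proceeds in precedence order:

* **Splice (SSD/SSA, High).** If the edited span intersects a donor
  (acceptor) window — for insertions, if the insertion point falls
  strictly inside the 2-bp window — the call is splice-site disruption,
  regardless of reading frame: losing a splice site compromises the
  transcript whether or not the local frame is preserved.
* **Frame shift (FS, High).** Otherwise, if the edit changes the coding
  length by an amount not divisible by 3.
* **In-frame (Moderate).** Reading-frame positions are accumulated
  across CDS intervals and are strand-aware: on the minus strand the
  frame is counted from the genomically-high end of the CDS. A deletion
  of whole codons aligned to the frame is CD; an insertion exactly at a
  codon boundary is CI; in-frame events that straddle a boundary also
  rewrite a flanking codon and are C&D / C&I. A deletion combined with
  an insertion (complex anchored allele) always rewrites flanking
  codons and is C&D or C&I by the sign of the net change.
* **Non-coding (Low).** Everything else.

The categories are validated two ways: hand-built transcripts covering
every category on both strands, and a sequence-level oracle that edits a
random genome string, re-splices the CDS by plain coordinate
arithmetic, translates before and after, and checks that FS coincides
with a frame change and that CD/CI produce a clean block
deletion/insertion at the protein level. An invariance property —
shifting an in-frame edit by whole codons within an exon preserves its
category — guards the frame bookkeeping.

The packaged indel table carries its printed categories verbatim (the
table publishes no coordinates or transcripts to re-derive them from);
`classify_indel` is exercised on synthetic transcripts instead.

## Exome homozygosity mapping

The mapping has three stages with the study's published constants as
defaults (`roh_params()`):

* **Marker calls.** With variant-allele fraction `f = variant_reads /
  depth`: homozygous iff `f ≥ 0.95` at depth ≥ 5×; heterozygous iff
  `0.30 ≤ f ≤ 0.70` at depth ≥ 10×; everything else — including the
  70–95% band — ambiguous. The map itself admits only autosomal sites
  with depth ≥ 20×, which makes the 5×/10× call floors vacuous under
  defaults; the floors stay implemented for non-default parameter sets.
  The threshold comparisons need no epsilon: fractions such as 19/20
  round to the same double as the literal 0.95.
* **Window scan.** Windows contain `window_markers = 500` markers (a
  marker-count window, not a base-pair window) and advance one marker at
  a time, never straddling a chromosome end. A window qualifies iff it
  holds at most `max_het_per_window = 2` heterozygous markers and no
  adjacent-marker gap inside it exceeds `max_gap_bp = 500` kb.
  Ambiguous markers occupy window slots and participate in the gap
  chain but never count as heterozygous: the call scheme defines them
  as a third class with no exclusion rule, and dropping them would
  silently stretch windows over uncalled territory. The production scan
  uses cumulative sums; `oracle_scan` re-checks every window by full
  iteration, and the two are asserted identical on constructed maps
  covering each disqualification structure and on seeded random maps up
  to 5,000 markers.
* **Coalescence.** Qualified windows whose marker ranges overlap or
  touch merge into maximal runs; merging never crosses a stretch not
  covered by any qualified window. A run is reported as a region
  spanning its first to last marker (1-based inclusive internally,
  0-based half-open on BED export) when it reaches `min_region_bp =
  1` Mb.

Two geometric consequences are worth stating because they govern what
the method can detect. First, a homozygous stretch is only detectable
when it contains at least `window_markers` markers — at the exome-like
5 kb mean spacing used in the simulations, a 500-marker window spans
about 2.5 Mb, so stretches shorter than that cannot host a qualified
window against a heterozygous background and are invisible at the
default window size. Second, against a dense heterozygous background
the reported region overshoots the true stretch by exactly the
heterozygote allowance: windows may absorb up to 2 flanking
heterozygous markers per side, so boundaries land 2 markers (~10 kb at
5 kb spacing, plus any ambiguous calls in between) outside the planted
span. The recovery tests assert exactly this envelope rather than a
fixed base-pair error.

Monotonicity properties — loosening `max_het_per_window` or
`max_gap_bp` never removes qualified windows, raising `min_region_bp`
never adds regions — are tested on seeded maps.

## Cohort statistics

Recurrence is the fraction of cohort patients carrying at least one
event in a gene; the denominator is the supplied patient table when
given, so patients without events still count. Gene symbols are
compared case-insensitively with markdown emphasis stripped, because the
source tables typeset symbols inconsistently.

The two-sided Fisher exact p is computed by full hypergeometric
enumeration: all tables with the observed margins are enumerated and
the probabilities of those no more likely than the observed table are
summed, using the conventional `(1 + 1e-7)` relative tolerance on the
"no more likely" comparison so that ties of equal probability are
included despite floating-point noise. The implementation is checked
against both an independent closed-form enumeration (log-factorial
arithmetic) over every 2×2 table with total ≤ 40 and
`stats::fisher.test` on random tables.

The study reports Fisher tests on per-patient SNP burden without
stating how the 2×2 table was built, so `fisher_group_test` offers two
labeled constructions — `median_dichotomy` (patients split at the
cohort median count, strictly above = high) and `pooled_events` (total
events vs patient counts per group) — and claims neither as the
published one. A degenerate table with an empty margin is an error, not
a p-value of 1: an empty margin means the comparison was ill-posed.

Network hub ranking drops edges with confidence `score ≤ min_score`
(strict, matching "score > 0.9"-style statements), computes degrees on
the undirected graph and breaks ties alphabetically. Interaction edges
and annotation clusters are user-supplied files; no web service is
queried.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions; the defaults are
the cohort the rest of the package is tested against:

* nine patients, 500 germline plus 50 somatic events each — an
  exome-scale rare-variant load after upstream quality filtering;
* consequence mix 15% non-coding, 25% synonymous, remainder functional;
  30% of variants common (frequency drawn above the 0.5% threshold),
  and 30% of rare variants novel (unknown frequency);
* one somatic driver-gene missense per patient with probability 1,
  emulating a universally mutated driver and giving downstream
  recurrence of 100%;
* marker maps with exponential inter-marker gaps of mean 5 kb, Poisson
  depth of mean 30×, and a true heterozygosity rate of 0.65 outside
  planted stretches — exome variant sites are roughly two-thirds
  heterozygous; inside a planted stretch every marker is homozygous.
  Reads follow `Binomial(depth, 1 − 0.01)` for homozygous truth
  (a 1% per-read error) and `Binomial(depth, 0.5)` for heterozygous.

Population frequency is assigned independently of germline/somatic
origin: database membership does not distinguish origin in real data,
and the choice keeps the frequency filter a live constraint on the
somatic truth set rather than a no-op.

One pseudo-random stream is seeded once per generator call and consumed
in a fixed order (positions, then zygosity, then depths, then reads),
so identical configurations produce byte-identical outputs and the
truth labels are exact. The generator does not model read-level
artifacts, alignment error, tumor purity or subclonality, linkage
disequilibrium, or non-uniform mutation rates along the genome —
passing its recovery tests therefore demonstrates the algorithms'
correctness under clean sampling noise, not robustness to the full
messiness of real exomes.

## Problem sizes and runtime choices

The test suite runs the window-scan/oracle equivalence on constructed
maps of 499–2,000 markers and on ten seeded random maps of ~5,000
markers (25 Mb at 5 kb spacing) at the default 500-marker window;
planted-stretch recovery uses 3 Mb plants in 12 Mb single-chromosome
genomes over multiple seeds, sized so a full window fits inside the
plant; the Fisher check enumerates every 2×2 table with total ≤ 40
(~10^5 tables). These sizes keep the full suite under a couple of
minutes on one core while still exercising the algorithms at the
study's own window geometry.

## Known limitations

* No somatic genotyping model: a tumor call absent from the normal is
  accepted without any minimum depth or allele-fraction requirement in
  the tumor, because the source analysis states none.
* Indel classification assumes anchored, normalized alleles and
  classifies edits that straddle a CDS boundary conservatively (C&D)
  rather than modeling exon-boundary rewriting.
* ROH mapping is marker-count based with no allele-frequency or LD
  model; it cannot distinguish autozygosity from deletion-driven loss
  of heterozygosity.
* The packaged study tables publish no genomic coordinates, so fixture
  positions are deterministic synthetic placeholders; analyses that
  depend on real coordinates (e.g. re-classifying the printed indels
  against real transcripts) are out of reach by construction.
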