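---
title: "Methods: miRNA-space quantification, QC filtering and tissue specificity"
author: "isomiRatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-space quantification, QC filtering and tissue specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRatlas)
```

## The problem

Small RNA-seq libraries contain, besides the database-canonical mature
miRNAs (Ref-miRs), large numbers of isomiRs: length and sequence variants
arising from imprecise Drosha/Dicer cleavage and post-transcriptional
modification. Building a multi-tissue expression atlas from heterogeneous
libraries therefore needs (i) a reference in which reads can be placed and
classified at isomiR resolution, (ii) an aggressive but auditable QC
cascade, (iii) a way to consolidate externally predicted novel hairpin
loci, and (iv) specificity and ranking statistics that are robust to
batch structure. `isomiRatlas` implements those four layers plus a
synthetic-data generator that provides ground truth for all of them.

## The miRNA-space model

The *miRNA-space* is the union of all known and predicted hairpin
precursor sequences. Quantification is by exact matching within this
space, never by genome alignment:

* Hairpins are extracted strand-aware from the genome, so every hairpin
  string reads 5'→3'; mature coordinates are hairpin-local, 0-based,
  half-open, counted from the hairpin 5' end. `GRanges` (1-based) is used
  at every genomic boundary, and GFF3/BED conversion is delegated to
  `rtracklayer`, so no hand-rolled coordinate arithmetic crosses a file
  boundary.
* Reads are matched **sense-only** within hairpins (mature miRNAs are
  single-stranded); both genome strands are scanned only when assessing
  *exclusivity*.
* `T` and `U` are equivalent on input; DNA letters are the internal
  alphabet.
* The occurrence index covers substrings of length 17–25, the same window
  as the read-length filter: shorter fragments are degradation products,
  longer ones other small RNA species, so nothing outside the window can
  ever need a lookup.

A sequence is tagged `exclusive` when every exact genomic occurrence (both
strands) lies within an annotated hairpin interval, `ambiguous` otherwise;
one or more bases of overlap with a declared repeat interval sets the
repeat flag. The repeat rule is ≥ 1 base because no minimum overlap is
biologically motivated for an exact-copy occurrence.

## Placement and isomiR classification

A read is placed wherever a prefix of length ≥ `length − maxNtTail`
matches a hairpin exactly; the remainder is a 3' non-templated tail. Two
conventions matter:

* **Templated preference (maximality).** A tail is only called when its
  first base differs from the hairpin continuation base. If the added
  base could be read from the template, the templated interpretation wins,
  and only longest-templated-prefix placements are reported. This makes
  tail calls unambiguous at the cost of never calling a non-templated
  addition that happens to match the template — such molecules are
  indistinguishable from templated extensions by sequence alone.
* **Default tail bound `maxNtTail = 3`.** Post-transcriptional 3'
  additions are dominated by mono-/di-uridylation and adenylation;
  three bases cover these with headroom, and the bound is configurable.

Relative to a mature reference, a placement is summarized by `d5` (read
start minus mature start; positive = 5' trim, negative = extension), `d3`
(templated 3' end minus mature end) and the tail length. The classes
partition exactly:

| class | condition |
|---|---|
| `canonical` | `d5 = 0, d3 = 0`, no tail |
| `iso_5p` | `d5 ≠ 0`, `d3 = 0`, no tail |
| `iso_3p` | `d5 = 0`, `d3 ≠ 0`, no tail |
| `iso_3p_nontemplated` | `d5 = 0`, tail present |
| `mixed` | `d5 ≠ 0` and any 3' change |

Any `d5 ≠ 0` shifts the seed (residues 2–8), so `seed_shifted = (d5 ≠ 0)`.
Polymorphic isomiRs (internal substitutions) are deliberately **not**
called: exact matching cannot distinguish a substitution from a distinct
locus, and the retained class taxonomy contains no polymorphic class.

A read is *assigned* to a mature when its templated interval overlaps the
mature interval by ≥ 1 base and `|d5| ≤ 5`, `|d3 + tail| ≤ 5`. The windows
are configurable; placed reads with no assignable mature are reported as
unassigned hairpin fragments and excluded from miRNA matrices, rather than
being forced onto the nearest mature. Reads placeable at several loci are
counted **once** per sample with the full parent list retained — origin
attribution by fractional splitting would claim information exact matching
does not have.

Sequence identifiers pack 2 bits per base (A=00, C=01, G=10, T=11,
big-endian), zero-pad to whole 5-bit symbols and render them in the
RFC 4648 base-32 alphabet as `iso-<length>-<code>`; the map is injective
and invertible, so the identifier *is* the sequence.

RPM normalization divides by the sample's total post-filtered,
length-selected read count (not by the placed subtotal), times 10^6.

## The QC cascade

Steps run in a fixed order with a before/after count recorded at each:
read length (17–25) → depth MAD filter → miRNA biotype fraction →
tissue minimum → feature expression → low-signal samples → missingness →
tissue minimum re-check. Boundary conventions follow the wording of each
rule exactly and are asserted in the tests:

* **Depth filter:** on `log2` post-filtered counts, fail when
  `y < median − 3 × MAD*` with `MAD* = 1.4826 × MAD` (the
  normal-consistency "unbiased" MAD; the raw MAD is available via
  `unbiased = FALSE`). One-sided: only low-depth outliers fail. Applied
  jointly across all samples by default; per-source application is a
  caller-side subset.
* **Biotype:** fail strictly below 10% miRNA-assigned reads; exactly 10%
  passes.
* **Feature expression:** keep a miRNA only with RPM **> 20** in ≥ 2
  samples (strict, the atlas retention rule). The screen for predicted
  hairpins uses **≥ 20** (`inclusive = TRUE`) — the two rules are worded
  differently at their sources and both wordings are honoured.
* **Low signal:** fail strictly below 10% non-zero features; **missingness**
  fails at ≥ 90% zeros. With few features these two are near-complements;
  they differ only at the exact 10%/90% boundary, which is why both exist.
* The tissue minimum (≥ 2 independent samples) is re-checked after
  sample-level drops, since removing samples can strand a tissue.

The cascade is idempotent and monotone (tightening any threshold never
enlarges the surviving set); both properties are tested.

## Novel-locus consolidation

Predicted hairpin loci arrive from an external predictor and are
consolidated, never re-predicted:

* **"Maximum overlap of 17"** is read as: overlaps of ≤ 17 bases are
  tolerated, sharing **more** than 17 bases (one full minimal mature
  sequence) merges two predictions — or removes a candidate against the
  known annotation. The inclusive alternative is exposed as a flag.
* Merging respects strand; removal against known hairpins is
  strand-agnostic by default (a known locus on either strand makes a
  co-located prediction suspect). Both are configurable.
* The representative of a merged group is the locus with the highest
  total count; exact ties are broken by a **seeded** uniform draw, and
  the seed is recorded in the report, making an otherwise irreproducible
  random choice reproducible.
* The multiplicity cap counts exact occurrences of the hairpin sequence
  on **both** genome strands and keeps ≤ 15.
* Ortholog naming keeps hits with q-value < 0.01 and query coverage
  > 80%, takes the highest percent identity, and resolves cross-species
  ties by an ordered species-priority list (default for an equine atlas:
  cow, sheep, pig, dog, human, mouse). "Evolutionarily closest" is a
  user-editable list because no tree is implied by the inputs. Candidates
  with no surviving hit keep their original predicted id.
* Upstream screening against non-miRNA RNA families is consumed as a
  boolean exclusion column, not recomputed.

Input order never changes the outcome: loci are canonically sorted before
grouping and tie-break seeds are derived per group.

## Organ-enrichment index

Tissues from the same organ (heart chambers, kidney regions, skin
sections, brain subregions) are pooled before scoring. The organ mean is
the **pooled sample mean** — every sample weighs equally — rather than a
mean of tissue means; the alternative only differs for unbalanced groups
and pooling matches the way the mean RPM is described. For miRNA $j$ over
$N$ organs with organ means $m_{j,i}$ and $x_{j,i} = m_{j,i} / \max_i
m_{j,i}$:

$$\mathrm{OEI}_j = \frac{\sum_{i=1}^{N} (1 - x_{j,i})}{N - 1}$$

so 0 is perfectly uniform and 1 single-organ. Only miRNAs with a mean
RPM > 20 in at least one organ are scored. Bands: < 0.15 ubiquitous,
> 0.85 tissue-specific, boundaries intermediate. Per-source scoring
(e.g. separate collections to avoid batch effects) is a grouping choice
by the caller, not hard-coded.

A property worth knowing: because of the max-normalization, the index of
a truly uniform miRNA is **positively biased** under sampling noise — the
maximum of $N$ noisy organ means exceeds the typical mean, so
$E[\mathrm{OEI}] \approx \frac{N}{N-1}\,(1 - E[m]/E[\max_i m_i]) > 0$.
With lognormal per-sample noise (CV 0.2) and 8 samples per organ over 10
organs this bias is ≈ 0.11, close to the 0.15 ubiquitous boundary, so a
tail of genuinely uniform miRNAs scores "intermediate". Tissue-specific
calls are essentially unaffected (a 20× dominant organ sits at 0.95
noiselessly). This is a property of the index itself, shared with the
tau-style indices it is modelled on, not of this implementation.

## Robust rank aggregation

Each sample contributes a full ranked miRNA list (descending RPM, ties
broken by id so lists are total orders; a truncation depth is available
but the default is full depth — with exact-match RPM values, truncation
only discards information). For an item ranked in $m$ lists with
normalized ranks $r_{(1)} \le \dots \le r_{(m)}$, each order statistic is
compared with its uniform null, $B_k = P(\mathrm{Beta}(k, m-k+1) \le
r_{(k)})$; the score is $\rho = \min_k B_k$ and the reported significance
is the Bonferroni bound $p = \min(1, m\rho)$ over the $m$ statistics
considered. Items absent from a list contribute no rank there (their $m$
is smaller) rather than an imputed worst rank. The p-values are
conservative by construction, which the tests confirm against the uniform
null, and $\rho$ is validated against Monte-Carlo order-statistic
frequencies.

## The synthetic-data generator

`makeReference()` plants 60–90 nt hairpins (each with one 20–23 nt mature,
≥ 5 nt of flank) in a random genome, on both strands; optional verbatim
copies at unannotated positions force `ambiguous` tags, and optional
repeat intervals cover chosen hairpins. Mature uniqueness is verified by a
brute-force both-strand scan before the bundle is emitted.
`simulateReads()` draws category-labelled reads (`d5 ∈ ±1..2`,
`d3 ∈ ±1..3`, tails of 1–3 nt over {A,T} chosen to mismatch the template;
draws leaving the 17–25 nt templated window are resampled and counted).
`simulateAtlas()` plants ubiquitous (equal organ means) and specific
(one organ at 20× background) miRNAs with mean-preserving lognormal noise.

Defaults are fixed once and express the emulated study conditions: 10
organs, **8 samples per tissue** (representative of a multi-source
tissue atlas, where a few hundred usable libraries spread over several
dozen tissue types), per-sample noise CV 0.2, dominance 20×,
ubiquitous base mean 200 RPM and specific background 25 RPM (comfortably
above the 20 RPM inclusion rule). Expression noise is lognormal and read
sampling multinomial — standard choices for RNA-seq magnitude data.

What the generator does **not** emulate: sequencing error (the upstream
pipeline error-corrects reads before quantification, so the engine's
contract assumes corrected reads), adapter artefacts, quality strings,
compositional biotype structure, or real tissue biology. Passing
round-trip tests therefore demonstrates correctness of placement,
classification, filtering and scoring logic — not robustness to raw
sequencer output.

## Numerical and degenerate-input choices

* All-equal depth vectors give `MAD* = 0` and nothing fails (no sample is
  below the median); all-zero miRNA rows are excluded from the index
  (maximum undefined) rather than scored.
* `rho` on a single list reduces to the normalized rank itself
  (Beta(1,1) is uniform).
* Exact count ties in representative selection and exact RPM ties in
  ranking are both broken deterministically (seeded draw; lexicographic
  id).
* Reads containing `N` are reported as unplaced with the reason
  `ambiguous_base`; identifier encoding refuses them.
* Test problem sizes: synthetic genomes of 15–50 kb with 6–12 hairpins,
  3,000–50,000 simulated reads, 200-replicate recovery simulations —
  sizes at which every oracle (naive scans, Monte-Carlo) is itself exact
  enough to arbitrate.

## Known limitations

* Exact matching cannot see polymorphic isomiRs or non-templated 5'
  additions; both are out of scope by design.
* A non-templated addition matching the template base is reported as
  templated (maximality); this undercounts tails by the fraction of
  additions that coincide with the template.
* The ubiquitous OEI band is noise-sensitive (see above); with few
  samples per organ, band membership for genuinely uniform miRNAs should
  be interpreted cautiously, or more samples pooled per organ.
* Overlapping hairpins are kept as separate space regions and all
  placements are reported; no attempt is made to decide whether they are
  one transcription unit.
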