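# isomiRatlas

Building a multi-tissue miRNA expression atlas from small RNA-seq means
more than counting canonical miRNAs: most expressed molecules are
**isomiRs** — 5'/3' length variants and 3' non-templated additions of a
reference mature miRNA (Ref-miR) — and heterogeneous public libraries
need aggressive, auditable quality control before any cross-tissue claim
can be made. `isomiRatlas` is an R package for scientists assembling such
atlases (in horse or any species). It provides:

* **miRNA-space references** — the union of known and predicted hairpin
  precursors, indexed for exact-match lookup, with sequences tagged
  *exclusive* (occurring only inside hairpins) or *ambiguous*, and
  flagged for repeat-element overlap;
* **isomiR classification and quantification** — exact sense-strand
  placement of collapsed reads, classification into `canonical`,
  `iso_5p`, `iso_3p`, `iso_3p_nontemplated` and `mixed` with offsets
  (`d5`, `d3`), non-templated tails, seed-shift flags (seed = residues
  2–8), invertible nucleotide-packed sequence identifiers, and
  reads-per-million (RPM) normalization;
* **a QC filter cascade** — read-length window 17–25 nt, a one-sided
  depth filter at 3 unbiased MADs (1.4826 × MAD) below the median log2
  count, a <10% miRNA-biotype filter, RPM > 20 in ≥ 2 samples feature
  retention, low-signal and missingness sample filters, and minimum two
  independent samples per tissue — with a per-step attrition report;
* **novel-locus consolidation** — merging predicted hairpins sharing
  > 17 bases, count-based representative selection with seeded
  tie-breaks, RPM ≥ 20 expression screening, removal against the known
  annotation, a ≤ 15 genomic-copies cap, and ortholog-based naming from
  BLAST-style hit tables (q < 0.01, coverage > 80%, closest species);
* **atlas statistics** — the organ-enrichment index
  `OEI_j = Σ_i (1 − x_{j,i}) / (N − 1)` with `x_{j,i}` the organ mean
  scaled by its maximum (0 = ubiquitous, 1 = single organ; bands at 0.15
  and 0.85), and robust rank aggregation of per-sample rankings via beta
  order statistics, `ρ = min_k P(Beta(k, m−k+1) ≤ r_(k))`,
  `p = min(1, mρ)`;
* **a synthetic-data generator** — random genomes with planted hairpins,
  duplicated and repeat-resident loci, category-labelled reads, and
  expression matrices with planted ubiquitous/tissue-specific miRNAs,
  giving every module a ground truth.

## Worked example

```r
library(isomiRatlas)

# a synthetic reference: 8 hairpins planted in a 20 kb genome
bundle <- makeReference(seed = 7, nHairpins = 8, genomeLen = 20000)
bundleSpace(bundle)
#> MiRNASpace with 8 hairpin(s) and 8 mature reference(s)
#>   genomic ranges on: chr1, chr2
#>   occurrence index: lengths [17, 25], 4185 distinct substrings

# simulate one sample's reads and quantify them
reads <- simulateReads(bundle, profile = c(canonical = 0.6, iso_5p = 0.1,
    iso_3p = 0.2, nt_tail = 0.1), nReads = 5000, seed = 8)
counts <- aggregate(count ~ sequence,
    data.frame(sequence = reads$sequence, count = 1L), sum)
q <- quantifySample(counts, bundleSpace(bundle), sampleTotal = 5000)
table(q$assignments$class)
#>           canonical              iso_3p iso_3p_nontemplated              iso_5p
#>                   8                  46                  83                  32
head(q$records[order(-q$records$count), c("uid", "count", "rpm", "parents")], 3)
#>                   uid count   rpm    parents
#> 87   iso-21-MUMPCJIKA   391 78200 syn-miR-01
#> 151  iso-21-7JTRDVJSI   389 77800 syn-miR-07
#> 27  iso-23-B65TT2OMMQ   388 77600 syn-miR-08
```

Each distinct sequence gets an invertible identifier (`decodeUid()`
recovers the sequence), its per-sample count, and RPM = count /
sample total × 10^6 — here 391 / 5000 × 10^6 = 78,200.

```r
# a 10-organ atlas with planted specificity structure
atlas <- simulateAtlas(30, nOrgans = 10, nSpecific = 5, nUbiquitous = 5,
    seed = 9)
oei <- computeOEI(groupOrgans(atlas$rpm, atlas$meta)$means)
table(oei$class[oei$included])
#>    intermediate tissue_specific      ubiquitous
#>              17               8               5
head(subset(oei, class == "tissue_specific"), 2)
#>         mirna included       oei           class
#> 1 syn-miR-001     TRUE 0.9557164 tissue_specific
#> 2 syn-miR-002     TRUE 0.9534368 tissue_specific

# top miRNAs per tissue by robust rank aggregation
top <- topTissueMiRNAs(atlas$rpm, atlas$meta, n = 3)
head(top, 3)
#>    tissue rank       mirna          rho      p_value m
#> 1 organ01    1 syn-miR-001 1.524158e-12 1.219326e-11 8
#> 2 organ01    2 syn-miR-013 9.988721e-08 7.990977e-07 8
#> 3 organ01    3 syn-miR-016 5.953742e-07 4.762993e-06 8
```

The planted organ-01-specific miRNA scores OEI ≈ 0.96 (> 0.85, the
tissue-specific band) and tops organ01's aggregated ranking with a
Bonferroni-corrected p of 1.2 × 10⁻¹¹ across its 8 sample lists.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript inst/cli/isomiratlas.R make-fixtures --seed 7 --out fixtures/
Rscript inst/cli/isomiratlas.R quantify --space fixtures/space \
    --reads fixtures/reads.tsv --out quant/
Rscript inst/cli/isomiratlas.R oei --rpm fixtures/rpm.tsv \
    --meta fixtures/meta.tsv --out oei.tsv
```

Every run writes a `resolved-config.yaml` beside its outputs; rerunning
with the same inputs reproduces byte-identical results.

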