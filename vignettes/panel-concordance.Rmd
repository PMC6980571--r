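---
title: "Evaluating cross-panel concordance of myeloid NGS gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cross-panel concordance of myeloid NGS gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcompare)
library(dplyr)
```

## The analysis model

Targeted gene panels for myeloid neoplasms differ along four axes that all
propagate into the reported mutation profile: which genes and exons the
design targets, the library chemistry (PCR amplicon vs hybridization
capture), the sequencing read length, and the variant-calling software
upstream of the laboratory's review. `panelcompare` treats a panel
comparison as a fixed sequence of typed transformations:

1. **Designs.** A panel is a set of half-open genomic target intervals
   (BED convention) annotated with genes, plus a chemistry tag and read
   length. Gene identity is by symbol string, case-sensitive, with no alias
   resolution — clinical panel documentation operates at symbol level, and
   silent aliasing is worse than an explicit mismatch. Overlapping records
   are stored distinct (amplicons legitimately overlap) but merged by union
   whenever physical bases are counted (footprints, coverage means), so
   tiling depth never double-weights a base.

2. **Calls.** A variant call is one observation of (sample, panel, locus,
   alleles, VAF, depth, consequence, classification). VCF positions are
   1-based; BED intervals 0-based half-open; every conversion happens at
   the I/O boundary and nowhere else. Calls from different callers are made
   comparable by *normalization*: shared allele suffix then prefix are
   trimmed (always keeping one base per allele) and pure indels are shifted
   left through repeat context as far as the reference allows. The
   normalized representation is the parsimony-minimal, leftmost one; the
   test suite checks this against an exhaustive search over all equivalent
   representations on random contexts, together with idempotence and
   haplotype preservation.

3. **Filtering.** The reporting filter keeps calls with VAF ≥ 5% and depth
   ≥ 100 reads whose consequence is coding (intronic, intergenic and
   splice-region calls are dropped). Both bounds are inclusive: "minimum
   X" plainly includes X. Clinical relevance is then a property of the
   classification label alone — pathogenic or likely pathogenic — with
   unknown labels raising an error rather than defaulting.

4. **The four-state matrix.** For each clinically relevant variant and each
   panel exactly one status holds, assigned by precedence: `ND` (sample not
   assessed with the panel), else `NI` (variant's reference span outside
   the design — intersection with any target interval suffices, so a long
   deletion straddling a target edge still counts as covered), else `C`
   (present in that panel's calls), else `NC`. Discordance counts rows with
   any `NC` or `NI` cell; `ND` never contributes, because a panel a sample
   never ran on cannot disagree. Both `NI` and `NC` rows count as
   discordant — design gaps and calling failures are both ways a laboratory
   misses a reportable mutation, and only this reading reproduces the
   packaged study table's discordance count.

5. **VAF concordance.** Panel pairs are compared by squared Pearson
   correlation of VAFs over calls paired by sample and identical normalized
   key within the panels' shared genes. Pairing is exact — no positional
   fuzz — trading recall for determinism; the pair table is returned so
   users can recompute alternatives. Fewer than two pairs yields an
   undefined (`NA`) coefficient, never zero.

6. **Artifacts.** A recurrent sequencing error is a variant key whose
   occurrences in one panel are *all* below 5% VAF, span at least 30% of
   that panel's analyzed samples, and sit in repetitive context — a
   homopolymer run of ≥ 5 bases or ≥ 3 tandem copies of a 3-mer within
   ±10 bp. The all-occurrences reading of the VAF clause is deliberate: a
   key ever seen at high VAF is plausibly a real variant somewhere, and
   flagging it panel-wide would discard evidence. The repeat-size
   thresholds are not standardized anywhere; 5-base runs and 3-unit
   triplets are the conventional Illumina error-prone motifs, and both are
   exposed in `error_config()`. Recurrence is computed per panel over that
   panel's own samples by default (a cohort-wide denominator is a config
   switch), which matches how per-panel error counts are reported in
   practice.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `vaf_min` | 0.05 | fraction | clinical reporting threshold below which calls are review noise |
| `depth_min` | 100 | reads | minimum evidence for a reportable call |
| `min_supporting_reads` | 10 | reads | caller support cutoff behind the limit of detection |
| low-coverage `threshold` | 1000 | reads | reference mean depth for confident low-VAF detection |
| `uniformity_cv` | 0.5 | — | separates bimodal amplicon dropout (CV near 1) from uniform capture coverage (CV ≲ 0.1); not a published constant |
| `vaf_max` (artifacts) | 0.05 | fraction | complements `vaf_min`, so artifacts and reportable calls are disjoint by construction |
| `recurrence_min` | 0.30 | fraction of samples | a variant recurring in a third of unrelated samples at sub-threshold VAF is systematic, not somatic |
| `homopolymer_min_run` / `triplet_min_units` | 5 / 3 | bp / copies | conventional error-prone motif sizes |

The limit of detection is `min_supporting_reads / mean_depth` — at 1000x
with a 10-read cutoff, 1% — assuming no strand bias. Published panel
descriptions sometimes quote 0.1% for the same figures; the package
implements the arithmetic and documents the discrepancy rather than
reproducing it.

The FLT3-ITD allelic ratio classifies as favorable below 0.5 and
unfavorable above; published rules leave exactly 0.5 unassigned, and the
package assigns it to unfavorable, matching the "high ratio" convention in
AML risk stratification. This is a package decision, not a literature fact.

## The synthetic-cohort generator

`cohort_config()` fixes every condition of a simulated study; its defaults
emulate the packaged study's shape: 32 bone-marrow samples (17 AML, 7 MPN,
6 MDS, 2 CMML), four panels — three hybridization-capture designs at
251/251/151 bp reads and one amplicon design at 201 bp — with partially
overlapping gene subsets, one panel assessing every sample and the others
47%, 50% and 53% of the cohort respectively. Failure modes are explicit
and deterministic by default:

- **Long-indel dropout.** Each panel has a length threshold L (default:
  35 bp on the short-read capture panel, disabled elsewhere); truth indels
  longer than L are removed from that panel's observed calls. This mirrors
  the absolute character of observed > 35 bp misses; an optional
  probabilistic mode (`dropout_prob`) models partial sensitivity instead.
- **GC dropout.** Amplicon chemistry misses all variants in one designated
  GC-rich single-exon gene (default *CEBPA*), and that gene's depth track
  collapses to near zero over half its target, so the coverage flags have a
  positive control.
- **VAF noise.** Observed VAFs are truth VAFs plus Gaussian noise with a
  per-panel standard deviation (defaults 0.01/0.01/0.02/0.06; the amplicon
  panel is noisiest, mirroring the dispersion ordering reported for
  amplicon vs capture comparisons — tests assert the ordering of the
  resulting R² values, never the printed values themselves).

Truth VAFs are drawn uniformly from [0.10, 0.60] — the clinical somatic
range — and observed VAFs of true calls are floored at 0.06: noise models
assay dispersion, not sensitivity, and dropout is modeled only by the
explicit mechanisms above. This keeps every expected status derivable from
the configuration alone before any observation is generated, which is what
makes `expected_matrix()` a genuine oracle: the end-to-end property test
requires `pipeline_matrix(cohort)` (normalize, filter, subset, build) to
equal it *exactly*, over 100+ seeded cohorts.

The reference is a synthetic genome with one 3 kb contig per gene, a
planted 8-base homopolymer and a planted CAG×5 repeat at fixed recorded
coordinates per contig (accidental runs of ≥ 4 bases elsewhere are broken
at generation time, so repeat context is fully controlled). Artifacts are
injected at the planted repeats at sub-threshold VAFs in a configured
fraction of each panel's samples. All randomness flows through one seeded
generator; the same seed reproduces the written FASTA/BED/VCF/TSV tree
byte for byte.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: read-level errors and alignment (no
FASTQ/BAM), strand bias, caller-specific representation quirks beyond what
normalization absorbs, classification disagreement between reviewers, and
correlated mutation patterns within diagnoses (genes and positions are
uniform draws). The packaged study fixtures, not the simulator, carry the
real-data evidence.

## Numerical and degenerate-input choices

- Coverage means are computed over every base of the merged target span
  with absent positions counted as depth 0 — a base `samtools depth` never
  printed is a base with no aligned reads. Means are exact (integer sums
  before division); the property tests compare against a literal per-base
  oracle with `expect_equal` at default tolerance.
- `hgvs_c_span()` parses a closed dialect (underscore ranges with
  `del`/`dup`, single-position `del`/`dup` with optional bases, `ins` with
  explicit length or sequence, substitutions) and returns `NA` for
  everything else — abstention, never a guess. Spans from printed tables
  and lengths from allele strings are cross-checked wherever both exist.
- The packaged study table prints positions and HGVS but not allele
  strings, so its variants key as `chrom:pos:hgvs_c`; allele-level keying
  is exercised on synthetic data where alleles exist. Keys never include
  sample or panel.
- Decimal commas in transcribed ratios ("1,11") are parsed as decimal
  points. "NP"/absent conventional-testing fields are represented uniformly
  as `not_tested`.
- Degenerate inputs fail loudly: empty BED, start ≥ end, duplicate design
  records, unknown classification labels, negative ratios, positions off
  the contig, artifact detection with an empty sample manifest. An empty
  call set in the concordance report is *not* an error — it produces a
  zeroed report.

## Problem sizes in the test suite

The suite validates the normalization oracle on ~85 random contexts, the
repeat-context and artifact detectors against brute-force scans on 100+
random call sets, and the end-to-end matrix equality on 130+ seeded
cohorts of 4–12 samples; the binomial dropout check uses one 40-sample,
160-variant cohort. These sizes give each property hundreds to thousands
of individual comparisons while keeping the default test run around a
minute on one CPU.

## Known limitations

- Partial design fixtures: the packaged per-panel BEDs carry one synthetic
  span per targeted gene (plus exon-level detail where the analysis needs
  it), not the full proprietary probe/amplicon tilings; footprint values
  computed from them are illustrative. The gene sets themselves reproduce
  all published pairwise overlap counts.
- Per-panel mean-calls-per-sample figures depend on per-sample data that a
  printed variant table only partially determines; the package computes
  them from the matrix and manifest but asserts them only on synthetic
  data and on directly derivable fixture counts.
- No transcript models, liftover, phasing, CNV or fusion analysis; the
  CEBPA biallelic flag is explicitly a *candidate* status because
  short-read panels cannot phase the two mutations.

## A complete run

```{r example, eval = FALSE}
designs <- load_panel_fixtures()
m <- table3_matrix()
glance(m)
count_discordant(m)$n_discordant          # 11
nrow(subset_core(m, load_core_genes()))   # 37
missed_indel_lengths(m)                   # 3 rows, all > 35 bp

co <- generate_cohort(cohort_config(seed = 1))
identical(as.data.frame(pipeline_matrix(co)),
          as.data.frame(expected_matrix(co)))
```
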