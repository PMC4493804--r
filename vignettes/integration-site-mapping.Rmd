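---
title: "Mapping retroviral vector integration sites from LTR-junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping retroviral vector integration sites from LTR-junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rispipe)
library(dplyr)
```

## The problem

A retroviral or lentiviral vector integrates semi-randomly into the host
genome, and the genes neighbouring each provirus can be dysregulated --
the genotoxicity that produced leukemias in early SCID-X1 gene-therapy
trials. Assessing a vector's safety, tracking the clonality of transduced
cells, and running retroviral mutagenesis screens all reduce to the same
computational task: given deep-sequencing reads that span the junction
between the proviral long terminal repeat (LTR) and the host chromosome,
recover the set of distinct integration sites (RISs), how often each was
sequenced, and what lies nearby in the genome.

Two artefacts complicate this. PCR amplification recovers the same
junction many times over, and sequencing errors can shift the mapped
junction by a few bases; both must be collapsed before sites are counted.
And a read whose genomic portion maps almost equally well to two loci
carries no positional information and must be discarded, not guessed.

## The pipeline

`run_pipeline()` executes the stages in a fixed order. All thresholds sit
in `ris_config()` and every one can be overridden; the defaults below are
the recommended operating point for LTR-primed (e.g. LAM-PCR) libraries.

**1. Trimming (`trim_reads()`).** The LTR is located in each read by
exact, case-insensitive substring search; the query is everything
downstream of its first occurrence. If a linker-cassette (LC) sequence is
supplied it is searched for *within the query* and the query is truncated
immediately before it. A run of 3 or more consecutive `N` bases truncates
the query before the run (keeping the LTR-proximal prefix, which carries
the junction base that defines the site). Queries shorter than 30 bp are
eliminated: a perfect 30 bp ungapped alignment scores exactly 60, the
score cutoff of the next stage, so shorter queries can never pass. Each
read therefore yields exactly one query or one filter reason -- the
partition is checked by the test suite at every stage.

Matching is exact by design. Mismatch-tolerant adapter trimming would
rescue a small number of reads with sequencing errors inside the LTR, at
the cost of occasionally trimming at a spurious position and mis-placing
the junction base; since frequency estimates tolerate the loss of
individual reads but position estimates do not, exactness is the safer
trade. When the LC precedes the LTR in a read (an inverted artefact) the
query is left untrimmed and generally fails alignment -- such reads are
reported among the eliminations rather than silently reinterpreted.

**2. Alignment (`align_queries()`).** Queries are aligned against the
reference chromosomes *plus the vector sequence*. Three backends share one
blast8 (12-column BLAST tabular) interface: a pre-computed blast8 file
from an external aligner such as BLAT, an arbitrary external command
template, or the built-in aligner. The built-in backend
(`builtin_align()`) finds every ungapped full-query placement on both
strands by tiling the query with non-overlapping exact seeds
(`min_seed = 7` bp) and Hamming-scoring each implied placement: by the
pigeonhole principle any placement with fewer than `floor(len/7)`
mismatches contains an exact seed, so for queries of 30 bp and up the
scan is exhaustive at 92 % identity and beyond. The score is
`2*matches - 6*mismatches`, calibrated so the perfect-30-bp/score-60
coupling above holds. The built-in aligner is ungapped and full-length on
purpose -- it is a deterministic, provably exhaustive backend for
validation and small genomes, not a BLAT replacement; gapped or clipped
alignments enter through the blast8 route. Its e-value column is written
as 0, and minus-strand placements use the blast8 convention of
`t_start > t_end`, preserved un-normalised throughout.

**3. Filtering and candidate calling.** `initial_filter()` removes
alignments with score < 60, identity < 92 %, or a query start offset
greater than 3 bp (`q_start - 1 > 3`: the first query base is the
junction base, and an alignment that skips more than 3 bp of it does not
anchor the junction). `top_alignments()` keeps the 5 best-scoring
alignments per query (ties broken by target then position, for
determinism). `classify_queries()` then applies the ambiguity filters in
order: best hit to the vector; second-best score strictly greater than
95 % of the best (90 % when the best score is below 100 -- short queries
score low, and a looser ratio there rejects near-ties that a fixed 95 %
would let through); best-hit identity below 95 %. The boundary cases are
decided as: ratio *strictly* greater rejects (a second hit at exactly
95.0 % survives), and the 95 % tier applies when the best score is at
least 100. A surviving query's best alignment becomes a candidate RIS:
position `t_start` (the coordinate paired with the query start, on either
strand) and far end `t_end` (the shear/LC-side endpoint). The second-best
ratio is computed over the retained list including vector hits -- a
strong vector second hit still signals that the placement is ambiguous.

**4. Unique-site calling (`call_unique_ris()`).** Candidates within
±5 bp on the same chromosome *and strand* are taken to be the same
integration event (opposite-orientation proviruses at one coordinate are
biologically distinct, so strand is part of the clustering key).
Clustering is greedy: the highest-scoring unassigned candidate (ties:
lowest position, then read id) becomes the unique RIS and absorbs all
unassigned candidates within the window; members at the identical
coordinate are labelled `repeat_ris`, others `in_range_ris`. Greedy
best-score-first selection makes the outcome independent of input order
and is verified in the tests against an exhaustive re-implementation.
Each site reports `frequency` (all grouped members, including the unique
representative -- counting the whole cluster keeps the conservation
identity "sum of frequencies = number of candidates" exact) and
`span_count`, the number of distinct far-end coordinates. Distinct shear
points can only arise from independent fragments, so frequency ≫ span
suggests PCR duplication while many spans indicate clonal expansion.

**5. Annotation.** Gene proximity runs in two phases.
`annotate_genes()`: a site inside a gene's transcription bounds (the
gene "body" is `tx_start..tx_end`, not the CDS) gets distance 0; an
outside site gets the nearest gene end within 5 kb, or no gene at all.
The distance is unsigned but the side (upstream/downstream in gene
orientation) is reported, because the dysregulation mechanism differs --
enhancer activation upstream, premature polyadenylation inside.
`annotate_tss()` independently reports the gene with the nearest
transcription start site at any distance, signed negative upstream of the
TSS in gene orientation: a provirus can sit inside one gene yet be closer
to another gene's promoter, and both facts matter. The 5 kb gene search
is purely positional (nearer of the two gene ends); all equidistant ties
break lexicographically. `annotate_features()` does the same for a
user-supplied BED interval list, with no distance cap.

**6. Random controls and the goodness-of-fit test.** A meaningful "does
this vector prefer genes?" statement needs a null that carries the same
mapping biases as the data. `generate_random_sites()` draws sites
uniformly over the genome (chromosome chosen proportional to its number
of valid start positions, start uniform, strand uniform, minus-strand
sites reverse-complemented); sites containing `N` are redrawn -- up to
`100 * n` attempts -- rather than emitted, so downstream ambiguity
truncation cannot distort the control length distribution. The published
operating range is enforced: lengths 30-1000 bp, counts 1-100,000.
Controls carry no LTR, so they enter the pipeline at alignment and run
through *the same* filter and annotation functions as real queries
(`random_control_run()` calls the identical code path; a test asserts
survival of perfect-copy sites and rejection of sites planted in
duplicated segments). The surviving controls' proximity proportions are
the expected values of a Pearson chi-squared goodness-of-fit test,
`chisq_gof()`, over three gene categories (in gene / within 5 kb /
beyond -- the two proximity classes the summary reports, plus the
remainder) and two feature categories (within / not). The statistic is
the textbook `sum((O - N p)^2 / (N p))` with `k - 1` degrees of freedom;
the tests require agreement with `stats::chisq.test()` to 1e-9.

## The synthetic-data generator

`simulate_dataset()` is the package's source of ground truth. It draws a
uniform-random toy genome, plants non-overlapping proviruses at jittered
grid positions on both strands, and emits per site a
`1 + Poisson(reads_per_site - 1)` number of reads of the form
`LTR + genomic fragment (+ LC)`, with fragment ends varied uniformly over
`0..shear_spread` bp (the distinct-span truth), per-base substitution
errors, optional `N` injection, and optional vector-internal and LTR-less
contaminant reads. Every planted 40 bp junction flank is verified
genome-unique on both strands, so at zero error the pipeline must recover
every site exactly -- recall, precision, frequencies and span counts are
all checked against the truth table. Genes are placed on a regular grid
(width half the grid step, alternating strand) so in-gene fractions have
closed-form expectations.

What the simulator does *not* emulate -- and hence what passing tests do
not show about real data: indels and quality-correlated error profiles,
restriction/shear-site bias of LAM-PCR, repetitive-element structure of a
real genome (ambiguity is exercised only through deliberately planted
duplications), and chimeric reads. Results on hg38-scale data also depend
on the external aligner's gapped-alignment behaviour, which the built-in
backend deliberately does not model.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally (the blast8
  convention); BED and genePred/refFlat are converted at the I/O
  boundary, and the conversion round-trips exactly.
* All randomness (simulation, random sites) flows through explicit seeds;
  a run with the same inputs and seed is byte-identical on disk,
  including CSV reports.
* Degenerate inputs: empty read sets, header-only reports, chromosomes
  with no genes, and empty random controls are all defined (empty
  tibbles, `NA` annotation fields, tests skipped with a warning).
* A chi-squared category with zero expected proportion and zero observed
  count contributes nothing; a zero-expected category with observations
  is an error advising a category merge.
* Validation problem sizes were chosen once: toy genomes of 12-60 kb,
  40 planted sites with ~4 reads each for the end-to-end runs, 2000
  random control sites, brute-force oracle comparisons at up to 50
  candidates and 10 kb of reference. These are the scales at which the
  exhaustive oracles are exact and fast; all invariants checked are
  size-independent.

## Worked example

```{r example}
sim <- simulate_dataset(genome_length = 30000, n_integrations = 8,
                        reads_per_site = 4, error_rate = 0, seed = 7)
run <- run_pipeline(sim$reads, ltr = sim$ltr, lc = sim$lc,
                    genome = sim$genome, vector = sim$vector,
                    genes = sim$genes, random_n = 500)
run
tidy(run)
glance(run)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(run)
plot_gene_proximity(run)
```

## Limitations

The built-in aligner is exhaustive only for ungapped full-length
placements; reads whose un-trimmed tails (e.g. an error-corrupted LC)
depress full-length identity below the reporting threshold are lost
rather than clipped, slightly deflating frequencies at nonzero error
rates. Clonality quantification here is the frequency/span report only;
sonication-abundance estimators, common-integration-site statistics and
multi-sample comparisons are out of scope, as are FASTQ quality handling
and mismatch-tolerant adapter matching.
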