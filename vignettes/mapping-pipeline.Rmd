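---
title: "Mapping a recessive locus from pooled crosses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus from pooled crosses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melomap)
```

## The mapping problem

melomap implements the desk side of a mapping-by-sequencing study of a
fully penetrant recessive trait — amelanism in the corn snake, caused by a
retrotransposon insertion in *OCA2*. The experimental design it assumes is
a set of amel/amel × amel/+ crosses. Such a cross is maximally informative:
every meiosis of the heterozygous parent is a test cross, phenotype reads
out the transmitted causal allele directly (mutant ⇔ amel/amel), and
offspring segregate ~1:1.

Four DNA samples are sequenced: the heterozygous WT parent, the homozygous
mutant parent, and two pools of phenotype-sorted offspring. At a variant
site linked to the causal locus the four samples must show a fixed
pattern — heterozygous in the WT parent and the WT pool, homozygous
("fixed") in the mutant parent and the mutant pool. Everything else in the
pipeline is machinery for exploiting that signature and then dissecting
the candidate gene.

## The filter cascade (`segfilter`)

The cascade applies, in a fixed order whose stage-wise counts are
reportable:

1. **Quality exclusions** — indels, triallelic sites, site mapping quality
   < 100, and any sample whose coverage (ref + alt reads) falls outside
   the closed window [18, 50]. The bounds are strict exclusions, so 18 and
   50 themselves pass.
2. **Parental pattern** — WT parent heterozygous, mutant parent fixed.
3. **Pool pattern** — WT pool heterozygous, mutant pool fixed.

A sample is *fixed* when its minor allele has at most `tolerance_reads`
(default 1) supporting reads; it is *het* when both alleles exceed the
tolerance. The one-read tolerance absorbs the sequencing-error reads that
would otherwise make nearly every deeply covered homozygous site look
marginally heterozygous.

Two classifier decisions were genuinely open:

* **Which homozygote counts as "fixed".** The alignment reference in this
  design is assembled from the mutant parent's own reads, so at a causally
  linked SNP the mutant-linked allele *is* the reference allele and the
  mutant samples are homozygous-reference. `filter_thresholds(fixed_allele
  = "either")` therefore accepts both homozygous states by default;
  demanding the alternate allele specifically would discard the true
  signal. The option exists for designs with an independent reference.
* **Pools use the same classifier as individuals.** A pool of 20
  heterozygotes has an expected minor-allele fraction of 0.5, so the
  tolerance rule behaves sensibly at 18–50× coverage. For much larger
  pools a minimum minor-allele fraction (`pool_maf_min`, default 0) can be
  layered on.
* **Mapping quality is site-level.** The callers this schema abstracts
  emit a site-level mapping-quality summary, and the published wording
  ("SNPs with mapping quality…") is a site property. The TSV dialect has
  no per-sample MQ column.

The surviving set is a pure conjunction of the three stage predicates, so
it is independent of stage order; only the audit attribution (first
rejecting stage) depends on the order, and the tests verify both facts.

Contigs are then judged as a unit: `CONSISTENT` requires at least one
surviving SNP and *no* quality-passing SNP on the contig contradicting the
expected pattern; one discordant quality-passing SNP makes the contig
`CONTRADICTED` (a false positive in the published procedure's sense). Only
quality-passing SNPs can contradict — quality-failing records carry no
reliable allelic state. Whether quality-failing SNPs should also count as
contradictions is unstated in the source procedure; we chose not to, and
note the alternative here.

## Synteny clustering (`synteny_map`)

Consistent contigs are placed on a chromosome-scale reference of a related
species via a hit table (contig, chromosome, span in Mbp, score),
abstracting translated alignment. Per contig only the best-scoring hit is
kept (ties: lexicographic chromosome, then leftmost). The candidate
chromosome is the plurality chromosome of the best-hits — chromosome first,
interval second, matching the two-step narrative this mirrors. On that
chromosome the cluster is the maximal-cardinality run of hit midpoints
whose consecutive gaps are at most `max_gap_mbp`.

The published account reports only the outcome ("a vast majority define an
interval"), not a rule. We chose the gap-bounded run because it is
auditable — every excluded hit is excluded by a visible gap — and exposed
the gap as a flag (default 10 Mbp; the implied tolerance of the original
interval is unknown). Midpoints are used for gap computation because hit
spans are exon-scale (kb) while gaps of interest are Mbp-scale. Width-zero
clusters (all hits co-located) are flagged degenerate rather than being an
error.

## Two-point linkage and interval refinement (`linkage`)

For a marker with `r` recombinants among `n` informative meioses the
two-point LOD is the closed form

$$\mathrm{LOD}(\theta) = \log_{10}\frac{\theta^{r}(1-\theta)^{n-r}}{0.5^{n}},$$

maximized at $\hat\theta = r/n$, with the complete-linkage value reported
as the limit $n\log_{10}2$ when $r = 0$. For the full 256-meiosis panel
this limit is 77.06. The published bound for the same panel is "> 74.2",
which implies a slightly smaller effective meiosis count or a different
LOD variant; neither is stated, so we report our closed form and flag the
discrepancy rather than reverse-engineering an effective `n` (74.2 would
correspond to about 246.5 meioses at complete linkage — or, notably, to
exactly one recombinant in 256, whose maximized LOD is 74.22).

Missing genotypes reduce `n` rather than being imputed, and the trait
genotype is inferred from phenotype with penetrance 1 (the trait is
treated as fully penetrant recessive).

Interval refinement uses flanking recombinants: the zero-recombinant
markers delimit the locus, and the interval runs from the nearest
recombinant marker below them to the nearest above, taking the *outer*
gene-span edges of those flanks. With the published marker panel
(recombinant counts 7, 4, 0, 0, 0, 1, 2 ordered along the chromosome) this
yields 108.455–113.359 Mbp, displayed as 108.5–113.4 (width 4.9 Mbp at
0.1 Mbp display rounding; boundaries are otherwise kept unrounded
internally and reported to 3 decimals). Two degenerate cases are handled
explicitly: a missing flank opens the boundary to the chromosome end with
a warning, and a panel with no zero-recombinant marker (possible in tight
simulated panels) substitutes the least-recombinant marker, flagged.

## Insertion and cryptic-exon analysis (`insertion_analysis`)

`detect_insertion` requires the mutant sequence to be the WT sequence plus
exactly one contiguous insertion, and left-normalizes the ambiguity that
repeated junction sequence creates, mirroring variant left-alignment so
coordinates are deterministic.

`reconstruct_splice` recovers which pieces of the genomic insertion
survive in the mature transcript: the minimum-cardinality chain of exact,
non-overlapping, order-preserving matches of cDNA substrings in the
genomic insertion that concatenate byte-exactly to the cDNA insertion.
Minimality is the parsimony assumption (fewest cryptic exons); order
preservation encodes that splicing does not rearrange; exactness reflects
that both sequences derive from the same allele — a mismatch tolerance
would belong in a cross-allele setting and is deliberately not offered.
The minimum fragment length (default 20 bp) suppresses spurious
micro-chains assembled from chance matches; the real retained fragments
this models total 397 bp. The search is a dynamic programme over (cDNA
offset, minimum usable genomic offset) states with memoized minimum
fragment counts and a 4-mer index for candidate starts; among minimal
chains the leftmost is returned and alternatives set an ambiguity flag.
Each inter-fragment gap is then checked for the canonical `GT` donor and
`AG` acceptor.

`find_orf` defaults to the longest ATG-initiated stop-terminated frame.
For the WT/mutant *comparison*, however, `truncation_report` translates
the mutant from the **WT start codon** (unchanged by a downstream
insertion). This matters: after a frameshifting insertion the downstream
original CDS is stop-free in its own frame, so a longest-ORF policy can
latch onto an internal ATG and report a long, biologically irrelevant
frame instead of the truncation the ribosome actually produces. The
report lists *all* in-frame stops whose codon lies inside the insertion
(the source account does not say which of its two insert stops terminates
the truncated protein; with the default geometry it is the first).

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| families × offspring | 7 totalling 256 | the emulated panel size |
| map function | Haldane at 1 cM/Mbp | simplest standard choice; no genetic map is published |
| coverage | Poisson, mean 30× | centers depths inside the [18, 50] filter window so the coverage filter is non-degenerate |
| sequencing error | 0.002/read | typical short-read substitution rate |
| pool size | 20 + 20 from one family | the emulated pooling design |
| causal position | 110.5 Mbp on a 200-Mbp chromosome | inside the refined interval, at the HERC2 marker midpoint — reflecting the physical adjacency of HERC2 and OCA2 in amniote genomes |
| fraction of linked contigs | 0.1 | makes both verdict classes well populated |
| hit rate | 0.36 | the placed fraction the hit table emulates |
| insertion geometry | 2,011-bp intron + 5,832-bp insertion; 3 retained fragments totalling 397 bp; 2 stops | the characterized allele's arithmetic |

Markers *UNC50*, *HERC2*, *NIPA2* have no published coordinates; the
default marker table assigns synthetic spans inside the refined interval
that preserve the published marker order. Pool membership deviates from a
hard precondition: a family of ~40 rarely splits exactly 20/20, so the
generator picks the most phenotype-balanced family and pools all available
offspring of a scarce phenotype (with a warning) — pool allele dosages at
fully linked sites are 0.5/0 regardless, so this does not bias the filter.

Unlinked sites draw each sample's true state independently and uniformly
from hom-ref/het/hom-alt. That prior is a modelling choice (real unlinked
sites inherit within-family structure and would not be called at all when
every sample is reference); the enumeration oracle used in the tests
applies the same prior, so what the test establishes is agreement between
simulator and classifier, with a chance match probability of 4/81 per
quality-passing site.

The generator also imposes three identifiability constraints on the gene
fixture (retained-fragment boundary bases avoid `G` next to the splice
signals; the last inserted base differs from the base preceding the
junction). These rule out the measure-zero junction coincidences under
which left-normalization and minimal-chain reconstruction are genuinely
ambiguous — for real data the ambiguity flag exists instead.

What the generator does **not** emulate, and passing tests therefore do
not demonstrate: read-level artifacts (mapping bias, indel realignment,
base-quality structure), linked contigs at intermediate recombination
distances (linked means fully linked), within-family allele-frequency
drift in pools, multi-insertion or rearranged alleles, and reference
genomes beyond one gene locus. The study-scale quantities the pipeline
cannot reproduce at desk scale (raw variant counts in the hundreds of
thousands, absolute contig/hit tallies, the initial 82.7–119.5 Mbp
interval) depend on the original reads and are used only to fix the
reporting shape.

## Numerical and reproducibility choices

* One global seed with derived per-stage substreams (pedigree, variants,
  hits, gene), so any stage is reproducible in isolation; identical
  configurations give byte-identical artifacts, and the run summary
  contains no timestamps.
* Internal sequence offsets are 0-based half-open; on-disk formats are
  1-based (VCF); interval boundaries are kept unrounded internally,
  displayed at 3 decimals, widths at 0.1 Mbp.
* Ties are always broken deterministically (documented lexicographic /
  leftmost rules in best-hit selection, clustering and splice chains).
* Degenerate inputs are first-class: empty FASTA, zero-width clusters,
  uninformative markers, zero-recombinant-free panels, zero-fragment gene
  models, and no-ORF transcripts all have defined, tested behavior.

## Problem sizes used by the test suite

The statistical suites run at the sizes the properties are stated for:
10,000 random sites for cascade monotonicity/order-robustness, 10,000
unlinked contigs against the enumeration oracle, 200 default-configuration
replicates for causal-position recovery, 500 random gene models for splice
round-trips, and 10,000 meioses for the Haldane check. Pipeline-level
tests use a few hundred contigs, which keeps the default run fast while
every code path is still exercised.

## Known limitations

* The segregation classifier is depth-threshold based, not
  likelihood-based; very unbalanced heterozygous sites near the coverage
  bounds are its weak spot (by design — it reproduces the published rule).
* `reconstruct_splice` is exact-match only and assumes no rearrangement;
  chimeric or inverted retained fragments are reported as unsplicable.
* The LOD machinery is two-point only; no multipoint analysis or
  interference modelling.
* `detect_insertion` handles exactly one contiguous insertion; alleles
  differing by additional substitutions need upstream cleaning.
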