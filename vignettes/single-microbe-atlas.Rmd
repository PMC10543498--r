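---
title: "Reference-free atlasing of single-microbe barcode groups: models and methods"
author: "scMicrobeAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free atlasing of single-microbe barcode groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data and the problem

Droplet-based single-microbe shotgun sequencing tags every read with a cell
barcode; after barcode correction, the reads sharing one corrected barcode
form a *barcode group* — the unit standing in for a single microbial cell.
Coverage per cell is shallow (often well below 1% of the genome), so two
cells of the same species usually share *no* overlapping reads. Ordinary
sequence-similarity clustering therefore cannot assemble a cell atlas, and
for novel communities there is no reference to map against.

The package's central procedure sidesteps both problems: each barcode group
is treated as a tiny metagenomic sample, its reads are classified
taxonomically, and the per-group taxon counts are binned into a vector over
all genera. Two cells of the same taxon produce similar genus vectors even
when their reads cover disjoint genomic regions — and even when individual
reads are misassigned, as long as they are misassigned consistently. The
vectors are then filtered, embedded and clustered to form the atlas.

## Classification

The built-in classifier is a canonical k-mer LCA classifier. Every k-mer of
every reference genome is indexed under the lowest common ancestor (LCA) of
all genomes containing it; a k-mer and its reverse complement share one
entry. For a read pair, k-mer hits from both mates are pooled, every
root-to-leaf path of the taxonomy is scored by the summed hit counts of its
nodes, and the pair is assigned to the leaf-most node of the best path.
Ties between best paths resolve to the LCA of their terminal nodes; a pair
with no indexed k-mer is unclassified.

* `k = 21` by default. Production k-mer classifiers use longer k-mers with
  minimizers; for desk-scale genomes (tens of kb to a few hundred kb) 21 is
  long enough that k-mers are effectively genome-unique on random sequence
  (collision probability per k-mer about \(L \cdot 4^{-21}\)), yet short
  enough that an uncompressed in-memory hash index is cheap. The valid
  range is odd k in [11, 31] (two-bit packing into 64-bit words).
* There are no minimizers, spaced seeds or confidence thresholds: the
  surrounding method needs the classifier's input/output contract, not a
  particular implementation's internals. Reports produced by external
  classifiers can be imported instead (`importExternalReport()`), so the
  downstream clustering can run on real classifier output unchanged.

Counts are then moved to a working rank (genus by default) by
`redistributeToRank()`: counts at or below the rank are lifted to their
rank ancestor; counts above the rank are split among the node's rank-level
descendants proportionally to the descendants' lifted counts, or uniformly
when all are zero; counts on paths that skip the rank are dropped. This is
a deliberate simplification of Bayesian per-k-mer redistribution: the
proportional split dominates that computation in practice, and conservation
(lifted + redistributed + dropped = classified) is exact and testable.

## Abundance vectors and quality filters

For a group with \(c\) reads classified at the rank out of \(t\) total, the
abundance vector holds the per-taxon fractions of the \(c\) classified
reads. Three per-unit statistics drive filtering:

| statistic | definition | default threshold |
|---|---|---|
| read count | \(t\) | ≥ 1000 |
| classified fraction | \(c / t\) | ≥ 0.5 |
| purity | maximum entry of the vector | ≥ 0.8 (cells), ≥ 0.9 (contigs) |

Purity is computed over *classified* reads, so it stays defined when
classification is partial; the classified-fraction filter separately plays
the role of an alignment-rate cutoff. The two statistics capture different
failure modes (a multiplet has low purity; a cell from a taxon absent from
the reference has a low classified fraction) and conflating them into one
denominator would hide the distinction. All comparisons are inclusive: a
unit exactly at a threshold is retained, because the filters are defined by
what they *remove* (strictly fewer than 1000 reads, and so on).

## Embedding and clustering

Vectors are row-normalised relative abundances; no log or CLR transform is
applied, and the neighbour metric is cosine, which is scale-free for
compositional rows. Clustering is Leiden community detection on the shared
nearest-neighbour (SNN) graph built in the original vector space; the
2-D UMAP embedding (same cosine metric) is for display only. Clustering on
the graph rather than on the embedding is the standard robust choice: the
embedding distorts densities and is the least reproducible step.

Tunable parameters, with defaults:

* `nNeighbors = 15` — neighbourhood size for both the SNN graph and UMAP,
  clamped to \(n - 1\). It should stay below the expected size of the
  smallest population; for very small fixtures pass something smaller.
* `minDist = 0.1` — UMAP display parameter only.
* `resolution = 0.1` — Leiden resolution (modularity objective). The
  within-population vectors of this data type are nearly identical
  (cosine ≈ 0.999), so the SNN graph inside a population is close to a
  random k-NN graph, and modularity at resolution 1 finds spurious
  substructure in such graphs. Because truly distinct populations form
  disconnected components of the SNN graph — and no positive resolution
  ever merges disconnected components under modularity — a low resolution
  only suppresses spurious splits. The default was calibrated on separable
  synthetic communities (10 populations × 50 barcode groups, three seeds),
  where resolutions ≤ 0.1 recover every population exactly and resolution 1
  splits them roughly twofold. On messy, connected real-data graphs a
  higher resolution may be appropriate; the parameter is exposed
  everywhere.
* `seed = 0` — both Leiden and UMAP are run under an explicit seed with
  single-threaded SGD, so results are reproducible bit-for-bit.

Each unit is annotated with its most abundant taxon and each cluster with
the modal unit annotation; ties break lexicographically and are flagged
rather than silently resolved.

A degenerate matrix whose rows are all identical is reported as a single
cluster with a zero embedding — clustering noise on zero variation would be
misleading.

## Metagenomic contig integration

Contigs assembled from bulk metagenomic sequencing of the same sample can
be folded into the atlas: each contig's associated read group is treated as
a pseudo-barcode, classified the same way, filtered at the stricter contig
purity default (0.9 — contig read groups are larger, so their purity
estimates are tighter and chimeric assemblies should be excluded firmly),
and co-embedded with the cells, with a `batch` column distinguishing the
sources. No batch-effect correction is applied; the vectors live in the
same compositional space by construction.

## Strain resolution

Within a panel of strains at ~99% identity, most reads map to several
strains; only reads overlapping divergent sites are informative. The
package treats the strains like transcript isoforms and the barcode group's
reads like multi-mapping RNA-seq reads:

1. **Alignment likelihoods.** Candidate placements are found by exact
   21-mer seeding (stride 5) with ungapped extension, in both orientations.
   For a read of length \(L\) placed with \(m\) mismatches at per-base
   error rate \(\varepsilon\), \(\log P = m \log(\varepsilon/3) +
   (L - m)\log(1 - \varepsilon)\); placements beyond 5 mismatches are
   discarded. Mates contribute the sum of their log-likelihoods on strains
   where both place, falling back to the single placed mate otherwise. Read
   positions are treated as uniform over the genome; no fragment-bias
   model is applied. SAM records from an external all-hits aligner can be
   ingested instead (`likelihoodsFromSam()`, using `NM` tags).
2. **Variational Bayes.** The mixture model \(P(r_i \mid \theta) =
   \sum_s \theta_s L_{is}\) with a \(\mathrm{Dirichlet}(\alpha)\) prior is
   fitted by mean-field coordinate ascent: responsibilities
   \(r_{is} \propto L_{is}\exp(\mathbb{E}[\log\theta_s])\), pseudo-counts
   \(\alpha + \sum_i r_{is}\), iterated until the posterior-mean \(\theta\)
   moves less than `tol` (default 1e-8, capped at 1000 iterations; the
   evidence lower bound is tracked and is non-decreasing by construction).
   `alpha = 0.1` by default — a sparse prior suits the expectation that a
   true single cell is one strain. Note that on *uninformative* data a
   mean-field VB posterior mean and a maximum-likelihood EM estimate
   legitimately differ at order \(1/n\) per component; they coincide as
   reads accumulate.
3. **Assignment.** A group is assigned to its maximum-abundance strain when
   that maximum is at least 0.15, and called `"mixed"` otherwise or on a
   tie. The threshold is inclusive (≥ 0.15), matching a rule phrased as
   "smaller than 15% means mixed". Mixed calls flag multiplets and
   unresolvable cells rather than forcing an arbitrary label.

## The synthetic data generator

The generator exists so the whole pipeline can be exercised and tested with
no external data, and its defaults *are* the standard validation design:

* 150 bp paired-end reads from amplicons of uniformly drawn length in
  [400, 1000] bp, placed uniformly on the source genome (mate 1 reads the
  5′ end, mate 2 is the reverse complement of the 3′ end);
* 1,000–10,000 read pairs per barcode, drawn uniformly;
* a contaminant read fraction drawn uniformly from [0, 0.49] per barcode
  (the maximum-entropy reading of a stated range; a fixed-fraction mode is
  also available), with contaminant reads drawn from uniformly chosen other
  community genomes;
* 100 barcode groups per species in the full design;
* strain panels derived from a common ancestor at 1% substitutions per
  base, giving ~99% identity to the ancestor;
* contig read groups drawn from genome windows with a configurable foreign
  read fraction (modelling chimeric assemblies).

Synthetic genomes are i.i.d. random sequence of configurable GC content,
100 kb by default: long enough that 21-mers are effectively unique per
genome and per-barcode coverage stays realistically sparse, small enough
that hundreds of barcode groups per run simulate in minutes on one core.
Genomes are linear; amplicons never overrun the 3′ end (the start is drawn
uniformly from the valid range for the drawn length). Contaminant pair
counts are rounded half-to-even, so truth tables are exactly reproducible.
Quality strings are constant Q37 unless a substitution error rate is set,
in which case qualities reflect that rate.

What the generator deliberately does **not** model: indels and chimeric
reads, PCR duplicates, transposase insertion bias, within-genome coverage
bias, and real taxonomic structure (synthetic genera are maximally
separated random sequence). Passing the recovery benchmarks therefore
demonstrates the pipeline's correctness and internal consistency — not its
accuracy on real communities, where reference incompleteness and shared
sequence between genera dominate.

## Numerical and edge-case conventions

* Tie-breaks are deterministic everywhere: classification ties go to the
  LCA; annotation ties go to the lexicographically first name and are
  flagged; an abundance tie at assignment time yields `"mixed"`.
* Ambiguous barcode corrections (two whitelist entries at Hamming
  distance 1) are rejected, not arbitrarily assigned, to avoid
  cross-contaminating groups.
* Coverage intervals are half-open; duplicate placements double depth but
  not covered fraction.
* Gene presence/absence filtering drops genes below the cell minimum first,
  then cells below the gene minimum, in one pass — no fixed-point
  iteration. Defaults are 10 cells per gene and 10 genes per cell (5/5 is
  equally expressible where a lighter filter is wanted).
* Empty inputs return empty, typed results (zero-row tables, all-zero
  vectors) rather than errors, except where the operation is undefined
  (clustering fewer than two units).
* The redistribution step and the VB fit return fractional counts and
  probabilities; nothing is rounded internally.

## Validation design and problem sizes

The test suite and the acceptance script validate against independent
oracles: a path-enumeration LCA/classification oracle, brute-force
whitelist scans, closed-form binomial arithmetic, and a plain EM fit
(uniform prior) for the VB estimator. The community-recovery benchmark
runs 10 species × 50 barcode groups at the full per-barcode read depths
with contamination capped at 0.2, across three seeds; strain recovery runs
a 4-strain panel at 1% divergence with 200 single-strain groups of 1000
pairs and 60 synthetic doublets. These sizes were chosen as the smallest
designs that exercise every code path at realistic per-unit depth; all of
them complete on a single core in minutes.

## Known limitations

* The classifier is exact-match only; heavily diverged reads (beyond ~5%
  from any reference) go unclassified rather than to a coarse rank.
* The strain aligner is ungapped; indel-bearing reads lose their true
  placement and either misalign within the mismatch cap or drop out.
* Mean-field VB underestimates posterior correlation between strains;
  abundance *uncertainty* is not reported, only the posterior mean.
* Leiden resolution is a single global knob; communities of very different
  densities in one graph may not all be recovered at one setting.
* The pipeline stages exchange data through plain-text artifacts sized for
  desk-scale studies; none of the containers are disk-backed.
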