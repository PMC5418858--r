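---
title: "Methods: gene-sharing clusters, codon bias, composition scans and phage–host local similarity"
author: "phagecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-sharing clusters, codon bias, composition scans and phage-host local similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecomp)
```

This vignette describes the models and procedures the package
implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## Coordinates and I/O conventions

All gene coordinates are internal **0-based half-open** intervals
`[start, end)`; GFF3 and GenBank readers convert from the 1-based
inclusive file convention and writers convert back. This makes interval
arithmetic (gaps, window tiling, mirroring under reverse complement)
free of off-by-one case analysis. RNA-style `U` in input sequences is
normalized to `T`; codons are converted back to the RNA alphabet only
for display. Circular topology is carried as metadata, but windows and
regions never wrap: the genomes this package targets are handled as
linear contigs, and a wrap-around convention would silently change
window counts for users comparing against linear tools.

GenBank reading is intentionally minimal (single-interval locations,
optional `complement()`, `/locus_tag`, `/product`, `/anticodon`);
multi-interval `join()` locations are rejected rather than approximated.

## Gene-sharing similarity and clusters

Two genomes are compared through the **sets of ortholog-group
identifiers** their genes map to, not through raw gene multisets:
paralogs collapse to a single set element, which keeps the Jaccard
index

$$J(A,B) = \frac{|A \cap B|}{|A \cup B|} \in [0,1]$$

symmetric and bounded, and matches the practice of counting shared
genes "according to" a precomputed ortholog-group table. `J` of two
empty sets is defined as 0. Genes missing from the ortholog table
become unique `singleton:<gene_id>` elements by default: an unannotated
gene is evidence of *dissimilarity* and should inflate the union. A
flag disables this for users whose tables are known to be complete.

A cluster is **reference-anchored**: every candidate genome with
`J(ref, X) ≥ cutoff` (default 0.1, boundary included, since the rule is
stated as "≥") is a member; no transitive closure is applied, so the
cluster is exactly the reference's neighbourhood and two references can
yield overlapping clusters. The full pairwise `J` matrix is available
separately for reporting.

Conservation queries are set queries over the cluster: per OG, the
number of member genes and of distinct member genomes (sorted by
genomes, then genes, then OG id — a deterministic "most conserved"
ranking); the **core** is the OGs present in every member; the
**exclusive** OGs of a genome subset are those present in all of the
subset and in none of the other members. With singletons included, the
per-OG gene counts in the conservation table sum exactly to the
cluster's gene total, a property the tests exploit.

## Synonymous codon usage and the tRNA complement

Codon counting uses the bacterial genetic code (translation table 11,
identical in codon→amino-acid assignments to the standard code).
Initiator codons get no special handling — AUG is methionine with
synonymous family size 1 and usage 1. Per CDS, a terminal stop codon is
excluded; CDS whose length is not a multiple of 3 are skipped with a
warning; internal stop codons are counted and flagged rather than
fatal, because annotated pseudogenes occur in real data.

**Synonymous usage** of a codon is its count divided by the total count
of its amino-acid family; families with zero counts have undefined
(missing) usage rather than 0. The **random baseline** is `1/k` for a
`k`-codon family — the usage expected with no bias. Tabular output
**truncates** (never rounds) to three decimals, so `1/6` prints as
`0.166`; raw fractions are retained in machine output.

The **tRNA complement** maps each annotated tRNA's anticodon to the one
codon it decodes by strict Watson–Crick pairing (reverse complement).
Wobble pairing is deliberately not modelled: the analysis asks whether
the phage carries a tRNA *dedicated* to a host-rare codon, and a wobble
model would require isoacceptor efficiency assumptions the input data
cannot support. tRNA features lacking a parseable anticodon (from the
`anticodon` attribute or product text like `tRNA-Pro(ugg)`) are counted
as undetermined — the pseudo-tRNA case. A codon is flagged **rare in
the host** when host usage is *strictly* below the random baseline; a
tie is not bias.

Gene ranking by target-codon content scores each gene by the fraction
of its codons in the target set (typically the codons decoded by
phage-carried tRNAs), excluding genes with fewer than 30 codons, whose
fractions are too unstable to rank.

## GC windows, composition, intergenic regions

Windows are non-overlapping by default (`step = window`, default
100 bp); a sliding mode is available. The trailing partial window is
included and flagged, so the length-weighted mean of window GC equals
whole-genome GC exactly — an invariant tested to 1e-9. `N` bases are
excluded from numerator and denominator alike; an all-`N` window
reports missing rather than 0.

Intergenic regions are maximal gaps in the union of *all* annotated
feature intervals, clipped to the genome, with a 200 bp default minimum
length: small enough that genuine non-coding islands of a few hundred
bp pass, large enough to suppress ordinary inter-ORF spacers. Each
region carries its base composition and its GC and T deviation from the
whole genome, since composition shifts (GC drop, T enrichment) are the
signal of interest in phage non-coding regions. Genome summaries round
GC to integer percent for report parity with the usual genome-table
style, keeping raw fractions in machine output.

## Relative abundance and local similarity analysis

Read counts are normalized as
$$\mathrm{RA\%} = 100 \cdot \frac{m/T}{L/1000},$$
the percentage of sample reads per kilobase of target genome —
`relative_abundance(1000, 1e6, 1000)` is 0.1. The kilobase convention
is a documented choice; because the downstream analysis is rank-based,
any common monotone normalization gives identical LSA results (an
invariance the tests check).

**LSA** transforms each series to normal scores
(`qnorm(rank/(n+1))`), then for every lag `|d| ≤ D` (default `D = 3`)
finds the contiguous run of aligned points with the maximal positive or
maximally negative sum of score products (a prefix-sum formulation of
the maximum-subarray recursion), and reports `LS = max/n`, its sign,
and the optimal delay (positive delay: the second series lags the
first). Equivalence with an exhaustive search over all contiguous
intervals is tested for `n ≤ 10`.

Significance comes from permuting one series (`n_perm = 1000` by
default) with the add-one estimator
`p = (1 + #[LS* ≥ LS]) / (1 + n_perm)`, which can never return an
exact zero. The permuted member of the pair is chosen by a canonical
rule (lexicographic comparison of the score vectors) rather than by
argument order, so `local_similarity(x, y)` and
`local_similarity(y, x)` return identical p-values along with equal
scores and negated delays. A seed is mandatory; there is no silent
default RNG state. Constant series are an error (ranks are undefined);
up to 25% missing values are linearly interpolated with a warning,
more is an error. Theoretical (non-permutation) p-values are out of
scope, as is multiple-testing correction beyond an optional
Benjamini–Hochberg adjustment users can apply to the reported table.

## What the synthetic generators emulate — and what they do not

`gen_genome_set` plants cluster structure directly at the
ortholog-table level: each cluster has a fixed core (default 15 OGs,
a typical phage-cluster core-genome size), per-genome private
accessory OGs controlled by `shared_fraction_within` (default 0.6, so
within-cluster `J ≈ s/(2-s) ≈ 0.43`, comfortably above the 0.1
cutoff), disjoint OG namespaces between clusters (between-cluster
`J = 0`), one pair-exclusive OG for the first two genomes of each
cluster, and per-genome unassigned "noise" genes. The truth file
records membership, core, exclusive OGs and the *realized* minimum
within-/maximum between-cluster Jaccard. Gene sequences are random
CDS; nothing about sequence similarity, synteny or phylogeny is
emulated, so a green recovery test establishes that the set algebra
and clustering are correct, not that ortholog inference would work on
real sequences (ortholog inference is explicitly out of scope).

`gen_cds_biased` draws amino acids uniformly and codons from the
target synonymous-usage profile, so codon-usage estimation can be
checked by parameter recovery. Real coding sequences have non-uniform
amino-acid composition and length-dependent bias; the generator makes
no attempt at that, which is exactly why it is a calibration tool and
not a sequence-evolution model.

`gen_timeseries` plants `phage[t] = coupling · host[t − lag] + noise`.
The host is a smooth **mean-reverting AR(1) fluctuation** around the
baseline (autoregression 0.7, innovation s.d. half the baseline),
reflected at zero, rather than a drifting random walk. This was a
deliberate design decision: a population tracked over a few weeks of
composting fluctuates about a carrying capacity rather than drifting
without bound, and a near-unit-root walk makes a planted lag nearly
unidentifiable in principle — the walk's extremes sit at the series
endpoints, which any lagged alignment must drop while the unlagged
alignment keeps every point at rank-autocorrelation ≈ 0.9. Latent
series are rescaled so the host peaks at 0.01 RA% (keeping integer
counts well below per-sample totals of 10⁶) and rounded to counts;
counts are simulated at the table level because read mapping is out of
scope. Both latent series are recorded in the truth file.

## Degenerate inputs and tie-breaking

* Empty OG sets: `J = 0`; empty genomes give an empty set with a
  warning, not an error.
* Cluster member ordering: `J` descending, ties by genome id;
  conservation ordering: genomes, genes, OG id — all deterministic.
* Gene ranking ties: score, then gene length, then gene id.
* `window > genome length`: one whole-genome window with a warning.
* p-values: permutation count ≥ 1 enforced by the add-one estimator.
* All generator outputs are byte-identical under a fixed seed.

## Known limitations

* The ortholog table is consumed, never computed: no protein
  clustering, no sequence similarity.
* Wobble decoding, codon-adaptation indices and tRNA efficiency are
  not modelled.
* The GenBank parser covers the flat-file subset used by simple phage
  genome records.
* LSA p-values are marginal per pair; across many pairs the optional
  Benjamini–Hochberg correction should be applied.
* The CLI's structured config format is JSON (no YAML parser in the
  supported dependency stack).
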