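# mirseqpipe

Indexed small RNA-seq analysis for microRNA expression profiling, with a
matched microarray arm. The package targets the kind of study where several
brain-region RNA pools are barcoded with short 5′-adapter indexes, pooled
and sequenced at 36 cycles, and the resulting counts are compared between
two regions and against array signal — and it ships a synthetic-data
generator that reproduces the statistical structure of such an experiment
so that every stage of the workflow can be tested against known truth.

## What it does

**Simulation.** `build_reference()` creates a mature-miRNA catalogue
(19–24 nt sequences organised into seed families and genomic clusters, with
star sequences and mitochondrial/ribosomal-like contaminant decoys);
`simulate_abundances()` draws heavy-topped relative abundance profiles with
fold changes planted in designated families/clusters;
`simulate_library()` emits 36-nt reads of structure
`[6-nt index][mature insert + substitution errors][3′ adapter]` with
adapter dimers, contaminant fragments, homopolymers, short inserts and
corrupted-index reads at configurable fractions, plus a per-read truth
table; `simulate_array()` produces matched log2 array signals as a
compressive monotone function of abundance.

**Preprocessing.** `demultiplex()` (exact 6-nt prefix), `trim_reads()`
(earliest adapter-prefix match, ≥7 nt overlap, 1 mismatch per 10 bases),
`classify_inserts()` (discard order: dimer → contaminant (≤2 mismatches vs
any decoy subsequence) → homopolymer (>80% one base) → short (<14 nt)),
with exact per-stage read accounting in `run_preprocess()`.

**Quantification.** `align_inserts()` does 5′-anchored ungapped comparison
against the mature reference with ≤2 mismatches and ≤3 nt 3′ overhang,
lexicographic tie-breaking; `build_count_table()` applies the
single-count elimination per group; `summarize_run()` emits the standard
run-accounting table.

**Differential expression.** For counts: geometric-mean size factors,
method-of-moments common dispersion φ (variance = μ + φμ²), and a
conditional negative-binomial exact test — condition on the two groups'
summed equalized counts s = y₁ + y₂, enumerate all splits, and sum the
probabilities of splits no more likely than the observed one (at φ = 0
this is exactly the conditional Binomial(s, n₁/(n₁+n₂)) test). BH q-values
are reported alongside but p < 0.05 is the selection rule. For arrays:
present calls (signal above background in ≥2 replicates) and an
empirical-Bayes moderated t with (d₀, s₀²) fitted by moment matching of
the scaled-F distribution of sample variances.
`group_de_by_family_cluster()` highlights seed families and genomic
clusters with ≥2 co-directional significant members.

**Cross-platform comparison.** Spearman correlation, pairwise replicate
concordance, top-k abundance shares, and a weighted ordered-list
similarity: score = Σₙ e^(−βn) (|topAₙ ∩ topBₙ| + |botAₙ ∩ botBₙ|) with an
empirical permutation p-value (1000 permutations, +1 correction).

**Target filtering.** The consensus rule for binding-site prediction
tables: a (miRNA, gene) pair passes iff its Poisson multiple-binding-site
p-value (upper tail of Poisson(rate × UTR length) at the maximum site
count) is below 0.05 **and** ≥2 of 5 programs support it; star miRNAs are
excluded up front.

## Worked example

```r
library(mirseqpipe)
run <- run_pipeline(pipeline_config(seed = 1, n_reads = 20000))
print(run)
```

```
mirseq_run (seed 1)
Run accounting
 row_label                                                        FCx    
 # of technical replicates                                            3.0
 # of pre-filtered reads after base calling                       60000.0
 # of sorted reads with indexes                                   55312.0
 Indexing efficiency (%)                                             92.2
 ...
 # of known miRNAs with >=2 reads                                    88.0

DE: 10 by sequencing, 15 by array; 14 rows in highlighted families/clusters
```

Three FCx and three HP libraries (20,000 reads each, indexes UUAGGC /
CAGAUC / GGCUAC) were simulated, preprocessed and counted; 92.2% of reads
carried an intact index, 88 miRNAs were detected in FCx with ≥2 reads, and
the planted differentially expressed families/clusters appear as
highlighted groups. `write_report(run)` adds the platform-concordance and
target sections:

```
== Platform concordance ==
FCx: 88 miRNAs on both platforms; Spearman rho = 0.965; ordered-list p = 0.000999; top-15 share 92.4% (counts) vs 59.7% (array)
...
== Target summary ==
consensus targets per miRNA: 4 - 11 (median 7)
targets shared between regions: FCx 34.1%, HP 28.0%
```

The contrast between the top-15 count share (~92%) and array share (~60%)
is the expected signature of the array's compressed dynamic range. A thin
command-line wrapper is installed at `inst/scripts/mirseqpipe.R`.

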