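---
title: "Methods: an indexed small RNA-seq workflow with a matched array arm"
author: "mirseqpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an indexed small RNA-seq workflow with a matched array arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseqpipe)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The experiment being modelled

Two brain-region RNA pools (labelled FCx and HP throughout the defaults)
are each converted into three sequencing libraries tagged with a different
6-nt index embedded at the 3′ end of the 5′ adapter. Because the
sequencing primer sits on the constant part of the 5′ adapter, each 36-nt
read begins with the index, followed by the mature miRNA insert and then
the 3′ adapter. Differently indexed libraries of the same pool are
technical replicates. The same pools are also measured on a miRNA
microarray with three replicates per region.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth. What it emulates, and how:

* **Reference** (`build_reference()`). Mature sequences are 19–24 nt;
  a *seed family* is defined operationally as identical nucleotides 2–8,
  and a *genomic cluster* as loci on one chromosome and strand whose
  single-linkage gaps are at most 10 kb. Neither notion has a universal
  operational definition; the seed identity and the 10 kb window are the
  common conventions and both are exposed as parameters. Constraints
  enforced by rejection sampling: all mature pairs differ at >2 positions
  over their aligned length (so ≤2-mismatch alignment is unambiguous), no
  mature sequence lies within 2 mismatches of a contaminant subsequence,
  and no mature sequence comes close to the homopolymer filter (max base
  fraction ≤ 0.6). A configurable fraction of entries (default 12%) are
  star sequences, marked `*` in the name.
* **Abundances** (`simulate_abundances()`). Baselines are log-normal with
  `sdlog = 2.5`. This value was chosen once so that the 15 most abundant
  of ~300 miRNAs typically hold well over half of all reads, the high-skew
  regime characteristic of bulk brain small-RNA libraries; the generator
  property test asserts the >0.5 share over 100 seeds. Group 2 equals
  group 1 times the planted fold changes, renormalized. Renormalization
  means large planted changes on abundant miRNAs would shift the relative
  abundance of *every* null miRNA (a compositional effect, not an
  artifact); the default pipeline therefore plants fold changes on
  mid/low-abundance families and caps each member's post-change mass share
  at 0.3%, mirroring real data where the large-fold-change miRNAs are
  never the dominant tier.
* **Counts with exact conservation** (`simulate_library()`). Per-miRNA
  clean-read counts are a gamma-weighted multinomial: weights
  `w_i ~ Gamma(shape = 1/φ', scale = φ' p_i)` with
  `φ' = φ / (1 + Σ p²)`, then a multinomial draw of the clean total.
  Marginally this gives `Var(K_i) ≈ μ_i + φ μ_i²` (the `φ'` shrinkage
  compensates the variance the weight-sum normalization would otherwise
  add), while read totals are conserved exactly so truth labels partition
  the library. One structural consequence is genuine: a miRNA holding a
  large share of the library has its variance compositionally suppressed
  by roughly `(1 − share)²` — the total is fixed, so the dominant feature
  cannot fluctuate freely. The dispersion estimator accounts for this
  (below). At `φ = 0` the draw degenerates to a plain multinomial.
* **Contaminant classes.** Adapter dimers (index directly followed by
  adapter), fragments of the mitochondrial/ribosomal-like decoys
  (16–28 nt), homopolymer inserts, short inserts (12–13 nt), and reads
  whose index carries one substitution (`unindexed`). The last class is an
  addition to the obvious four: without it indexing efficiency is always
  100%, whereas real runs lose ~10% of reads at index sorting; its default
  fraction (0.08) puts the simulated efficiency in that realistic range.
  Default fractions (5% dimer, 18% contaminant, 2% homopolymer, 3% short)
  give a 25–35% loss between index sorting and the filtered set,
  qualitatively matching published per-stage attrition. Substitution
  errors are applied to the mature insert only — the error model is
  substitution-only because the aligner tolerates mismatches, not gaps.
  A short random insert occasionally sits within 2 mismatches of a decoy
  subsequence and is then (correctly, per the filter's definition)
  discarded as a contaminant rather than as short; truth-agreement tests
  therefore assert exact recovery only for clean and dimer classes.
* **Array signals** (`simulate_array()`).
  `log2 signal = background + compression × log2(abundance / min abundance) + N(0, noise_sd²)`,
  with the minimum taken over the whole profile so equal abundances give
  equal expected signal in both groups. `compression = 0.5` halves the
  log-dynamic range, which reproduces the hallmark that the top-15 share
  of linear array signal sits far below the top-15 count share.

What the generator does **not** emulate: PCR amplification bias,
sequencing quality scores, indels, probe-level array effects and
cross-species probe hybridization, isomiR length heterogeneity (inserts
are full mature sequences), and ligation bias between indexes. Passing
tests therefore demonstrate the correctness of the pipeline's logic and
its statistical calibration under the stated model, not robustness to
those real-data phenomena.

## Preprocessing rules

Demultiplexing is an exact match of the read's first 6 nt against the
index set — no mismatch rescue, since only reads with an intact index are
retained (a rescue flag is deliberately absent; corrupted-index reads are
accounted as unassigned). Adapter trimming takes the *earliest* position
where a prefix of the 3′ adapter aligns with at most
`floor(overlap/10)` mismatches, requiring ≥7 nt of overlap; a shorter
read tail qualifies only if it matches exactly. Untrimmable reads keep
their whole 30-nt remainder as the insert — they may be long inserts —
and then face the filters. Discard precedence is fixed (dimer →
contaminant → homopolymer → short) so each read has exactly one discard
reason and the per-stage counts partition the input; the homopolymer rule
is strictly greater than 80% of the insert.

## Quantification

Alignment is a direct 5′-anchored ungapped scan against the small mature
reference (≤2 mismatches over the shared prefix, ≤3 nt length difference)
rather than a genome aligner: only mature-reference hits feed the count
table, the reference is a few hundred sequences, and an exhaustive scan is
both faster at this scale and exactly testable against a brute-force
oracle. Multi-mapping ties are broken by the lexicographically smallest
miRNA name — a deterministic stand-in for an unspecified reporting mode;
with the reference's >2-mismatch separation guarantee, ties only occur
for error-bearing reads. The mismatch cap of 2 is the workflow's
convention and is configurable. A miRNA whose summed count within a group
is exactly 1 is dropped from that group's detected set (the "≥2 reads"
rule); the interpretation is per group, matching per-region accounting,
with the count matrix itself left intact.

## Count differential expression

Size factors are each library's total over the geometric mean of totals;
the reported *concentration* is the count divided by `factor × geometric
mean`, i.e. the within-library proportion, and the exact test operates on
counts equalized to the geometric-mean library size. The common dispersion
φ (variance `μ + φμ²`) is a pooled method-of-moments estimate from
within-group residuals — transparent and directly testable, which is why
it was preferred over a likelihood-based estimator; the acceptance surface
is calibration and power, not numerical identity with any particular
implementation. Two corrections matter:

* dividing by size factors inflates Poisson-level variance by
  `mean(1/factor)`, which the numerator subtracts;
* features holding more than 5% of all counts are excluded from the
  moment sums, because their compositionally suppressed variance would
  otherwise drag φ toward zero for everyone else (the exclusion is
  skipped when fewer than 20 features would remain).

The exact test conditions on the total `s = y₁ + y₂` of the group-summed
equalized counts (rounded to integers). Group sums are NB with means
`n_g μ̂` and sizes `n_g/φ` where `μ̂ = s/(n₁+n₂)`; the two-sided p-value
sums the conditional probabilities of all splits no more likely than the
observed one (with a `1e-10` log-scale tie tolerance so the symmetric
split returns exactly 1). All splits are enumerated exactly at every `s`
— the enumeration is vectorized and cheap even for totals in the
hundreds of thousands. At `φ = 0` the NB conditional law reduces exactly
to `Binomial(s, n₁/(n₁+n₂))`. Significance is `p < 0.05` without
multiple-testing selection — BH q-values are always reported alongside —
because correlated platforms make FDR selection across the joint list
overly conservative; log2 views use a pseudo-count of 0.5.

## Array arm

Present calls require signal above the background threshold in ≥2
replicates of a group; the default threshold is the 0.9 quantile of the
Gaussian background model (closed form `b + 1.2816 σ`), and an explicit
null signal set can be supplied instead. The moderated t squeezes pooled
per-feature variances toward a prior fitted by matching the mean and
variance of `log s²` under the scaled-F model (inverting the trigamma
function numerically with `uniroot` on `[1e-8, 1e8]`); `d₀ → 0` recovers
the ordinary pooled t and `d₀ → ∞` fixes all variances at `s₀²` — both
limits are unit-tested, and the whole fit is cross-checked against an
independent reference implementation in the test suite.

## Family/cluster grouping

A family or cluster is *highlighted* when at least two of its members are
significant **in the same direction** — co-transcribed clusters and
shared-seed families shift coherently, and the co-direction requirement
prevents two unrelated false positives that happen to share a label from
being presented as a co-regulated group. Star status is flagged purely by
`*` in the name; `-5p/-3p` names are not treated as star.

## Ordered-list similarity

Both value vectors are ranked descending (ties broken by a fixed
identifier order, `ties.method = "first"`) and compared through
`score = Σₙ e^{−βn} (|topAₙ ∩ topBₙ| + |botAₙ ∩ botBₙ|)`, computed in
O(N) as a cumulative histogram of pairwise maximum positions. The default
`β = log(100)/100 ≈ 0.046` keeps the weight above 0.01 over roughly the
top 100 ranks — the scale at which a few hundred miRNAs are compared; β is
a free parameter of the method and is exposed. The null is `n_perm`
random permutations of the second list, and the empirical p-value carries
the +1 correction, so its minimum is `1/(n_perm+1)` and it is valid
(conservative) by construction. The bottom-of-list term is a toggle
(`two_sided_ends`), with the joint two-ended score as the default.

## Consensus target filter

Sites are aggregated across programs by maximum, not sum: the five
programs scan overlapping site sets, and summing would double-count the
same site. The Poisson null rate is, by default, estimated from the input
itself per miRNA (total sites over total scanned UTR length) — a
scale-free, self-contained choice when nothing else is known. Its limit:
if the input table consists mostly of genuinely enriched pairs, the
self-estimated rate absorbs the enrichment; whenever the scanned universe
(or simulation truth) is known, the fixed `background_rate` override is
the right choice, and the bundled pipeline passes its generator's true
rate. The pass monotonicity property (adding a program or a site never
flips pass→fail) holds for a fixed rate; under the self-estimated rate
the null adapts and monotonicity is not guaranteed. The pooled
(maximum-site) Poisson p was chosen over per-program p-values and is
flagged here as a choice.

## Determinism and problem sizes

Every stochastic operation takes an explicit seed; the pipeline derives a
fixed offset seed per stage from the master seed (reduced modulo 2×10⁶ so
derived seeds remain valid 32-bit integers), and two runs with the same
configuration produce byte-identical artifacts, recorded with MD5 hashes
in a JSON manifest. The test suite exercises the workflow at the scales
the package is designed around: truth recovery on 3+3 libraries of 50,000
reads over a 300-miRNA reference; exact-test calibration on 2,000-feature
null tables over 10 seeds; similarity calibration on 200 repetitions of
1,000 permutations; the end-to-end determinism check on 5,000-read
libraries. The acceptance script uses 20,000-read libraries and 5
calibration replicates.

## Known limitations

The common dispersion is a single shared φ — no tagwise moderation, no
GLM designs, no batch correction. Alignment is ungapped and
reference-only; novel miRNAs and isomiRs are out of scope. The array arm
is feature-level only. The exact test inherits the compositional
worldview of relative-abundance data: a planted change on a dominant
feature genuinely shifts everything else's relative abundance, and no
normalization can undo that at 50% mass share. Contaminant matching is
ungapped with ≤2 mismatches against the decoy set only.
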