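---
title: "Methods: expression fate and regulatory divergence of recent duplicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression fate and regulatory divergence of recent duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupfate)
```

# Scope and model

`dupfate` analyzes what happens to gene expression after a very recent
segmental duplication: a gene family consists of an *ancestral* paralog
(syntenic with the single-copy ortholog of an outgroup species), one or more
*derived* paralogs, and the outgroup *ortholog*. The classic fates are:

* **conserved** -- the ancestral copy keeps the ortholog's cross-tissue
  profile, the derived copy drifts (relaxed selection), typically downward;
* **pseudogenized** -- the derived copy is silent;
* **neofunctionalized** -- the derived copy is expressed but its profile is
  uncorrelated with the ortholog;
* **subfunctionalized** -- the daughters partition the ancestral expression
  domain, so the *sum* of the paralogs tracks the ortholog better than any
  individual paralog does.

The package turns these expectations into statistics on a genes x samples
TPM matrix with tissue labels: per-tissue means, Pearson correlation of each
member (and of the family sum) with the ortholog profile, the tissue
specificity index
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$, mean relative expression
$\overline{\log_2((h+pc)/(o+pc))}$, and expression divergence
$|\log_2((d+pc)/(a+pc))|$ on median TPM.

## Fate classification

`classify_family()` reduces a family to a call using two rules:

1. if $r_\text{sum} - \max_j r_j \ge$ `margin` (default 0.05), the family is
   a `subfunctionalization_candidate`;
2. otherwise the best-correlated individual member decides:
   `ancestral_conserved` or `derived_conserved_candidate`.

The 0.05 margin reflects treating differences in Pearson's r below 0.05
between the sum and the best paralog as negligible; it is exposed as a
tunable. Members with undefined correlation (silent genes, zero variance)
are excluded rather than scored 0, so a silent derived paralog cannot
masquerade as "uncorrelated but expressed".

**Correlation scale.** Correlations are computed on `log2(TPM + pc)`
per-tissue means (`pc` = 1e-4) rather than raw TPM. On raw TPM a Pearson
correlation over seven conditions is dominated by the single most highly
expressed condition (TPM is approximately lognormal), which destroys the
subfunctionalization signature: a paralog holding only the top-expressed
tissue correlates near 1 with the ortholog even though it carries half the
expression domain. The log scale weighs tissues evenly; `log_scale = FALSE`
restores the raw behavior.

## Group-level tests

`fisher_de_proportions()` is the exact two-sided test of association in a
2x2 table of non-DE/DE counts for ancestral vs. derived genes.
`most_conserved_enrichment()` asks whether the most-conserved member of each
family is the ancestral paralog more often than chance; because "chance"
is ambiguous here, both nulls are implemented and labeled: an equal-choice
null (family *i* picks its ancestral member with probability $1/k_i$;
exact Poisson-binomial tail by dynamic programming -- the default) and a
draw-without-replacement hypergeometric null over the pooled gene set.
`groupwise_tests()` is a Kruskal--Wallis test with Dunn's pairwise z
comparisons (tie-corrected pooled ranks) and Benjamini--Hochberg adjustment
across pairs.

## Copy-number-adjusted differential expression

CN varies between individuals and paralogs and itself moves expression, so a
naive paired test confounds CN dosage with regulatory divergence.
`cn_adjusted_pair_test()` stacks a pair into long form and fits

$$\log_2(\mathrm{TPM}+pc) \sim \mathrm{paralog} + \mathrm{CN} +
  \mathrm{paralog}\times\mathrm{CN}.$$

If the interaction is detected at raw $p \le 0.05$ the pair is reported as
`interaction_detected` and the paralog main effect is *not* tested: with
paralog-specific CN slopes a single adjusted contrast has no unambiguous
interpretation. Otherwise the model is refit without the interaction and the
paralog coefficient is tested; BH is applied across tested pairs at a 5%
FDR. The interaction screen deliberately uses the raw p-value, not an
FDR-adjusted one. When CN is constant the procedure reduces to a paralog
location test, which the suite verifies.

## EM reallocation of multi-mapping reads

Reads from near-identical duplications map to multiple loci and are usually
discarded, depleting coverage-derived signals (e.g. ChIP peaks) in
duplicated regions. `em_allocate()` defines a concrete EM: each read starts
uniform over its candidates; a candidate's support is

$$s_{ij} = U_j + M_{ij} + \varepsilon,$$

where $U_j$ is unique-read coverage summed over a `window_w` = 101 bp window
centered on the candidate start, $M_{ij}$ is the current posterior mass of
*other* multireads in that window, and $\varepsilon$ = 0.1 avoids absorbing
zeros. Responsibilities $r_{ij} = s_{ij}/\sum_j s_{ij}$ are iterated to
`tol` = 1e-6 (cap 200 iterations). Excluding the read's own allocation
prevents self-justifying placements in unique-coverage deserts. Fragment-
length smoothing of coverage is deliberately omitted for clarity; alignment
scores can optionally multiply support as `exp(score)`.
`select_primary()` takes the posterior argmax with lexicographic
(chrom, position, strand) tie-breaking, so outputs are deterministic.

With a 3:1 true coverage asymmetry the best achievable primary-selection
accuracy for a coverage-based allocator is the majority fraction (75%); the
package's recovery property (>= 65% over 10 seeds) sits deliberately below
that ceiling.

## Permutation depletion test

`depletion_test()` computes the fraction of region bases covered by peaks
and compares it with `n` = 1000 replicates in which each region is uniformly
re-placed on its own chromosome (lengths preserved, replicates independent).
The one-sided depletion p-value is $(M+1)/(N+1)$ with $M$ the replicates
strictly below the observed value -- never 0, bounded by $1/(N+1)$.

Numerical choices:

* permuted regions stay on their own chromosome by default (preserves
  chromosomal composition); `cross_chromosome = TRUE` draws the chromosome
  with probability proportional to length;
* permuted regions *may* overlap each other, and the replicate statistic is
  the sum of per-region intersections over total region length (the
  marginal-uniform null). The observed statistic is computed on the merged
  observed regions, which are disjoint in practice, so observed and null use
  the same functional there. Under this null the replicate mean equals the
  genome-wide peak density and the p-values are uniform, both of which the
  suite checks;
* inside the permutation loop intersections use a prefix-sum representation
  of the merged peak set (two binary searches per region end) rather than
  interval algebra; the two routes are cross-checked in the tests.

`filter_hsd()` extracts the high-identity subset of a segmental-duplication
table (`fracMatch` strictly > 0.98 by default) and merges it, which is how
the "highly identical duplication" region set for the depletion test is
built from a standard SD annotation.

## Motif gains and losses between paralogs

`scan_pwm()` scores every window on both strands with the base-2 log-odds of
a position probability matrix against its background and converts scores to
*exact* p-values: the full null score distribution is computed by dynamic
programming over motif positions with per-letter scores discretized to
1e-3 bins. The discretization bounds memory for motifs up to ~20 bp at a
p-value distortion far below the reporting precision; for short motifs the
DP distribution is identical to exhaustive enumeration over all $4^k$
windows, which the suite asserts. Matrix probabilities are floored at 1e-6
so scores stay finite. BH is applied per scan (one motif, one sequence,
both strands), mirroring per-query FDR semantics; windows containing N are
skipped. The default background is uniform, which also makes the null
strand-symmetric.

`compare_homologs()` anchors hits to a reference homolog through pairwise
gapped alignments; hits of the same motif within +/-3 reference positions
(tunable) count as one site, a tolerance that absorbs micro-indels without
conflating neighboring sites. Polarity needs the outgroup: a site present
only in derived paralogs is a derived gain; a site absent from exactly one
paralog but present in the ortholog and another paralog is a loss in the
absent paralog; configurations the outgroup cannot polarize are labeled
`unpolarized` rather than forced. `tf_expression_filter()` restricts the
motif library to factors expressed above 1 TPM in strictly more than 75% of
libraries.

# The synthetic world

All generators live in one configuration (`sim_config()`) and one master
seed; each generator draws from its own stream (seed + stage name), so
regenerating one stage never perturbs another. Defaults describe the world
the analyses assume: 30 families with 2--4 paralogs (~75 genes), 7
expression contexts with 3 replicates each, paralog sequences at ~99.5%
identity via Poisson-placed PSVs (rate 0.005/bp), continuous CN around 2
(SD 0.5, truncated at 0), and a 10-Mb landscape with 30 SD intervals of
50 kb and 5000 peaks of 400 bp.

Free parameters with no externally stated value were fixed once at values
realistic for bulk expression data and documented here: log2 baselines
N(3, 1.5) across tissues, expression noise SD 0.25 on the
`log2(TPM + 1e-4)` scale (roughly a 20% coefficient of variation),
a -3 log2 shift for conserved-fate derived paralogs, and a 3:1 read-origin
asymmetry for the duplicated-read simulator (comfortably above the minimal
2:1 asymmetry the allocator-recovery property assumes).

**Subfunctionalized families.** Daughters receive complementary near-binary
weights (0.98/0.02 per tissue for a pair) over a tissue partition, so the
member sum equals the ortholog profile exactly. The partition is not a fixed
sigmoid along the tissue index: with only seven tissues, a fixed split can
by chance produce an individual paralog whose masked profile is almost
collinear with the ortholog (a two-cluster geometry), which would break the
noise-free recovery guarantee. Instead a small search under the family's
RNG stream picks the partition minimizing the largest individual
paralog--ortholog correlation -- a deterministic construction of the
most-divergent split, which is also the biologically intended reading of
expression-domain partitioning.

**What a green test does not establish.** The generator emulates the
*statistical signatures* of the fates, not real transcriptomes: noise is
homoskedastic on the log scale, tissues are exchangeable and independent,
CN is independent of expression unless a slope is injected, read sampling is
uniform with no GC or mappability structure, and peaks are independent
fixed-width intervals. Green properties mean the estimators recover the
stated structure at the stated noise -- not that the pipeline is robust to
batch effects, expression-dependent variance, or alignment artifacts of
real data.

# Reproducibility and I/O

Everything tabular is plain TSV; intervals are BED (0-based half-open,
validated on read and write); sequences are FASTA; motifs are MEME minimal
format; the pipeline configuration is a single JSON file (JSON rather than
YAML so the only structured-text dependency is `jsonlite`). `run_pipeline()`
executes simulate -> stats -> fates -> cnde -> alloc -> depletion -> motifs
as toggled, writes one TSV per stage plus a run log recording the seed and
every default in effect, and is byte-reproducible under a fixed
configuration, which the suite asserts. The `dupfate` script in `exec/`
exposes the same stages on the command line.

# Known limitations

* Fate calls are correlation heuristics over seven conditions; they rank
  hypotheses, they do not test them.
* The EM allocator is a deliberately transparent re-statement of
  coverage-weighted reallocation; it is not expected to be bit-identical to
  any external tool, and it ignores fragment-length structure.
* The DE-proportions and most-conserved tests consume upstream DE labels
  and correlation tables as inputs; cross-species normalization and
  quantification are out of scope.
* `compare_homologs()` trusts the supplied pairwise alignments; misalignment
  shows up as `unpolarized` or missing anchors rather than being corrected.
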