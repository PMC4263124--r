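---
title: "Population-resolved integrated omics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-resolved integrated omics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popomics reconstructs population-level genomes ("composite genomes", CGs)
from mixed microbial community sequence data and integrates metagenomic
(metaG), metatranscriptomic (metaT) and metaproteomic measurements at the
population level. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic benchmark community does and does
not emulate, and the design decisions taken where several choices were
defensible.

## Signature-based binning

Each contig is summarised by its canonical pentanucleotide signature: counts
of all 5-mers, collapsed under reverse complementation so that counting is
strand-independent. For odd k no k-mer equals its own reverse complement, so
the canonical set has exactly 4^5/2 = 512 members; the canonical
representative is the lexicographically smaller of a pentamer and its
reverse complement. Windows containing ambiguous bases are skipped.

K-mer profiles are compositions, so Euclidean geometry is applied only after
a centred log-ratio (CLR) transform: with pseudocount-augmented proportions
`p`, `clr_j = log p_j - mean(log p)`. The pseudocount (default 1) handles
zero counts on short contigs and is exposed as a parameter; every CLR vector
sums to zero by construction, which the tests assert.

The 512-dimensional CLR signatures are projected to 2-D with t-distributed
stochastic neighbour embedding after a PCA reduction to 50 components. The
package implements the embedding with the exact O(n^2) gradient: at the
contig counts this package targets (a few thousand), the exact gradient runs
in seconds as compiled code and removes the approximation parameter that a
tree-based gradient would add. Perplexity defaults to 30 (an embedding needs
at least `3 * perplexity + 1` points), with 750 gradient iterations,
learning rate 200, early exaggeration 12 for the first 250 iterations and a
momentum switch from 0.5 to 0.8 at iteration 250 — the conventional settings
for this family of embeddings. The embedding is seeded and reproducible; all
randomness in the package flows from one root seed through fixed per-stage
substreams, so adding a stage never perturbs another stage's draws.

Clusters in the embedding are modelled as a 2-D Gaussian mixture fitted by
expectation-maximisation. Means are either supplied (the interactive
workflow, where a user picks one centre per visible cluster) or initialized
by k-means for a requested K; a BIC scan over K is available when no count
is known. Covariances start as diagonal matrices with small positive
entries (1% of the data variance) and keep a 1e-6 variance floor throughout
to prevent singular components. EM stops when the relative log-likelihood
change falls below 1e-6 (at most 500 iterations); the log-likelihood trace
is retained and is non-decreasing, which the tests assert. Contigs are
assigned to their maximum-responsibility component; a contig whose maximum
posterior falls below 0.5 is reported as "unbinned" rather than forced into
a bin.

Binning is iterative: first-round groups recruit their mapped reads, then
each group is re-profiled and re-clustered on its contigs of at least
1,000 bp (the first round admits contigs from 500 bp). A group is split in
round two only when a multi-component mixture beats the single component by
more than 10 BIC units. Contigs below the round-two length threshold keep
their group; if the group splits they join its largest sub-bin — the choice
is conservative and only affects contigs too short to re-profile.

## Coverage-based bin refinement

Two populations with near-identical sequence composition can share a bin;
they are separable by read depth. `split_by_coverage()` fits one- and
two-component Gaussian mixtures to log10 per-contig depth and splits when
the two-component model improves BIC by more than 10. Two details matter.
First, the components share one variance: per-contig depth noise shrinks
with contig length, so a single population's depths form a scale mixture
that an unequal-variance two-component model can imitate; a common variance
restricts the second component to describing a genuine second depth mode.
Second, the two fitted modes must differ by at least a factor of 2 —
coexisting populations merged into one bin differ substantially in
coverage, and smaller contrasts are indistinguishable from depth noise.
Sub-bins are labelled `a` (lower depth) and `b` (higher depth).

## Relative population sizes and expression calls

The relative size of population i is a length-normalized read share,
analogous to RPKM:

    N_i = (c_i / l_i) / sum_j (c_j / l_j)

with `c_i` the metaG reads mapped to CG i and `l_i` its length. In this
default "relative" mode the N_i sum to 1 and are dimensionless. An
"rpkm_like" mode (`1e9 * c_i / (C * l_i)`, `C` the total mappable reads) is
provided for sensitivity analysis; the two are proportional within a
sample, and every output records which mode produced it. The relative mode
is the default because it makes the expression threshold below operate on
an interpretable 0–1 scale.

Per-gene expression uses FPKM (`count * 1e9 / (gene_length *
total_mapped)`), with the denominator the total fragments mapped in the
sample — the population-size correction is carried by the threshold, not by
a per-CG denominator. A gene is called expressed when its metaT FPKM is at
least `50 * N_i` of its population, boundary inclusive. Scaling the
threshold by N_i makes calls comparable between abundant populations (whose
genes accumulate reads by abundance alone) and rare ones. Raising the
factor can only shrink the expressed set (tested as a monotonicity
property). The fraction of a CG's genes called expressed is the package's
niche-breadth readout: a generalist expresses a small fraction of a large
repertoire, a specialist most of a smaller one.

Functional profiles count genes per COG category, normalized by the CG's
gene total; genes with several categories collapse to `Multi+I` when lipid
transport and metabolism (I) is among them, `Multi-I` otherwise, and
unannotated genes to `No`. Completeness is the detected fraction of a
40-gene universal single-copy marker panel. Amino-acid identity between two
proteomes (AAI) uses reciprocal best hits under global Needleman-Wunsch
alignment with BLOSUM62 (gap open 10, extend 0.5), reporting the median,
s.d. and pair count; identity is matches over alignment columns.

## Variants

SNP call sets from several callers are normalized to (contig, 1-based
position, reference, alternate) keys — multiallelic records are decomposed,
indels skipped and counted — and intersected: only variants reported by
every caller survive, with per-library depths taken as the minimum across
callers (conservative). Variants then need depth of at least 10 in *both*
the metaG and metaT libraries, boundary inclusive; the depth is per-site, a
deliberate reading of a "regional depth" requirement that is simpler and
strictly more stringent at the variant position. Per-CG variant density is
SNPs per kb divided by N_i, which compares mutational load between
populations of different abundance without conflating the two.

## Protein quantification

The normalized spectral index of a detected protein is the sum of its
per-spectrum summed fragment-ion intensities over all peptides and spectra
(peptide and spectral counts enter as summation multiplicities), divided by
protein length and by the summed index of all detected proteins in the run:
`nsi_p = si_p / (length_p * sum_q si_q)`. The normalization order is fixed
by the closure identity `sum_p nsi_p * length_p = 1`, which holds on every
run and is asserted by the tests together with intensity-scale invariance
and the length-inverse property. NSI values are reported log2-transformed
for cross-protein comparison; undetected proteins are absent (not zero),
and no pseudo-offset is added to the logarithm since comparisons are
ratios. Normalization is per run; per-fraction normalization would require
fraction identifiers the evidence table does not carry.

## Ecology

Diversity is computed on rarefied counts: each sample is subsampled without
replacement to a common depth (default 6,359 reads, 10 replicates, seeded),
and indices are reported as mean ± s.d. across replicates. Samples
shallower than the depth are skipped with a warning by default. Simpson
diversity uses the Gini-Simpson form `1 - sum(p^2)` — the dominance and
inverse forms are available by flag and the form used is recorded in the
output metadata, since "Simpson index" is ambiguous in the literature.
Pielou evenness is `H / ln S` over taxa with non-zero counts and is
undefined (NA, not 0) for a single-taxon sample. Lipid accumulation is the
intracellular/extracellular concentration ratio per compound. Taxon-lipid
association uses Spearman correlation with average-tie ranks.

## The synthetic community generator

The generator produces a community with known ground truth and the
statistical structure the pipeline assumes, so that every stage can be
tested as a recovery problem.

Genomes come from an order-2 Markov chain — the minimal sequence model with
non-trivial pentamer structure. The chain's transition matrix starts from
the i.i.d. composition implied by the population's G+C target, is perturbed
per (dinucleotide state, base) by `exp(signature_bias * z)` with
population-specific standard normal draws, and is then recalibrated (a
bisection on a C/G column multiplier against the chain's stationary
distribution) so expected G+C matches the target exactly. Two populations
therefore differ in signature even at equal G+C; the default bias of 0.3
gives clearly separated CLR profiles, and the separability property is
checked by brute-force distance comparison in the tests.

Contigs tile each genome with log-uniform lengths on [1,000, 20,000] bp by
default (minimum 500 enforced), so concatenating them reconstructs the
genome. Genes are fixed 900-bp frames separated by 100-bp gaps, never
spanning contig ends (a generator simplification: coordinates stay simple
and per-gene counts unambiguous). MetaG counts are multinomial with
per-contig probability proportional to abundance × length; metaT counts are
multinomial over expressed genes with probability proportional to level ×
abundance × length, where per-gene levels are gamma-distributed (squared
coefficient of variation = `expression_dispersion`, default 0.5) — a
negative-binomial-type overdispersion, since fixed-rate Poisson counts are
unrealistically tight for expression. Each population's expressed genes are
an exact rounded fraction sampled without replacement, not i.i.d. coin
flips: `expressed_fraction` is a population parameter, and the exact
fraction makes it a recoverable ground truth.

True variants (`round(snp_per_kb * genome_length / 1000)` per population)
are placed uniformly without collision inside the population's expressed
genes, restricted to genes whose rounded metaT depth and whose contig's
rounded metaG depth reach 10: a variant without adequate coverage in both
libraries is unobservable by construction and would not be meaningful
ground truth for a pipeline whose filter requires both. A whole-genome
placement mode exists for tests that do not involve the depth filter. Each
synthetic caller reports the truth minus Bernoulli dropouts (default 2%)
plus uniformly placed false positives (default 5% of the true count);
with rates at zero every caller reports exactly the truth, which anchors
the exact-recovery check of the intersection-plus-filter pipeline.

Spectral evidence covers an exact rounded `proteome_detect_fraction` of
expressed genes, each with ≥1 peptide and ≥1 spectrum of log-normal
positive intensity — sparse detection, as in real metaproteomics.

The default benchmark community has five populations spanning G+C 0.35 to
0.65 at abundances 0.40/0.25/0.15/0.12/0.08, with genome lengths 1.7-2.1 Mb
(~1,500 contigs of at least 1 kb in total). The dominant population is a
"generalist": it transcribes 45% of its genes and carries a ten-fold lower
SNP density (0.2/kb) than the "specialist" second population (93%
expressed, 2 SNPs/kb) — the qualitative contrast the analysis is designed
to resolve. Library sizes are 4 × 10^6 reads per library so that the rarest
population reaches ~17× metaG coverage and ~29× mean metaT gene depth,
keeping all populations above the depth-10 variant filter.

What the generator does **not** emulate: sequencing errors, chimeric or
misassembled contigs, strain-level microdiversity within a population,
genome-scale composition heterogeneity (mobile elements, rRNA operons),
gene-length variation, partial gene models, or compositional biases of
library preparation. Passing recovery tests therefore demonstrates that the
implementation inverts its own generative assumptions correctly — not that
binning at these accuracy levels is attainable on real assemblies, where
signature overlap and fragmentation are harsher.

## Numerical choices and degenerate inputs

* CLR of an all-zero composition with pseudocount 0 is a domain error.
* EM raises a degeneracy error naming the component when one loses all
  support, and refuses more components than points.
* Bins with fewer than 4 contigs are never coverage-split (warning).
* Groups too small for re-embedding (fewer than `3 * perplexity + 2`
  eligible contigs) pass through round two unchanged, with a message.
* Ties in assignment posteriors resolve to the first component;
  sub-bin labels order by mean depth.
* Single-taxon evenness and constant-vector correlations return NA with a
  warning rather than a numeric sentinel.
* The pipeline's rarefaction depth is capped at the shallowest analysed
  sample so small simulated tables remain analysable; the depth actually
  used is written into the output metadata.

## Problem sizes

The test suite and the acceptance script run the full binning recovery on
the ~1,500-contig default community once (a few minutes of compute), and
exercise everything else on communities of two small populations
(~150 contigs), chosen so the whole suite completes comfortably on one
CPU. The embedding cost grows quadratically with contig count; communities
of up to a few thousand contigs are practical.

## Known limitations

* The embedding is exact-gradient; for very large contig sets (tens of
  thousands) a tree-approximated gradient would be needed.
* AAI uses full global alignment of all protein pairs to find reciprocal
  best hits; it is intended for the proteome sizes of single reconstructed
  genomes, not all-vs-all across large gene catalogues.
* The expression call is a hard threshold; borderline genes flip with
  sampling noise, which is why recovered expressed fractions carry ~1-point
  negative bias at finite sequencing depth (weakly expressed genes fall
  under the threshold).
* Variant identity is exact (contig, pos, ref, alt); no left-normalization
  is performed since only SNPs are modelled.
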