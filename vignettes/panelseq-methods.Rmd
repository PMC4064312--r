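---
title: "Methods: models, parameters and design choices in panelseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in panelseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelseq)
```

panelseq implements the analysis layer of a hybrid-capture targeted tumor
sequencing study of oropharyngeal (head and neck) squamous cell carcinoma,
in which two groups of tumors — HPV-positive and HPV-negative — are profiled
over a large cancer gene panel and compared at cohort level. The package
covers five analytic stages (substitution calling, indel assembly,
copy-number calling, viral-status classification, cohort statistics) plus a
synthetic cohort generator that provides fully ground-truthed inputs for all
of them. This vignette explains each model, its tunable parameters, and the
choices made where the underlying methodology left the design open.

## Bayesian substitution calling

At a pileup site with 4-allele read counts $R$, the caller evaluates the
posterior probability that a mutation is present,

$$P(F > 0 \mid R) \;=\; 1 - \frac{P(R \mid F=0)\,P(F=0)}{Z},$$

where $F$ is the mutant allele fraction and $P(F=0)$ the site prior of no
mutation. The likelihood $P(R \mid F)$ is multinomial: a read carries the
variant allele with probability $F$, and a per-base error $e$ moves any
observed base to each of the other three uniformly, giving alt-allele cell
probability $F(1-e) + (1-F)e/3$. The proportionality in the model statement
is resolved by normalising over a discrete grid of non-zero fractions —
by default 50 log-spaced points on $[0.005, 1]$ — that share the
complementary prior mass $1 - P(F=0)$ uniformly:

$$Z = P(R \mid F=0)P(F=0) + \sum_{g} P(R \mid F = g)\,\frac{1-P(F=0)}{|\mathrm{grid}|}.$$

This makes the posterior a proper probability without inventing a continuous
prior density. The reported allele-fraction estimate is the grid argmax of
the likelihood, which bounds its resolution at the grid spacing (about 11%
relative); at a 1% mutant fraction the neighbouring grid points are 0.96%
and 1.07%, both of which round to 1%.

Priors default to $P(F=0) = 0.999$ for ordinary sites, $0.99$ for
tissue-elevated sites and $0.9$ for hotspots. The methodology we follow
states only that hotspot sites receive elevated priors; the magnitudes are
package defaults chosen to expose the required ordering and are fully
configurable through `snv_params()`. The same holds for the call threshold
(posterior $\ge 0.99$ with $\ge 3$ supporting reads — the read floor
prevents single-read calls at extreme depth), and for the per-base error
rate: its magnitude is never stated by the source methodology ("empirically
observed error rates"), so the package defaults to $10^{-3}$ per base, a
typical post-filtering Illumina substitution rate. The error model is
global rather than per-substitution-type; this is the simplest symmetric
choice consistent with a multinomial likelihood.

Quality filters follow the count-level contracts: a Fisher exact test on
the allele-by-strand 2×2 table fails a site only when significant *and*
effectively one-stranded (minor-strand variant fraction < 5%), with totals
under 10 reads always passing (insufficient evidence); a read-position
filter fails sites whose variant offsets cluster tightly within 10% of a
read end, computed from summary statistics (mean and dispersion of the
offset fraction) because the package's input is count-level, not per-read.
Known-somatic annotation takes precedence over germline filtering, so a
recurrent somatic site present in both databases is never discarded as
germline.

## Indel detection by local assembly

Each targeted exon window is assembled de novo: reads are decomposed into
k-mers (default $k = 21$, retried at 31 when the graph is unanchored),
a de Bruijn graph is built, k-mers below support 2 are pruned, and anchored
haplotypes are enumerated by depth-first search with node revisits
forbidden (terminating repeat cycles), capped at 16 paths. Anchors are the
outermost *reference* k-mers with prunable-level read support, not the
literal window ends — short reads rarely start exactly at a window
boundary. Edges are kept whenever both endpoint k-mers survive pruning:
with staggered short reads, adjacent-k-mer co-occurrence within single
reads is much sparser than k-mer coverage itself, and pruning on edge
support would fragment genuinely supported haplotypes.

Haplotypes are aligned to the window by global affine-gap alignment
(match 1, mismatch −2, gap open 5, gap extend 1); alignment gaps become
VCF-style anchored indel calls, left-normalised within the window
(idempotently, stopping at the window edge so the anchored representation
keeps a preceding base). Each candidate is re-scored against the raw reads
by junction counting: occurrences of the variant junction sequence versus
the reference junction, each normalised by the number of read positions
that can span it (the two junction strings differ in length, and the
unnormalised ratio would be biased against long insertions). Calls below a 10%
supporting fraction are dropped; the floor sits well under the 20%
variant-fraction detection target so that junction-count sampling noise
(binomial, roughly 0.06 sd at typical coverage) rarely clips a true event.

## Copy-number model

An exon's expected log2 tumor/normal coverage ratio under absolute copy
number $C$, purity $p$ and tumor ploidy $\psi$ is the two-component
admixture

$$\mathrm{lr}(C) = \log_2 \frac{p\,C + 2(1-p)}{p\,\psi + 2(1-p)},$$

and the matching heterozygous-SNP B-allele fraction for minor copy number
$m$ is $(p\,m + (1-p)) / (p\,C + 2(1-p))$. The printed form of this
equation in the source methodology is typographically corrupted; the
interpretation above is the standard mixture used by the established
purity/ploidy methods it cites, and is dimensionally the only consistent
reading. Profiles are median-centred, segmented by penalised recursive
binary segmentation (no changepoint algorithm is named by the methodology;
the penalty defaults to $3\hat\sigma^2\log n$ with $\hat\sigma$ estimated
robustly from successive differences, which leaves a flat sd-0.1 profile of
3,230 exons unsplit while detecting single-gene events of a few exons), and
fitted by grid search over purity (0.05–1.00, step 0.01) and ploidy
(1.2–6.0, step 0.05), assigning each segment the integer copy number that
minimises the size-weighted Gaussian residual, with an equally weighted BAF
residual term where SNP data overlap a segment.

The likelihood surface has an exact whole-genome-doubling degeneracy: the
map $C \to 2C$, $\psi \to 2\psi$, $p \to p/(2-p)$ reproduces both the
log-ratio *and* the BAF expectations exactly, so no amount of data of
these two kinds distinguishes a solution from its double. Candidates
within one log-likelihood unit of the optimum (a doubled solution differs
only by grid discretisation) are therefore resolved deterministically
toward the lowest ploidy, then the highest purity. Profiles whose
segments all lie within noise of zero carry no copy-number information and
are flagged unidentifiable rather than assigned an arbitrary purity.
Focal events are called per gene from the modal exon copy number (ties
toward the more extreme value, matching focal-event intent): amplification
at $\ge 6$ copies, homozygous deletion at 0 copies, and never from samples
with purity $\le 20\%$ or unidentifiable fits.

## Viral read classification

Off-target viral reads recovered by capture are normalised to reads per
million sequenced read pairs; HPV status is positive at $\ge 5$ rpm and
negative at $\le 2$ rpm, both thresholds closed as printed. The open
interval between them maps to an explicit `indeterminate` status rather
than a forced binary call, mirroring the exclusion of borderline samples
in the study design. Whether the denominator is reads or read pairs is not
stated by the source; the package treats the supplied totals as pairs and
leaves the choice to the caller of `reads_per_million()`.

## Cohort statistics

Variant and copy-number calls are reduced to a samples × genes matrix with
cells in {none, mutation, amplification, deletion, multiple} (a gene with
both a small variant and a copy-number event is `multiple`). Per-gene
two-group enrichment uses Pearson's chi-squared test without Yates
correction (available by flag) on the altered/unaltered × group table,
restricted to genes altered in at least one sample, with Benjamini-Hochberg
FDR across the tested genes. Clinical covariates are tested by Wilcoxon
rank sum (ordinal coding never=0 < occasional=1 < heavy=2 for exposure
variables) except age, which uses a logistic group model with a Wald test;
perfect separation is flagged and the p-value suppressed. The Wilcoxon
implementation enumerates all group assignments exactly (handling ties) up
to a pooled size of 12 and otherwise uses the tie-corrected normal
approximation. Design power for the two-group comparison is the upper tail
of the noncentral chi-squared distribution with noncentrality
$N w^2$ beyond the central critical value; at $w = 0.5$, $\alpha = 0.05$,
$N = 40$, df = 1 this evaluates to 0.885.

Sample clustering binarises the matrix (any non-none call) and cuts a
hierarchical tree into two groups. The default distance is Hamming (simple
matching) with Ward linkage rather than Jaccard with average linkage: on a
sparse panel the *absence* of an alteration is informative — an unmutated
TP53 is itself characteristic of HPV-positive tumors — and Jaccard, which
ignores co-absences, places alteration-free samples at maximal distance
from every other sample, collapsing the two-group structure (mean cut
purity 0.68 on study-like prevalence simulations versus 0.96 for
Hamming/Ward). Jaccard and other linkages remain available as arguments
for denser matrices where co-absence is uninformative.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: two groups (HPV+ and HPV−,
20 samples each by default), group-specific gene alteration prevalences,
per-sample purity drawn on [0.3, 0.9] and tumor ploidy implied by the
drawn copy states. The default prevalence table follows the reported
cohort: TP53 mutation in 100% of HPV− and 5% of HPV+ samples, CCND1
amplification (55%) and CDKN2A/B deletion (40%) only in HPV−, PIK3CA
mutation and PTEN deletion enriched in HPV+ (35%/25% versus 10%/10%), and
FBXW7 (15%) and SOX2 amplification (12%) in both. Where the source prints
only a combined bound (PIK3CA/PTEN alterations in ">55%" of HPV+ tumors),
the split across the two genes is a package choice. The reported
CDKN2A/B prevalence is internally inconsistent in the source (≈40% in one
place, ≈55% in another); the generator uses 40%.

Every signal is generated from, and traceable to, a single truth record:
pileups are multinomial draws from the same error-mixture the caller
inverts, with the observed mutant fraction of a clonal heterozygous
variant scaled by purity and local copy state as
$p \cdot 1 / (p C + 2(1-p))$ — consistent with the copy-number mixture;
log-ratio profiles apply the expected-log-ratio equation plus Gaussian
noise (sd 0.15 by default); BAFs are binomial around the expected fraction;
exon reads tile a window uniformly at a target per-base coverage with the
variant haplotype drawn at its stated fraction; viral read counts are
binomial at a true reads-per-million rate (uniform 20–500 rpm for HPV+,
0–1 for HPV−, spanning the decision thresholds from both sides). Strand is
Bernoulli(0.5) independent of allele, and variant read offsets are uniform
unless an artifact signature is requested — so the strand- and
position-bias filters see null behaviour on clean data and can be driven
to failure deliberately.

What the generator does *not* emulate: FFPE damage chemistry, GC and
mappability bias, alignment and duplicate-marking artifacts, subclonal
copy number, and real germline variation. Passing tests therefore
demonstrate correctness of the inference given the stated generative
models, not robustness to every artifact of real FFPE capture data.

## Problem sizes and numerical choices

The test suite and examples run at deliberately desk-scale sizes chosen to
exercise every code path: panels of 20–30 genes (about 100 exons) instead
of the full 182-gene design, cohorts of 4–16 samples for end-to-end runs,
5,000 error-only sites for the specificity bound, 1,000 random count
configurations for posterior-oracle equivalence at $10^{-6}$, 20-replicate
purity recovery, and exon windows of ~260 bp at 100× coverage for indel
recovery across lengths 1–15. Degenerate inputs are defined behaviour
throughout: zero-depth pileups are rejected, zero-coverage exons dropped
with a log message, flat profiles flagged unidentifiable, zero-margin
contingency tables report p = 1 with a degeneracy flag, and
$\log_2(0)$ at full purity is floored at −8.

## Known limitations

Purity/ploidy fits on profiles with few distinct copy levels are weakly
identified beyond the doubling degeneracy (many integer assignments fit
within noise); rich profiles spanning several copy states, or BAF data at
imbalanced segments, are required for sharp recovery. The indel assembler
works per exon window and does not handle events longer than half a read,
assembly across exons, or structural variants. The caller models a global
substitution error rate; per-context error models would sharpen low-MAF
calling at hotspots. Rearrangement detection over the panel's intronic
baits is out of scope.
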