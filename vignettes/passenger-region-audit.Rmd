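---
title: "Auditing passenger-region confounding in knockout mouse transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing passenger-region confounding in knockout mouse transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passengerScan)
```

## The problem

A knockout mouse line made in one embryonic-stem-cell strain and
backcrossed into another retains a segment of donor-strain chromosome
around the targeted locus: linked loci resist recombination away, so
the "passenger region" survives many backcross generations.  Genes in
that segment differ between knockout and wildtype animals in *cis* —
promoter variants, expression-modifying SNPs — entirely independently
of the knocked-out gene's function.  A knockout-versus-wildtype
RNA-Seq comparison therefore mixes two signals: true downstream
effects of the missing gene and strain effects of the passenger
region.  This package implements the audit that separates them:

1. **Differential expression** on gene-level counts (exact
   negative-binomial test, Benjamini–Hochberg FDR).
2. **Signature shift analysis**: does a predefined gene set sit above
   or below zero in the fold-change distribution (sign test)?
3. **Strain-SNP density scan**: strain-informative variants per
   genomic window, with contiguous high-density regions called as
   candidate passenger segments.
4. **Positional enrichment**: are top differentially expressed genes
   over-represented inside the called region (chi-square and Fisher
   exact test on a 2×2 table)?
5. **Methylation comparison**: element-wise capture-coverage loads
   (TSS, exon, intron, intergenic) compared between groups, plus a
   per-TSS Pearson correlation.

A synthetic-data module generates all inputs with known ground truth,
so every stage is testable by parameter recovery at desk scale.

## Models and statistics

### Count model and the exact test

Counts follow a negative binomial,
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi)$ with
$\mu_{gj} = s_j \mu_g 2^{x_j \beta_g}$: $s_j$ a per-sample library
size factor, $x_j \in \{0,1\}$ the group indicator, $\beta_g$ the
signed log2 effect, and a single common dispersion $\phi$ (variance
$\mu + \phi\mu^2$; $\phi = 0$ is the Poisson limit).

*Normalization* uses median-of-ratios factors (median over genes of
the ratio to the per-gene geometric mean, rescaled to geometric mean
one).  *Dispersion* is estimated by pooled method of moments: each
(gene, group) cell with replication contributes
$\hat\phi_{gk} = (v - m\,c)/(m^2 - v/n)$, where $m, v$ are the
within-group mean and unbiased variance of normalized counts and
$c$ the group mean of $1/s_j$; cells are pooled by inverse-variance
weights $w = (c/m + \phi)^{-2}$, iterated three times from a median
start.  The naive pooled ratio $\sum(v - mc)/\sum m^2$ is dominated
by the few most-expressed genes under a heavy-tailed $\mu_g$
distribution; the weighting bounds each gene's influence.  No
per-gene (tagwise) shrinkage is attempted — a common dispersion is
sufficient for every check in the test suite and keeps the exact test
well-defined.

*The exact test* collapses each group's samples to a pseudo-count
$\tilde y = \mathrm{round}(\sum_j y_j / s_j)$ and conditions on the
two-group total $t$.  Group totals of $n$ i.i.d. NB draws with equal
means are $\mathrm{NB}(n\mu, \phi/n)$, so the conditional probability
of a split $(a, t-a)$ is proportional to
$f_{\mathrm{NB}}(a;\, n_A\hat\mu, \phi/n_A)\,
 f_{\mathrm{NB}}(t-a;\, n_B\hat\mu, \phi/n_B)$ with
$\hat\mu = t/(n_A + n_B)$.  The two-sided p-value sums all
conditional probabilities not exceeding the observed outcome's
probability (the "small-p" method), which reduces exactly to the
textbook two-sided binomial test at $\phi = 0$ with equal library
sizes.  The collapse is exact when all size factors are equal and an
approximation otherwise; the enumeration oracle in the test suite
covers the equal-size path, and the unequal-size path is exercised
only through simulation-level calibration (type-I error within
binomial error of nominal on a 10,000-gene null with log-uniform
library sizes in [0.7, 1.4]).

Note one consequence of anchoring factors at geometric mean one:
multiplying one sample's counts by a constant rescales *all* factors
by a common constant, so pseudo-counts change by one global scale and
p-values are invariant only approximately.  The property test asserts
exact invariance up to that single scale.

*Fold changes* are $\log_2\!\big((\bar y_B + 0.5)/(\bar y_A +
0.5)\big)$ on normalized group means; the pseudo-count of 0.5
(configurable) avoids infinities at zero counts and only matters for
very low-expressed genes.

*FDR* is the Benjamini–Hochberg step-up, implemented directly and
cross-checked against `stats::p.adjust`.

### Sign test

For a gene set, zeros are excluded (the classical treatment) and the
number of positive log2 fold changes among $n$ nonzero members is
referred to $\mathrm{Binomial}(n, 1/2)$; the two-sided p doubles the
smaller tail, capped at 1.  The test deliberately uses only signs: it
is insensitive to the heavy tails of fold-change estimates at low
counts.  Whether the published analysis tested against zero or
against the control set's median is not stated; we test against zero
and additionally report each set's median relative to the CON set
(`median_vs_con`).  Note the test is discrete: for $n = 100$ the
largest achievable p below 0.05 is ≈0.035, so a true null set
rejects at 0.05 in only ≈3.5% of realizations — and, conversely, any
single simulated realization of a null set has that probability of
failing a "p > 0.05" assertion, which is why the acceptance suite
evaluates that assertion by majority over three replicates.

### Window scan and region calling

Strain-informative variants (matched to a strain reference panel by
the full chromosome/position/ref/alt quadruple) are counted in
non-overlapping 50-kb windows (a variant at 1-based position $p$
falls in window $\lfloor (p-1)/w \rfloor$; the last window of a
chromosome is truncated).  Windows with at least `threshold` variants
are "hot"; maximal runs of hot windows, bridging up to `merge_gap`
consecutive cold windows, spanning at least `min_span` windows, are
called as regions.  Only the 50-kb window is taken from the source
analysis; the defaults `threshold = 5`, `merge_gap = 2`,
`min_span = 3` are this package's operationalization, chosen
conservatively against the simulated background rate (0.2 variants
per 50 kb gives a per-window hot probability below $10^{-6}$) and
fully configurable.  The scan runs on strain-labelled variants by
default, since the passenger signal is defined by donor-strain SNPs;
coding-only intersection is available but off by default for density
(the published method used the coding intersection for strain
linkage, not for density).

### Positional enrichment

The gene universe is every gene in the DE table with coordinates; a
gene is in-region when its interval overlaps the called region (any
overlap; midpoint mode available).  The 2×2 table (top-N by p-value,
ties broken by gene identifier, versus rest) × (in versus out) is
tested by Pearson chi-square *without* continuity correction and by
the Fisher exact test, with the sample odds ratio reported.  The
source analysis names only "chi square"; reporting both brackets the
unstated choice.  A zero margin leaves the chi-square undefined; the
Fisher p is still reported and the result flagged degenerate.

### Methylation comparison

Capture coverage is projected onto classified elements — TSS windows
(±1 kb around the strand-aware start; the window width is not stated
in the source and is a configurable convention), exons, introns,
intergenic gaps — as overlap-weighted coverage mass divided by
element length (per-bp load), so classes of different sizes are
comparable.  Per class, the two groups are compared by a two-sided
Mann–Whitney rank-sum test on the matched element universe (the
source says only "various statistical tests"; a t-test and a paired
signed-rank variant sit behind flags — the rank test is the default
because capture loads are strongly skewed).  Across TSS elements, the
two groups' loads are summarized by the Pearson product-moment
correlation.

## The synthetic world

`scenario_config()` presets encode the study designs: `GC` is the
pooled 2-vs-2 germinal-center comparison with the light-zone
signature up ($\delta_{LZS} = +0.5$), dark-zone down
($\delta_{DZS} = -0.5$) and the Ighv-like family up
($\delta = +1$); `activated` is the individually indexed 4-vs-4
design with those signs reversed; `naive` elevates the dark-zone
signature; `null` has no effects at all.  Defaults state the world
once:

* 12,000 expressed genes on five 100-Mb chromosomes — desk-scale but
  preserving the real proportions (a 20-Mb region holds ~4% of the
  genome and ~480 genes);
* baseline means log-normal (median 100 counts, sdlog 1.2),
  emulating a count matrix already filtered to expressed genes —
  which is also why the type-I calibration is clean: exact tests on
  totals below ~20 are visibly conservative by discreteness;
* common dispersion $\phi = 0.1$ (biological coefficient of
  variation ≈ 0.32, typical for inbred-mouse bulk RNA-Seq);
* library-size factors log-uniform in [0.7, 1.4], so normalization
  must actually work;
* one passenger region (chr2:40–60 Mb) with 200 cis-deregulated
  genes, effect magnitudes uniform in [1, 3] log2 units with random
  signs (region genes are up- *and* down-regulated — magnitudes are
  free parameters, the source gives none);
* strain-informative SNPs as a Poisson process: 10 per 50 kb inside
  the region versus 0.2 per 50 kb outside;
* methylation: per-element latent mean loads shared between groups
  (class means scaled by element length, log-normal spread sdlog 1,
  TSS bimodal between a methylated-promoter mode and an
  unmethylated-CpG-island mode at 2.5% of it), observed loads NB
  with dispersion 0.002 around the latent mean.  The near-Poisson
  dispersion reflects deeply sequenced pooled libraries aggregated
  over kb-scale elements; it is what makes the between-group per-TSS
  correlation exceed 0.99 under the null, as the real comparison
  showed.  An `inject_demethylation` factor multiplies one class's
  group-B means for power testing.

One global seed drives independent sub-streams per data type, so
regenerating one file never perturbs the others, and a fixed seed
fixes every emitted file byte-for-byte.

What the generator does **not** emulate: sequence content, read-level
sampling, mappability or GC biases, correlated gene programs (all
null genes are independent), linkage structure beyond the single
rectangular region, and per-gene dispersion variation.  A green test
therefore establishes that each stage recovers the parameters of this
stated world — not that the pipeline is robust to every artifact of
real libraries.

## Numerical choices and degenerate inputs

* Conditional probabilities are computed in log space and normalized
  by their maximum before exponentiation; outcome comparison uses a
  relative tolerance of $10^{-10}$ so ties at the observed
  probability are included deterministically.
* A two-group total of zero returns p = 1 (the only outcome).
* Dispersion estimates are clipped at zero; constant counts within
  groups give exactly zero.
* Ties in p-value rankings are broken by gene identifier, making
  top-N lists and reports order-independent and byte-reproducible.
* All internal coordinates are 0-based half-open (BED convention);
  VCF positions are 1-based and converted at the boundary.  A
  variant at position $p$ is inside exon $[s, e)$ iff
  $s < p \le e$.
* Zero-variance vectors make the Pearson correlation undefined; it
  is reported as `NA` with a message, never silently as 0 or 1.
* Gene sets whose members are absent from the DE table are flagged
  untestable; remaining sets proceed.

## Known limitations

* The pseudo-count collapse for unequal library sizes is an
  approximation (documented above), not edgeR's quantile adjustment.
* A single common dispersion understates uncertainty for genes with
  atypical biological variability.
* The region caller assumes one rectangular region per chromosome
  arm scale; overlapping or nested donor segments are merged or
  split purely by the run rule.
* The enrichment test treats genes as exchangeable units; gene
  length and expression-dependent detection power are not modelled.
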