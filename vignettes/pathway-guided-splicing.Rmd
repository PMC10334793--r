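---
title: "Pathway-activity-guided analysis of cassette-exon splicing"
author: "SpliceActivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-activity-guided analysis of cassette-exon splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceActivity)
```

## The problem

Oncogenic transcription factors such as MYC reshape alternative pre-mRNA
splicing indirectly: they change the expression of splicing factors, which
in turn shift the inclusion of particular cassette (skipped) exons. A
recurring analysis pattern for dissecting this in bulk RNA-seq cohorts is:

1. score each sample for the *activity* of the pathway, using a hallmark
   gene set as an expression proxy;
2. quantify the inclusion level (percent spliced in, PSI, denoted
   $\psi$) of every cassette exon in every sample from junction reads;
3. correlate $\psi$ (and splicing-factor expression) with the activity
   score within each cohort, adjusting for multiple testing;
4. compare the resulting "splicing programs" against programs obtained
   from perturbation experiments (e.g. splicing-factor knockouts), via
   overlap enrichment and Jaccard similarity; and
5. dissect individual exons mechanistically with cis-element maps:
   G-run (hnRNP H/F-binding) motifs in the flanking introns and antisense
   oligonucleotide (ASO) tiling screens.

`SpliceActivity` implements each stage behind a small S4 surface
(`SeEventSet`, `PsiExperiment`, `ActivityScores`, `NormalizedExpression`,
`OverlapResult`) and ships a synthetic cohort generator with known ground
truth, so the whole chain is validated by parameter recovery rather than
by eyeballing real cohorts.

## Models and formulas

### PSI from junction counts

For a skipped-exon event with inclusion junction count $I$, skipping
junction count $S$, and effective form lengths $l_I$ and $l_S$ (the number
of distinct read positions supporting each form),

$$\psi = \frac{I / l_I}{I / l_I + S / l_S},$$

missing when $I + S = 0$. This is the length-normalized inclusion ratio
used by junction-count splicing quantifiers; `readSeTable()` consumes the
standard `SE.MATS.JC.txt` tab-separated dialect directly, re-deriving any
stated `IncLevel` columns from the counts (counts are the source of
truth; disagreements beyond the dialect's 3-decimal rounding raise a
warning). All coordinates in the package are 0-based half-open.

### Pathway activity

Counts are normalized with median-of-ratios size factors (delegated to
DESeq2's implementation, the tool conventionally used for this step) and
transformed to $\log_2(\text{count}/s_j + 1)$. The default activity score
is **mean-z**: each gene-set gene is z-scored across the scoring group
(sample standard deviation, $n-1$ denominator; zero-variance genes
contribute 0), and a sample's score is the mean z across gene-set genes.
Scores therefore have mean zero within the scoring group, and the scoring
group should be one cohort's disease spectrum (pass that cohort's samples
explicitly for multi-cohort matrices). A rank-based single-sample
enrichment alternative (`method = "rank-ssgsea"`, a weighted running-sum
statistic on per-sample expression ranks with exponent 0.25) is exposed
behind a flag; no numerical equivalence with any external GSVA/ssGSEA
implementation is claimed, and downstream code treats scores opaquely.
Whether to z-score within a cohort or globally is genuinely open in this
kind of analysis; the package supports both and asserts neither as
canonical.

### Correlation engine

Per (event, cohort): Pearson $r$ between $\psi$ and the activity score
after pairwise deletion of missing PSI, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Records with
fewer than 10 complete pairs (configurable) report $r$ but withhold p:
the t-approximation is unreliable at tiny $n$. Benjamini-Hochberg
adjustment is applied within each cohort (events of one tumor type form
one family; pooled adjustment is available behind a flag). A permutation
p-value, $(1 + \#\{|r_\text{perm}| \ge |r_\text{obs}|\})/(B+1)$, is
provided as a distribution-free alternative. Note that BH is *not*
idempotent — re-adjusting an adjusted vector inflates non-maximal entries
— so adjusted values must never be fed back through `bhAdjust()`.

### Differential splicing between two groups

Replicate junction counts are pooled within each group (missing
replicates dropped, never imputed), and inclusion reads are modeled as
binomial draws from the total junction reads with read-level probability
$q(\psi) = \psi l_I / (\psi l_I + (1-\psi) l_S)$. Because $q$ is monotone
in $\psi$, the within-group MLE is the PSI formula applied to pooled
counts, and the likelihood-ratio statistic $2(\ell_1 - \ell_0)$ is
referred to a 1-df chi-square. This pooled LRT is a deliberate
simplification of hierarchical replicate models: the reproducible
contract here is the *filter chain*, not a specific tool's test
internals. Significant events are those with mean junction reads per
event strictly greater than 10, $|\Delta\psi|$ strictly greater than
0.05, and FDR strictly below 0.05. "Junction reads per event" is
summarized as the mean of $I+S$ over all samples by default; whether the
conventional ">10" filter means the mean, minimum, or sum over samples is
ambiguous in the field, so all three are configurable
(`read_stat = "mean" | "min" | "sum"`).

### Program overlap

Events are matched across comparisons purely by coordinates —
`(chrom, strand, exonStart, exonEnd)`, optionally plus the flanking exon
coordinates in strict mode — because event-id strings differ between
quantifier runs, and the *direction* of the inclusion change is ignored
when intersecting. Overlap enrichment is the one-sided upper tail
$P(X \ge k)$ of the hypergeometric distribution, computed in log space so
extreme enrichment probabilities (down to $10^{-300}$ and below) remain
representable; similarity is the Jaccard index $|A \cap B|/|A \cup B|$.
The universe size $N$ is a required, logged input. The recommended
default is the set of events quantifiable (passing the coverage filter)
in both comparisons — the most defensible background when the original
universe of a published probability is unstated — and any reported
probability should state the $N$ used.

### Cis-element maps

G-runs are maximal runs of $\ge 3$ consecutive guanines on the sense
(pre-mRNA) strand, classed `G3` (exactly 3) versus `G4plus` ($\ge 4$) —
the motif lengths bound by hnRNP H/F. Maximal-run semantics avoid
double-counting overlapping GGG/GGGG matches; whether published "G-run
counts" use $\ge 3$ or exactly {3,4} is usually unstated, and the
`min_len` argument makes the choice explicit. ASO tiles are 18-mers by
default, laid abutting from the window start (any sub-tile remainder is
reported uncovered) or at explicit scheduled offsets with recorded
overlaps; tile sequences are reverse complements of the sense window, and
backbone chemistry is metadata, not modeled. Per-ASO effects are called
with a two-sided equal-variance Student's t-test against the nontargeting
control (Welch behind a flag): a significant increase in inclusion marks
a blocked *silencer*, a decrease a blocked *enhancer*. Raw per-ASO calls
at $\alpha = 0.05$ match how tiling screens are conventionally
annotated (uncorrected per-ASO asterisks); BH-adjusted calls across the
panel are always emitted alongside. Element maps are emitted as BED6 with
strand-aware mirror mapping of local window offsets to genomic
coordinates.

## What the synthetic cohorts emulate

`simulateCohort()` draws, per sample $i$, a latent pathway activity
$a_i \sim \mathcal N(\mu_{\text{stage}}, \sigma_{\text{stage}})$ along an
ordered disease spectrum; the default is 300 samples in three stages
(normal / benign / tumor, 100 each) with means 0, 1, 2 and within-stage
sd 0.5, a desk-scale caricature of activity rising with disease
progression. Hallmark gene counts are negative binomial
(variance $= \mu + \mu^2/\theta$, $\theta = 10$, baseline means
log-normal around 300) with mean $\mu_g 2^{\beta_g a_i}$; the default
$\beta_g = 1$ per unit activity. Event coverage is NB with mean 100 and
dispersion 10 per event and sample; true inclusion follows a logit link
$\psi_i = \mathrm{logistic}(b_0 + b_1 a_i)$, and inclusion reads are
binomial in the total with the length-weighted probability $q(\psi)$
above (form lengths 198/99, a 100-nt read geometry). Coupled events in
validation runs use slopes $b_1 \in [-2, -1]$ — moderately repressed
exons on the logit scale; no published effect-size distribution exists
for activity-coupled exons, so this range is a package choice, stated
here and not claimed from any external source. `simulateTwoGroup()`
plants fixed $\pm\Delta\psi$ shifts (clamped to [0.01, 0.99], with the
baseline redrawn if clamping would erode the plant) on a
Uniform(0.1, 0.9) baseline. `simulateGRunSequence()` plants maximal
G-runs in a G-free background so a scanner must recover exactly the
recorded intervals.

What the generator deliberately does **not** model: batch effects,
library-composition artifacts, isoform-level coupling between events of
one gene, correlated gene-gene noise, empirical (non-Gaussian) activity
distributions, and read-level errors. Passing recovery tests on these
cohorts therefore demonstrates that the *statistics are implemented
correctly and are calibrated under their own assumptions* — not that
real-cohort effect sizes will be recovered at the same rates.

Every simulator takes an explicit seed, uses one private RNG stream, and
restores the caller's RNG state; identical seeds give byte-identical
outputs.

## Numerical choices and degenerate inputs

- Zero-variance variables (constant PSI, flat genes) are flagged
  unevaluable in correlation records, never raised as errors; $|r| = 1$
  maps to $p = 0$.
- In the LRT, $0 \log 0 = 0$; the statistic is clamped at 0 against
  floating-point negatives; events with zero pooled reads in either group
  are skipped and reported, outside the BH family.
- Size factors with an even number of zero-free genes follow DESeq2's
  log-space median interpolation (4th-decimal differences from
  arithmetic interpolation are expected and harmless).
- Hypergeometric tails use `phyper(..., log.p = TRUE)`;
  `hypergeometricTail(..., log.p = TRUE)` returns finite log
  probabilities even when the probability itself underflows.
- Jaccard of two empty sets is defined as 0 with a warning; ranked
  Jaccard tables break ties by set name for deterministic output.
- GMT duplicate genes collapse with a warning; duplicate FASTA ids and
  non-integer count cells are errors; RNA `U` is normalized to `T` on
  FASTA read.

## Validation problem sizes

The shipped test-suite and `scripts/acceptance.R` exercise, as the
package's chosen validation scale: one 300-sample / 500-event cohort with
25 repressed exons for pipeline recovery; five 2,000-event null cohorts
for correlation-p calibration (KS); five 2,000-event null and five
500-event planted two-group experiments (3 vs 3, coverage 100,
$|\Delta\psi| = 0.3$) for LRT calibration and power; exhaustive
hypergeometric enumeration to $N \le 12$; 1,000 random p-vectors against
a step-up BH oracle; and 1,000 random 500-nt sequences against a regex
G-run oracle. On these conditions the pipeline recovers ~100% of planted
exons with planted sign at $p_{\text{adj}} < 0.05$, flags well under 5%
of null events, and passes all oracle comparisons at $10^{-12}$.

## Known limitations

- The pooled LRT understates between-replicate variability relative to
  hierarchical models; with very few, highly variable replicates its
  p-values can be anticonservative.
- Mean-z scores depend on the scoring group's composition; scores from
  different cohorts are not on a common scale and should not be pooled
  without explicit cross-cohort scoring.
- Only skipped-exon (SE) events are supported; other event classes
  (MXE/A5SS/A3SS/RI) are rejected with a clear message at the table
  reader, which checks the SE column dialect.
- Supplementary event lists distributed as spreadsheets should be
  exported to the SE-dialect TSV before reading; the package reads only
  plain-text formats (TSV, GMT, FASTA, BED).
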