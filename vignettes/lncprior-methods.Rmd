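---
title: "Methods: integrative prioritization of candidate disease-associated lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative prioritization of candidate disease-associated lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprior)
```

## The scientific problem

Long non-coding RNAs (lncRNAs) are abundant in the human brain and largely
uncharacterized.  When a lncRNA is dysregulated in affected cortical tissue
*and* tightly co-expressed with known risk genes across normal brain
development, guilt-by-association makes it a strong disease candidate.
`lncprior` implements that integrative argument as a single reproducible
pipeline over five evidence channels:

1. **Differential expression** in a small case/control cortical RNA-seq
   design (negative-binomial Wald test).
2. **Tissue selectivity** from a multi-tissue median-expression panel
   (fractional brain expression).
3. **Developmental co-expression**: a signed weighted network over a brain
   developmental time course, with modules detected from topological
   overlap.
4. **Association statistics**: permutation tests for module coherence,
   module-level differential-expression overlay, and summed lncRNA/risk-gene
   co-expression, plus Fisher-exact gene-set enrichment per module.
5. **Genetic lesions**: overlap counts against disease-associated CNVs,
   used as the within-module tie-breaker of the final ranking.

Because the original external datasets (case/control cortex, the
developmental transcriptome, the tissue atlas, curated risk-gene and CNV
lists) cannot be bundled, the package ships a seeded synthetic-data
generator that emulates their *shapes* with planted structure, giving every
downstream stage a known ground truth.

## Differential expression

Counts for gene $g$ in sample $j$ are modelled as
$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and
$\log \mu_{gj} = \beta_{0g} + \beta_{1g}\,x_j + \log s_j$, where $x_j$
indicates the case group and $s_j$ is a median-of-ratios size factor
rescaled to geometric mean 1.  Technical replicates are summed into their
biological sample before testing: the NB model assumes independent
biological units, and count-level collapse preserves the sampling model.

The dispersion is a pooled within-group moment estimate on normalized
counts, $\hat\alpha_g = \max\{10^{-8}, (s^2_g - \bar\mu_g)/\bar\mu_g^2\}$,
linearly shrunk toward the across-gene mean.  The per-gene moment estimate
keeps weight `mom_weight = 0.25` and the shared mean receives the rest.
The strong shrinkage is deliberate: at three samples per group the raw
moment estimate is right-skewed, so most genes *under*-estimate their
dispersion and the Wald test becomes anticonservative.  With the default
weight, a null simulation (5000 genes, dispersion 0.1, 3 vs 3) yields a raw
p < 0.05 fraction of about 0.055–0.061, and sensitivity on the planted
fixture is unaffected.  The acceptance suite re-measures this calibration.

Each gene is fit by IRLS at its fixed $\hat\alpha_g$; the Wald statistic
$\hat\beta_1/\mathrm{SE}$ is referred to the standard normal (two-sided),
p-values are Benjamini–Hochberg adjusted across converged genes, and a gene
is significant when adjusted $p < 0.05$ **and** $|\log_2 \mathrm{FC}| \ge
1$ (the fold-change bound is inclusive).  Positive $\log_2$FC means higher
in cases.  Genes with zero mean are flagged untestable; non-converged genes
are reported, not silently dropped, and excluded from the BH denominator.

## Tissue selectivity

Tissues with fewer than 50 samples are removed (a tissue with exactly 50 is
kept).  For a gene with nonnegative abundances $x_t$ over the retained
panel, fractional brain expression is
$100 \cdot \sum_{t \in \mathrm{brain}} x_t / \sum_t x_t$; a gene is
brain-selective when this strictly exceeds 50% (the strict comparison is a
package choice, configurable, since equality is a measure-zero event on
real data).  All-zero genes are reported as `NA` and never selective.
Cross-tissue Z profiles use the population (n-denominator) standard
deviation — they normalize profiles for display and clustering, they are
not inferential — and constant profiles return zeros with a flag.  The
matrix is treated as unit-agnostic nonnegative abundance (RPKM, FPKM and
TPM are all acceptable inputs).

## The signed co-expression network

Genes below the median across-sample variance are removed first (bottom two
quartiles); ties at the median are kept, so an all-equal-variance matrix
passes through intact.

Pairwise similarity is the biweight midcorrelation: with
$u_i = (x_i - \mathrm{med}(x)) / (9\,\mathrm{MAD}(x))$ (MAD unscaled — the
9·MAD tuning convention), weights $w_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1]$
and deviations $d_i = (x_i - \mathrm{med}(x))\,w_i$,
$\mathrm{bicor}(x,y) = \sum d_i e_i / \sqrt{\sum d_i^2 \sum e_i^2}$.
A vector with zero MAD (or all-zero weights) cannot be biweighted; every
pair involving such a vector falls back to the Pearson correlation, and the
matrix and pairwise code paths implement identical semantics.

The signed adjacency is $a_{ij} = ((1+c_{ij})/2)^{\beta}$ with $\beta = 12$,
so anti-correlated genes are effectively disconnected.  Topological overlap
is
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$ and
$k_i = \sum_{u \ne i} a_{iu}$; $1 - \mathrm{TOM}$ is the clustering
dissimilarity under average linkage.

**Tree cut.**  Modules are branches obtained by cutting the dendrogram at
`cut_quantile` (default 0.99) of its **maximum** merge height; clusters
smaller than `min_module_size = 30` become `"unassigned"`.  The fraction of
the total height — rather than a quantile of the merge-height
distribution — is used deliberately: on TOM dissimilarities the
unstructured genes merge in a dense plateau just below the dendrogram top,
so any quantile of the height *distribution* lands inside that plateau and
cuts arbitrarily, while module branches join far below it.  A hybrid-style
refinement (`cut_method = "hybrid"`) optionally pulls unassigned genes with
module membership above `refine_kme = 0.7` into their best module.
Eigengene-based module merging exists behind `merge_threshold` but is off
by default.

Modules are named by size rank with stable color-style labels.  The module
eigengene is the first principal component of the standardized module
submatrix, oriented to correlate positively with the module's mean profile
and scaled to unit variance; per-gene module membership is the correlation
of the gene's profile with its module eigengene.  Per-module Pearson
correlation with sample age summarizes developmental trajectories.

## Permutation and enrichment statistics

All three permutation tests draw random gene sets of matching size, without
replacement, from all network genes, and report the add-one empirical
p-value $(r+1)/(B+1)$ — it can never be zero and is bounded below by
$1/(B+1)$, consistent with reporting $p < 10^{-4}$ at $B = 10{,}000$.
P-values are BH-adjusted across the targets of each run.

* **Module co-expression**: observed statistic is the mean correlation over
  all within-module pairs; one-sided greater.
* **DE overlay**: each network gene carries its estimated $\log_2$FC if
  significant, otherwise 0 (genes never tested also contribute 0); the
  statistic is the module mean, and the p-value is two-sided around the
  permutation mean because modules can be coherently up- or down-regulated.
* **Summed lncRNA/gene-set co-expression**: the sum of correlations over
  all (lncRNA, set-gene) pairs with self-pairs excluded; the lncRNA set
  stays fixed while the gene set is permuted; one-sided greater.

Gene-set enrichment per module is the one-sided Fisher exact test
(hypergeometric tail $P(X \ge a)$) on the module × set 2×2 table over a
configurable universe (default: all network genes, assigned or not).  The
odds ratio is the sample $(ad)/(bc)$ with a Haldane 0.5 correction on all
cells when any cell is zero; a set is *enriched* only when adjusted
$p < 0.05$ **and** OR $> 1$.  The same function doubles as a generic
overrepresentation engine for any user-supplied term→gene map.

## CNV overlap and the final ranking

A gene overlaps a CNV when the intervals share at least one base on the
same chromosome (no minimum reciprocal overlap; strand ignored).
Coordinates are 0-based half-open internally and on disk, so abutting
intervals do not overlap; 1-based inclusive inputs are converted at the
boundary with an explicit flag.  Only CNVs with report class `"Major"`
enter the pipeline by default.

Candidates are the significantly differentially expressed lncRNAs present
in the network.  Ranking is module-first: tier 1 = modules enriched for at
least one risk-gene set, tier 2 = modules enriched for the DE-lncRNA set
only, tier 3 = the rest.  Within a tier, modules are ordered by their best
enrichment adjusted p-value (the cross-module order within a tier is not
dictated by the source procedure; this choice is deterministic and
configurable).  Within a module, candidates sort by descending CNV overlap
count; remaining ties break by descending $|\log_2 \mathrm{FC}|$ and then
gene id.  Candidates missing from an evidence table get `NA` and sort last
within their group, with a warning.

## The synthetic-data generator

One `sim_config()` drives all generators, and a shared deterministic ground
truth guarantees cross-table consistency: the first planted module hosts
both the planted candidate lncRNAs (forced into the DE set, down-regulated)
and the protein-coding risk genes; the designed top candidate is
additionally brain-selective and covered by five planted CNVs.

Key defaults and what they emulate:

| parameter | default | rationale |
|---|---|---|
| `n_case`, `n_control`, `n_tech_reps` | 3, 3, 2 | the original case/control design: three cases and controls, two technical replicates each |
| `de_fraction`, `de_log2fc` | 0.05, 2 | planted effects detectable at this depth; DE baselines kept at mean ≥ 100 |
| `nb_dispersion` | 0.05 | moderate biological variability for bulk brain tissue |
| `module_sizes` | 100/80/60/40 | scaled-down module size spectrum |
| `module_strength` | 0.7 | latent-factor loading at which recovery is challenging but expected |
| `n_dev_samples`, `age_range_months` | 100, 2–12 | developmental window from 2 months post-conception to one postnatal year, log-uniform (dense prenatal sampling) |
| `n_tissues`, `n_brain_tissues` | 25, 5 | a tissue atlas with a brain subset; 3 tissues get < 50 samples to exercise the filter |
| `brain_inflation` | 20 | puts planted selective genes safely above the 50% rule under lognormal noise |
| `n_cnvs` | 60 | planted hits (5/2/1) on the top candidates plus random background intervals |

Module latents follow a round-robin of trajectory kinds — monotone in
log-age, sinusoidal, and age-flat (a shared random factor, i.e. co-expressed
but development-independent).  Repeated kinds are made mutually separable:
monotone repeats flip sign, sinusoids use successive cosine harmonics
(orthogonal to the monotone trend over the log-age window), and each flat
module draws a fresh factor.  Without this, two modules could share one
latent and be unrecoverable in principle.  Member genes follow
$x = r f_m(\mathrm{age}) + \sqrt{1-r^2}\,\varepsilon$; a block of equally
variable background genes is unstructured, and all remaining genes get low
variance so the variance filter removes exactly the uninformative half.
The final matrix is globally shifted to be nonnegative (correlations are
shift-invariant).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no read-level or mapping noise (counts are drawn
directly), no batch or donor effects, no correlated module overlap or
nested module hierarchy, no mean–dispersion trend, no expression-dependent
ascertainment of lncRNAs, Gaussian developmental noise without outliers
(the robustness of bicor is exercised by dedicated outlier fixtures, not by
the default generator).  Recovery rates on this fixture are upper bounds on
what messier real data would give.

## Numerical choices and degenerate inputs

* Empirical p-values always carry the $+1$ correction; permutations are
  seed-deterministic, and the pipeline derives independent per-stage seeds
  from one master seed so changing $B$ in one test does not perturb others.
* The eigengene sign is fixed against the module mean profile; an exactly
  constant eigengene is an error, not a silent zero.
* Variance-filter ties keep the gene; Fisher zero cells use Haldane 0.5 on
  all cells; ranking ties end at lexicographic gene id, making every output
  deterministic and row-order invariant.
* Readers reject rather than coerce: negative or non-integer counts,
  duplicated gene ids, unknown biotypes, inverted intervals and mismatched
  sample sheets all raise errors naming the offending line where possible.
* `collapse_technical_replicates` refuses replicate groups spanning
  conditions.

## Problem sizes used by the test and acceptance suites

The shipped suites run the pipeline at the default fixture scale: 1200
genes (600 entering the network), 100 developmental samples, four planted
modules, 3 vs 3 with technical duplicates, and a 25-tissue panel.
Calibration checks use 5000-gene null simulations for the Wald test and 200
replicate noise datasets at $B = 500$ for each permutation test; the
acceptance script uses $B = 2000$ permutations.  These sizes keep full runs
in the minutes range on a single core while leaving every statistic
well-resolved at the thresholds it is tested against.

## Known limitations

* The NB test is a deliberately simplified, fully specified estimator — a
  pooled moment dispersion with linear shrinkage and a normal-reference
  Wald test.  It is calibrated by construction on its null simulation but
  lacks the empirical-Bayes machinery (trended priors, Cook's distance
  outlier handling, independent filtering) of full-featured DE packages;
  absolute DE counts on real data will differ from those tools.
* The static height cut is simpler than deep-split dynamic cutting; very
  close or nested modules may merge.  The hybrid refinement recovers
  borderline genes but not nested structure.
* Fractional brain expression depends on the tissue panel composition;
  adding or removing tissues changes the denominator and hence the 50%
  call.
* CNV overlap counts ignore CNV type (gain vs loss) and dosage, as does the
  ranking rule they feed.
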