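---
title: "Methods: fusion screening and tumor-specific signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion screening and tumor-specific signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcsig)
```

## The analysis this package implements

Fibrolamellar carcinoma (FLC) is a rare liver cancer of adolescents and young
adults, defined molecularly by the *DNAJB1-PRKACA* chimeric transcript that
arises from a ~400 kb heterozygous deletion on chromosome 19. `flcsig`
re-implements, as composable and tested functions, the computational chain
used to find fusion-positive tumors in large RNA-seq compendia and to derive
an FLC-specific expression signature against hepatocellular carcinoma (HCC)
and cholangiocarcinoma (CCA) comparators:

1. **Fusion screen** — count split reads and spanning pairs at a defined
   junction on a fusion contig; call samples positive.
2. **Deletion confirmation** — segment binned tumor/normal coverage ratios by
   circular binary segmentation (CBS) and require a segment that completely
   encompasses the deletion interval with mean ≤ −0.1.
3. **Differential expression** — median-of-ratios normalization, a
   negative-binomial (NB) Wald test with trend-shrunk dispersions, and the
   discovery filters (fold change ≥ 2, FDR < 0.05, > 50 normalized counts in
   at least one group), intersected across the two comparator contrasts with
   concordant direction.
4. **Clustering view** — variance-stabilizing transformation (VST), top-K
   most-variable features, Ward (`ward.D2`) clustering on Euclidean
   distances, a monophyly (clade-purity) check, and centered PCA.
5. **Signature selection** — the quantile-separation rule: a feature
   qualifies iff *every* target sample lies beyond the q-th percentile
   (default 0.95) of the pooled comparator samples; plus cross-tumor
   fold-change and abundance ranking.
6. **Enrichment** — one-sided hypergeometric over-representation of the
   signature in GMT gene-set libraries, reported only at overlap ≥ 5.

The consortium data behind the original analysis are controlled-access, so
the package ships a synthetic cohort generator whose planted ground truth
makes every stage testable end to end.

## The synthetic cohort generator

`simulate_counts()` draws counts
$k_{ij} \sim \mathrm{NB}(\mu = s_j\,q_i\,2^{e_{ij}},\ \alpha(q_i))$ with

* $q_i$ — per-feature baseline mean, log-normal (default median 150,
  $\sigma_{\log} = 1$), the order of magnitude of moderately expressed genes
  in bulk RNA-seq;
* $s_j$ — per-sample depth multiplier, log-normal with
  `library_size_logsd = 0.25` (a few-fold depth spread, typical for
  compendium data), or planted explicitly;
* $\alpha(\mu) = a_0 + a_1/\mu$ — the mean-dispersion trend (default
  $a_0 = 0.01$, $a_1 = 1$), i.e. ~10% biological coefficient of variation at
  high counts plus shot noise, which is the variance family the downstream
  NB test assumes ($\mathrm{Var} = \mu + \alpha\mu^2$);
* $e_{ij}$ — planted log2 effect for signature features in the target
  cohort's tumor samples, default 16 features at effect 5. Planted baselines
  are drawn with median 100 so that every planted marker clears the 50-count
  floor and the 95%-separation rule *by construction* — the generator defines
  recoverable study conditions, it does not grade them.

Default cohort sizes are 6 (FLC-like), 60 (HCC-like) and 30 (CCA-like)
tumors: the same 1:10:5 imbalance, scaled down, as the 6/263/36 discovery
setting, keeping the small-target-group statistics (the hard part) while
fitting a laptop-scale run.

What the generator deliberately does **not** emulate: batch effects beyond
per-sample depth, isoform structure, sequencing-error models, tumor-purity
mixtures, or correlated genes. Passing tests therefore demonstrate that the
*methods* behave to contract under their stated model — not that real TCGA
cohorts would yield the same gene lists.

`simulate_fusion_reads()` emits coordinate-sorted SAM records on a synthetic
fusion contig: junction reads guaranteed ≥ `min_anchor` aligned bases on
both sides of the breakpoint, spanning proper pairs with mates entirely on
opposite sides, and single-sided background reads. Alignment itself (done by
a chimeric aligner upstream in practice) is out of scope; simulating the
*aligned* records keeps the evidence counter exactly testable.
`simulate_binned_coverage()` plants a deletion as an expected log2 ratio
(default −0.15: a heterozygous loss diluted by tumor purity) over a bin
interval, with Gaussian noise on the log ratio; coverage values are
real-valued so the noiseless contract is exact.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_anchor` | 8 | bp | standard split-read practice: enough sequence on each side to make the junction alignment specific |
| `min_junction`, `min_spanning` | 2, 1 | reads, pairs | operationalize "robust evidence"; exposed because the original thresholds are not published |
| CBS `alpha`, `n_perm`, `min_width` | 0.01, 1000, 3 | —, permutations, bins | permutation test resolution 1/1000 matches the 0.01 level; 3-bin minimum forbids single-bin segments |
| deletion `mean_threshold` | −0.1 | log2 | the published segment-mean cutoff for the chr19 deletion |
| DE `fc_min`, `fdr_max`, `count_floor` | 2, 0.05, 50 | fold, —, normalized counts | the published discovery filters; the floor applies to group means, in at least one group, and is dropped for lincRNA-style runs |
| `pseudocount` | 1 | normalized counts | keeps fold changes finite at zero means; converges to the raw filter as depth grows |
| cluster `top_k` | 10000 genes / 500 lincRNAs (pipeline default 1000 at synthetic scale) | features | the published most-variable cutoffs |
| separation `q` | 0.95 | quantile | the "beyond 95% of all comparator samples" rule; 0.90 is the published lincRNA relaxation |
| enrichment `min_overlap` | 5 | genes | the "at least 5 genes in each category" display rule |

## Numerical and design choices

**NB test.** The original analysis used DESeq's exact NB test. Exactness of
that particular test is not required by any downstream contract, so the
package uses a fully documented NB Wald test: per-feature method-of-moments
dispersions on normalized counts, a gamma-family regression of dispersion on
$1/\mu$ for the trend, the conservative rule
$\alpha = \max(\alpha_{\text{feature}}, \alpha_{\text{trend}})$, and a
two-sided normal p-value on the log fold change with delta-method variance
$\widehat{\mathrm{Var}}(\log \bar z_g) = \sum_{j \in g} s_j^{-1} / (n_g^2 \bar z_g) + \alpha / n_g$.
Calibration is verified by simulation (null 6-vs-60 cohorts keep the raw
p < 0.05 fraction near nominal and the filtered discovery count at zero);
any NB test with this calibration property could be swapped in.

**Size factors** are classic median-of-ratios; the estimate requires at
least one feature with positive counts in every sample and fails loudly
otherwise. BH adjustment runs across features with non-zero total counts
only; no further independent filtering is applied.

**VST.** Integrating $1/\sqrt{v(\mu)}$ for
$v(\mu) = (1 + a_1)\mu + a_0\mu^2$ gives the closed form
$u(x) = \log_2\{(2a_0x + b + 2\sqrt{a_0(a_0x^2 + bx)})/(4a_0)\}$, $b = 1 + a_1$,
which approaches $\log_2 x$ at high counts and degenerates to the Poisson
square-root stabilizer as $a_0 \to 0$. Variance is computed on VST values
(not raw counts) for the most-variable ranking, since the transformation
precedes clustering in the procedure being reproduced; a raw-variance
ranking would mostly select high-abundance features. Ties in the ranking are
broken by feature identifier so results are order-independent.

**Ward variant.** `ward.D2` semantics (plain Euclidean distances in,
Lance–Williams update on squared distances) — the published description
("Euclidean distance and Ward's minimum variance method") does not pin the
variant, and `ward.D2` is the one that actually implements Ward's criterion
on distance input. A naive $O(n^3)$ implementation serves as the test
oracle. PCA is centered but not scaled, because the VST already stabilizes
scale.

**CBS.** The "circular" statistic is the maximum over arcs $(i, j]$ of the
two-sample mean-shift statistic against the arc's complement, with a
permutation reference (early-stopped once significance is impossible) and
recursion into the accepted split — the core of published CBS without its
pruning/undo refinements, which do not change the segment contract here.
Permutations are seeded, so segmentations are reproducible.

**Bin ratios.** Ratios are the literal per-bin tumor/matched-normal ratio
on the log2 scale. Library-depth rescaling is available
(`depth_normalize = TRUE`) for libraries of unequal depth; it is off by
default because the matched-pair formula is the published one, and on a
short simulated window (where the deletion is a large fraction of all bins)
depth rescaling visibly shifts segment means — an artifact that vanishes at
genome scale. The published deletion interval `chr19:14239803-14624494` is
quoted 1-based inclusive and converted to 0-based half-open internally.

**Fusion evidence denominators.** `n_locus_reads` counts primary reads on
the contig, each mate once; both percentages use this denominator. The
original reports "percentage of reads" without defining the denominator, so
one convention must be fixed; this one is the simplest to reason about.
Junction overlap uses aligned span only — a soft-clipped read whose clip
abuts the breakpoint is *not* junction-overlapping, trading a little
sensitivity for determinism without re-alignment.

**Quantile-separation reading.** "Beyond 95% of all HCC and CCA samples" is
read as one pooled comparator quantile per feature (the literal reading of
*all ... samples*), estimated by linear interpolation of order statistics
(type 7) — with 90 comparator samples the estimator choice is visible, so it
is fixed and documented. The candidate universe is the concordant DE set, as
in the original ("among the 163 genes"); both choices are arguments.

**Count-floor ordering.** The floor is applied together with the other
filters after testing (the published Methods state the criteria jointly);
`floor_required = FALSE` reproduces the lincRNA variant that states no
floor.

**Enrichment.** A plain one-sided hypergeometric test replaces the combined
score of the web service used originally; the service's score blends a
rank-based z with Fisher p against its own library snapshots, which are
external artifacts, not methods. Identifiers are harmonized to upper case;
the default universe is the set of features tested for DE.

## Problem sizes and determinism

The test suite and the acceptance script run the full discovery chain at
10,000 features × 96 samples per seed (10-seed sweeps), 20-seed null
calibrations, 200-bin CBS profiles, and 20 fusion-evidence configurations —
sizes chosen so a complete run finishes in a few minutes on one core while
keeping the small-group statistics of the original design. Every stochastic
step takes an explicit seed (simulation specs, CBS permutations, the
pipeline master seed), and identical configurations reproduce results
bit-for-bit; the only platform sensitivity is ordinary floating-point
rounding in distances and p-values.

## Known limitations

* The NB Wald test is slightly conservative at extreme imbalance; it is a
  calibrated stand-in for, not a clone of, the historical exact test.
* CBS omits pruning/undo, so very long, low-amplitude shifts adjacent to
  detected segments can fragment differently than in the full procedure.
* The quantile-separation rule with 6 target samples is sensitive to a
  single outlying target sample by design ("all samples" is the contract).
* The generator's independence across features means clustering results on
  synthetic data are easier than on real, correlated transcriptomes.
* Real-data headline numbers (444/1509/163 DE genes, the 16-gene signature,
  6.4×/7.0× next-type ratios) require controlled-access cohorts and are not
  reproduced here; the package verifies the methods' contracts on planted
  truth instead.
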