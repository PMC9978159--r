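---
title: "Strain-level ASV clusters: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level ASV clusters: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainasv)
```

## The generative model

A bacterial strain carries $C$ copies of the 16S rRNA gene, partitioned
over $k$ distinct sequence variants with multiplicities
$m_1 \ge m_2 \ge \dots \ge m_k$, $\sum_i m_i = C$. In full-length
amplicon data each variant is its own ASV, and under unbiased
amplification the expected read share of variant $v$ of strain $s$ in a
sample is copy-weighted:

$$ p_v \;=\; \frac{\sum_s a_s\, m_{s,v}}{\sum_s a_s\, C_s}, $$

with $a_s$ the cell-level relative abundance of strain $s$. Two
consequences drive the whole package:

1. Within one strain, ASV read counts sit in the fixed integer ratio
   $m_1 : m_2 : \dots : m_k$ in every sample where the strain occurs —
   the counts are *proportional*, so their log ratio is constant up to
   sampling noise and their ranks co-vary.
2. Between strains, ASV count ratios track the ratio of strain
   abundances, which varies across samples.

Cluster inference exploits exactly this contrast. Its assumptions — no
amplification bias between variants, substitution-only variants (equal
amplicon lengths), denoised counts (no residual sequencing error) — are
stated here because violations (primer-site variants, chimeras, indels)
would show up as ratio drift that the constancy test is designed to
reject rather than absorb.

## Pair test and clustering

For an ASV pair $(i, j)$ sharing a species label, statistics are computed
over samples where both exceed a detection threshold. The pair passes
when

* co-presence in at least $m$ samples (default **6**): below this the sd
  estimate is too unstable to call constancy;
* sd of $\log(x_i/x_j) \le \tau$ (default **0.30** natural-log units,
  i.e. roughly ±30% ratio wobble): at depth 20,000 and within-cluster
  shares down to 20%, multinomial noise alone contributes sd ≈ 0.03–0.1,
  while independent strains drawn log-normally contribute
  $\sqrt{2}\,\sigma_{\log} \approx 1.1$ or more, so 0.30 separates the
  two regimes by a wide margin;
* Spearman $\rho \ge \rho_{\min}$ (default **0.8**): proportional counts
  are rank-correlated near 1; independent or compositionally
  anti-correlated counts are not.

Passing pairs form a graph; connected components are candidate clusters.
Components (not cliques) tolerate one noisy pair inside a genuine 5-ASV
cluster; the post-hoc requirement that the *average* pairwise log-ratio
sd stay $\le \tau$ guards the opposite failure, a chain of marginal
edges. Components failing either check fall back to singletons — the
method prefers missing a cluster over inventing one. Samples where either
ASV is absent are excluded outright, with no pseudocounts: under this
design absence reflects true strain absence, and a pseudocount would
manufacture ratio variance where the strain is simply missing.

Zeros, ties and degenerate inputs: an empty sample aborts
`relative_abundances()` with the sample named; a table with one ASV
yields one singleton; deterministic output order (species, then total
reads) makes runs reproducible and relabelling-invariant.

## Integer ratio fit and copy number

Observed mean shares $s$ (averaged over samples where all members are
present) are fit by a coprime positive integer vector $r$ with
$\sum r \le$ `max_copies` (default **15**, the upper range of known
bacterial *rrn* copy numbers). The fit criterion is the maximum relative
deviation $\max_i |r_i/\Sigma r - s_i|/s_i$, accepted when $\le
\varepsilon$ (default **0.10**).

The search is *parsimony-first*: among acceptable vectors it returns the
one with the smallest total, not the global deviation minimiser. The two
disagree in a way that matters. Shares of (0.74, 0.26) are approximated
more closely by 11:4 (deviation 0.026) than by 3:1 (0.038), but 11:4 is
a 15-copy genome conjured from 1.3% of noise; the biological reading of
a near-3:1 ratio is four copies. With `max_copies` = 15 the candidate
fractions form a fine grid, so a pure minimiser would routinely land on
large-denominator rationals under sampling noise. Smallest-total-within-
tolerance returns 3:1 unless the data genuinely exclude it. Ties resolve
by smaller deviation, then lexicographically; when nothing fits within
$\varepsilon$ the closest vector is returned flagged `rejected`, and the
clustering stage demotes such components to singletons.

The copy number is reported as the *lower bound* $\sum r$: a strain with
copies split 6:2 reduces to 3:1, indistinguishable from a 4-copy genome
by read ratios alone.

An ASV may be shared between clusters (a strain whose copies are all
identical, plus a multi-variant strain carrying the same dominant
sequence). The partition step cannot produce this — such configurations
were established from isolate evidence, not from count tables — so
shared-ASV clusters are declared explicitly and resolved by non-negative
least squares against the column-normalised signature matrix;
rank-deficient signatures abort with the confounded cluster ids. The
solution is exact (zero residual) whenever counts lie in the signatures'
non-negative cone, and read mass is conserved for exactly decomposable
samples.

## Species disambiguation

Identity is computed by global (Needleman–Wunsch) alignment with free
end gaps, match +1 / mismatch −1 / linear gap cost 2, counted as
matching columns over the full alignment span *including* terminal
overhangs ("ACGT" vs "ACG" is 3/4); `N` counts as a mismatch. For the
equal-length substitution-only comparisons the threshold rule actually
faces, this reduces to 1 − Hamming/length, so the convention choice is
documented rather than consequential. An ASV is assigned to a reference
species only when identity *strictly exceeds* the threshold (default
0.9980) for exactly one reference; identity at the threshold, or above
it for both references (a tie the data are not expected to produce, but
the code must decide), yields the joined intermediate label, the tie
additionally warning. Note one deliberate asymmetry: raising the
threshold can only retract species calls for genuinely intermediate
ASVs, but a both-above tie can *become* a species call under a stricter
threshold — the monotonicity property holds for the none-above case the
rule was designed around.

## Community statistics

Alpha diversity is inverse Simpson $1/\sum p_i^2$; beta diversity is
Bray–Curtis with a one-factor PERMANOVA using Anderson's distance-based
pseudo-F and the add-one permutation estimator
$p = (1 + \#\{F^\ast \ge F\})/(1 + n_\mathrm{perm})$, $n_\mathrm{perm}$
= 999 by default, seeded. Scaled PCA standardises columns before SVD and
fixes each component's sign by making its largest-magnitude loading
positive. Correlation analysis filters taxa at mean relative abundance
≥ 0.2% (inclusive) over a designated sample set, uses Spearman with
midrank ties and the t-approximation p-value (Pearson for single-time
sensory correlations), flags cells with fewer than 4 complete pairs or a
constant margin as undefined, and orders heatmap leaves by Ward.D2 on
Euclidean distances. Raw p < 0.05 is the significance convention;
Benjamini–Hochberg adjustment is available but off by default, matching
the analysis convention this package reproduces rather than a general
recommendation. Sensory scores are standardised per assessor,
$(x-\mu)/\sigma$ with the sample (n−1) sd — the denominator is
config-exposed since either convention is defensible — within one
ripening-time session by default (an assessor's frame of reference
plausibly drifts between sessions months apart); zero-variance assessors
are excluded with a warning.

## The synthetic-data generator

The generator emulates the features the inference relies on: strains
with substitution-only copy variants at uniformly drawn positions
(disjoint across variants, so copies are pairwise distinct), uniform
base composition, log-normal strain loads row-normalised per sample
(no distribution is prescribed by the data; log-normal spreads abundance
over orders of magnitude as fermentation communities do), copy-weighted
multinomial read sampling, metabolites as truncated-at-zero linear
responses to strain abundance with Gaussian noise, and panel scores as
clamped affine transforms of a latent quality. It does **not** emulate
sequencing error, chimeras, indels, primer or PCR bias, variable library
depth, or compositional effects of taxa outside the simulated set —
passing recovery tests therefore demonstrates the statistical machinery
under the stated generative model, not robustness to upstream artefacts,
which are assumed removed by denoising.

Presets pin the simulated strain configurations to the observed ones:
`leuconostoc` (4 copies split 3+1), `rennini` (5 copies split 3+1+1),
`tetragenococcus` (two independent strains with five single-copy
variants each), `lactococcus_pair` (two single-copy strains near two
type-strain references), `null_community` (twelve unrelated single-copy
strains under one species label — no true clusters). The single-strain
presets embed the focal strain in a three-species background (focal
weight 8, $\sigma_{\log}$ = 0.8): in a literal one-strain community the
focal ASV counts at fixed depth are multinomially *anti*-correlated
(exactly −1 for two ASVs), so no co-occurrence signal exists to detect;
the background restores the between-sample abundance variation within
which the clusters were originally observed. Read depth is a free
parameter (the source data do not state per-sample depths); 20,000 reads
per sample over 24 samples is the reference condition used throughout
the tests, and the recovery suites run 100 seeded replicates per preset
at that size. Other test problem sizes (200–1,000 random share vectors
for the ratio-fit oracle, 199–999 permutations for PERMANOVA checks,
25–50 seeds for Monte-Carlo recovery medians) were chosen as the
smallest sizes at which the checked quantities are stable.

## Known limitations

* Copy numbers are lower bounds; equal-multiplicity splits (e.g. 2:2)
  reduce to 1:1 and undercount by a factor.
* Two strains of one species whose abundances happen to co-vary across
  all samples are indistinguishable from one multi-copy strain — the
  method infers co-variation structure, not genome membership.
* Cluster inference needs the strain present in enough samples
  (default ≥ 6 co-present); rare strains stay singletons.
* The identity threshold rule is a two-reference disambiguation, not a
  general taxonomy assigner.
* PERMANOVA is one-factor; nested or stratified designs are out of
  scope.
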