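---
title: "Reproducibility-optimized differential expression testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-optimized differential expression testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-group differential expression methods for RNA-seq disagree with each
other, and which of them works best depends strongly on the data set at
hand: the depth, the number of replicates, and the amount of biological
variability all shift the balance between heavily regularized statistics and
plain fold changes.  Rather than committing to one statistic a priori, the
ROTS procedure implemented here *learns* the statistic from the data, by
asking which member of a simple parametric family most reproducibly ranks
the same genes to the top when the experiment is perturbed by resampling.

## The model

Let $x_{gi}^j$ be the normalized log2-scale expression of gene $g$ in sample
$i$ of condition $j \in \{1, 2\}$, with group sizes $n_1, n_2 \ge 2$.  With
group means $\bar x_g^j$, unbiased group variances $(s_g^j)^2$, and the
pooled standard error

$$s_g = \sqrt{\Big(\tfrac{1}{n_1}+\tfrac{1}{n_2}\Big)
  \frac{(n_1-1)(s_g^1)^2 + (n_2-1)(s_g^2)^2}{n_1+n_2-2}},$$

the candidate statistics are the modified t family

$$d_\alpha(g) = \frac{|\bar x_g^1 - \bar x_g^2|}{\alpha_1 + \alpha_2 s_g},
  \qquad \alpha_1 \ge 0,\ \alpha_2 \in \{0, 1\}.$$

$(\alpha_1{=}0, \alpha_2{=}1)$ is the ordinary pooled t statistic,
$(\alpha_1{=}1, \alpha_2{=}0)$ the absolute signal log-ratio, and
intermediate $\alpha_1 > 0$ with $\alpha_2 = 1$ are SAM-like fudge-factor
statistics that damp the influence of unstable small variances.

**Selection by reproducibility.**  For $B$ pairs of datasets bootstrapped by
resampling samples with replacement *within* each group, both members of a
pair are ranked by $d_\alpha$ and the overlap proportion $R_k^b$ of their
top-$k$ lists is recorded.  Writing $R_k(d_\alpha)$ for the mean overlap and
$s_k(d_\alpha)$ for the sample standard deviation of the $B$ per-pair
overlaps, and $R_k^0(d_\alpha)$ for the same mean overlap computed on pairs
of whole-dataset label permutations (the null reproducibility), the
procedure maximizes

$$Z_k(d_\alpha) = \frac{R_k(d_\alpha) - R_k^0(d_\alpha)}{s_k(d_\alpha)}$$

over a lattice of $\alpha$ and top-list sizes $k$ between 5 and the number
of genes $G$.  The selected statistic is then applied to the original data,
and significance is assessed by a SAM-style permutation FDR.  As a rule of
thumb, an optimized $Z$ below 2 means the data or the candidate statistics
are insufficient for reliable detection; `rots()` warns in that case rather
than failing.

## Parameters that matter

* **`B`** (default 1000) — bootstrap pairs, null pairs and FDR permutations
  alike.  No canonical value is prescribed for the procedure; 1000 makes
  the Monte Carlo error of $R_k$ and of the FDR small at desk scale.
  Tests and examples use 15–100 to stay inside their runtime budgets.
* **`alpha_grid`** — by default $\alpha_2 = 1$ with $\alpha_1 \in
  \{0, 0.01, \ldots, 1\} \cup \{1.1, \ldots, 5\}$ plus the single point
  $(1, 0)$.  Only "a dense lattice" is prescribed; density is concentrated
  near 0 where $d_\alpha$ changes fastest with the regularizer.  The single
  $(1,0)$ point suffices for $\alpha_2 = 0$ because $d_{(\alpha_1,0)}$
  induces the same ranking for every $\alpha_1 > 0$.
* **`k_grid`** — approximately log-spaced sizes
  $\{5, 10, 25, \ldots\} \cap [5, G]$, always including $G$.  Overlap
  curves are smooth in $k$, so a log grid loses little while keeping the
  lattice small.
* **`prior`** (default 0.5) and TMM trim fractions (0.30 on M, 0.05 on A) —
  the published defaults of the log-CPM transformation and TMM scaling.

## Preprocessing

Counts are normalized with TMM scaling factors (doubly trimmed,
precision-weighted mean of log count-ratios against a reference sample
chosen by the 75th-percentile rule) and transformed to
$\log_2\big((y + 0.5)\cdot 10^6 / (N f + 1)\big)$ against effective library
sizes $N f$.  This is the transformation half of voom only: the statistic
family above has no per-observation weight slot, so voom's precision
weights would have nowhere to act, and they are deliberately not computed.
Genes with zero counts in every sample are dropped first (they carry no
ranking information and have undefined M-values); the dropped count is
reported in the fit.

One property worth stating precisely: the trimmed M/A selection is
invariant to rescaling a single library's depth, but the published
precision weights $w_g = [(N_k - y_{gk})/(N_k y_{gk}) +
(N_r - y_{gr})/(N_r y_{gr})]^{-1}$ depend on absolute counts, so TMM
factors shift slightly (order $10^{-3}$ for a tenfold depth change) rather
than being exactly depth-invariant.  The reference Bioconductor
implementation behaves identically; the test suite documents this.

## Numerical conventions

* **Ties.**  Rankings break ties by ascending gene index; this makes
  overlaps, and hence the whole optimization, deterministic.  Where
  $\alpha_1 = 0$ and $s_g = 0$, $d$ is 0 for a zero numerator and $+\infty$
  otherwise; $+\infty$ values sort above all finite values, among
  themselves by descending numerator, then index.
* **Lattice ties.**  Equal $Z$ values (common, since neighboring lattice
  points often induce identical rankings) resolve toward larger $k$, then
  smaller $\alpha_1$, then larger $\alpha_2$ — i.e. toward the least
  regularized, most broadly reproducible point.
* **$s_k$** is the $B{-}1$-denominator sample SD of the per-pair overlaps;
  $Z$ is flagged undefined where $s_k = 0$ and such points are excluded
  from the optimization.
* **Null pairs** are two *independent* label permutations per pair.  The
  phrase "random permutations across the whole data set" is implemented
  literally; bootstrapping under permuted labels would be the main
  alternative reading and would mix within-group and between-group
  variation.
* **FDR.**  raw$(g)$ divides the mean permutation count of statistics
  $\ge d(g)$ by the observed count $\ge d(g)$ (ties on both sides counted
  with $\ge$), clipped to $[0,1]$, then a step-up pass takes the minimum of
  raw over all genes with statistic $\le d(g)$, making the estimate
  monotone along the ranking; tied statistics share one value.
* **Reproducibility.**  A single RNG seed drives everything; plans are
  drawn in the documented order (bootstrap, null, FDR permutations), so a
  run is bit-reproducible from `(counts, design, options, seed)`.

## The simulator, and what a green test establishes

`simulate_counts()` draws gene $g$ in sample $i$ of group $j$ from a
negative binomial with mean $\mu_g \cdot FC_g^{[j=2]} \cdot \ell_i$ and
variance $\mu + \phi\mu^2$.  Baseline means $\mu_g$ are log-uniform on
$[10, 10^4]$ and depth factors $\ell_i$ log-uniform on $[0.7, 1.4]$ — both
chosen once to span realistic sequencing depths and to exercise
normalization — and `spikein_preset()` emulates the classic external-RNA
control benchmark: 92 control genes at fold changes $\{0.5, 0.67, 1, 4\}$,
$n = 5$ technical replicates per group, dispersion 0.01 (technical
replicates vary little), inside a null background with $\phi = 0.1$ as a
biological-scale default.  Of the 92 controls, 23 sit at fold change 1 (the
non-differential class); lacking a canonical per-class split for the other
69, they are divided evenly, 23 per differential class.  The preset embeds
the controls in a 1000-gene matrix.

The simulator emulates the *marginal* count behaviour of a spike-in
experiment.  It does not model gene-gene correlation, GC/length biases,
batch structure, or outlying samples — so a green sensitivity or
calibration test establishes that the estimator chain is implemented
correctly and behaves sanely under NB noise, not that the same AUC would be
obtained on any particular real series.

## Known limitations

* Two groups only; no paired, multi-group or covariate designs.
* No moderated-variance empirical-Bayes alternatives; the family is exactly
  $d_\alpha$.
* The optimization cost grows as
  $O(B \cdot |\alpha| \cdot G \log G)$; at $G \sim 2 \cdot 10^4$ and
  $B = 1000$ expect minutes, not seconds, on one core.
* Permutation FDR granularity is limited by $P \cdot G$; very small FDRs
  are reported as 0 when no permuted statistic exceeds the observed one.
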