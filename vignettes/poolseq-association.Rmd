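---
title: "Scanning pooled sequencing data for environmental association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning pooled sequencing data for environmental association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(poolscan)
```

## The problem

Pool-seq experiments sequence RNA or DNA pooled from a handful of
individuals per sample, so allele frequencies are estimated from read
counts with two stacked sources of sampling error: the finite pool of
chromosomes (here 8 per pool: four diploid individuals) and the finite
read depth at each site. `poolscan` asks, for each biallelic SNP, whether
its allele frequency tracks an environmental gradient — in the default
design, panel temperature (ambient, +1 °C, +2 °C; three replicate pools
per treatment) — while accounting for both error sources and for shared
structure among pools, and then aggregates evidence to the gene
(supertranscript) level where the per-SNP signal is too noisy to call
individually.

## The statistic

For SNP with per-pool minor read counts $m_s$ and two-allele coverages
$t_s$:

1. **Effective allele number.** A pool of $n$ chromosomes sequenced to
   depth $c$ behaves like $e = (nc-1)/(n+c)$ independently sampled
   chromosomes; $e \to n$ at large $c$ and $e \to c$ for large pools.
   All frequency averaging is weighted by $e$ so that shallowly covered
   pools count less.
2. **Standardization.** $\hat p_s = m_s/t_s$,
   $\bar p = \sum_s e_s \hat p_s / \sum_s e_s$, and
   $x_s = (\hat p_s - \bar p)/\sqrt{\bar p(1-\bar p)}$.
3. **Among-pool covariance.** Over a "matrix" SNP set (coverage $\ge 5$
   in $\ge 6$ pools, $\ge 5$ minor reads in total, one SNP per
   transcript so linked sites do not dominate),
   $\Omega = L^{-1}\sum_l x^{(l)} x^{(l)\top}$ estimates how pools
   covary under drift and shared history. Whitening association
   statistics by $\Omega$ is what keeps structure among pools from
   masquerading as environmental signal.
4. **Score.** Each analysis SNP (coverage $\ge 5$ in *every* pool,
   $\ge 15$ minor reads in total) is whitened by the lower Cholesky
   factor $C$ of a shrunk $\Omega$ ($Cy = x$) and scored as
   $Z = |\rho_{\mathrm{Spearman}}(y, \mathrm{env})| \in [0,1]$, with
   average ranks for ties. $Z$ is invariant to swapping the major/minor
   labels.
5. **Permutation FDR.** The environment labels are permuted $p = 100$
   times (seed 8372); frequencies, covariance and gene membership do not
   change under label permutation, so only the rank correlations are
   recomputed. For an observed score $z$, with $i$ observed scores
   $\ge z$ and $n$ pooled null scores $\ge z$, the empirical FDR is
   $n/(ip)$ capped at 1 ($n = 0 \mapsto 0$; resolution floor $1/(ip)$).
   Gene scores are the mean $Z$ over a gene's scored SNPs (genes with
   $\ge 5$ scored SNPs), with the same FDR construction against
   per-permutation gene means.

The association score deliberately avoids MCMC: it is a deterministic,
bounded Bayenv-style statistic — covariance-corrected, rank-based, and
reproducible bit-for-bit from one seed. The environment vector itself is
not whitened, only the frequencies; rank correlation against the
(standardized) environment after whitening the frequencies is the closer
analogue of a nonparametric environmental correlation test. The
`as_printed` FDR mode reproduces the literal formula $ip/n$ found in some
descriptions of this procedure; that quantity grows as null exceedances
shrink — it is the reciprocal of an FDR — so the calibrated `empirical`
mode $n/(ip)$ is the default, and `as_printed` is kept for literal
comparability (with $n = 0 \mapsto +\infty$).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_cov` | 5 | reads | below ~5 reads a pool's $\hat p$ is mostly noise |
| `min_samples_matrix` | 6 of 9 | pools | matrix SNPs may be thin in a minority of pools |
| `min_minor_analysis` | 15 | reads | removes SNPs whose minor allele could be accumulated sequencing error |
| `min_snps_per_gene` | 5 | SNPs | a mean over fewer SNPs is dominated by single-SNP noise |
| `p` | 100 | permutations | FDR resolution $1/(ip)$; 100 matches the tied 3×3×3 design, which has only 1,680 distinct label arrangements |
| `lambda` | 0.05 | — | a 9×9 covariance from finitely many SNPs is near-singular; shrinkage toward its diagonal keeps the factorization stable |
| `z_report_threshold` | 0.49998 | — | a reporting cutoff for the summary table only, never an inference step |
| `seed` | 8372 | — | fixes permutations (and simulations) bit-for-bit |

Ties in the temperature design (three pools per treatment) are handled
with average ranks throughout, and exceedance counts use $\ge$ on both
$i$ and $n$, so a SNP always counts itself ($i \ge 1$).

## What the simulator emulates — and what it does not

`simulate_pools()` draws, per SNP and pool, a true frequency
$p = \mathrm{clamp}(\pi + \beta T + \gamma + \delta,\, 0,\, 1)$, then a
pool sample $k \sim \mathrm{Binom}(8, p)$, a coverage
$c \sim \max(1, \mathrm{Pois}(50))$, and minor reads
$m \sim \mathrm{Binom}(c,\ (k/8)(1-\epsilon) + (1-k/8)\epsilon)$. This
reproduces the features the method is built around: the two-stage
(pool-then-reads) sampling error whose variance follows the
$1/n + 1/c$ structure that the effective allele number addresses; shared
within-treatment deviations ($\gamma$, SD 0.02) that the covariance
matrix must absorb; independent pool noise ($\delta$, SD 0.05); a
low-frequency-skewed base frequency spectrum (Beta(1.5, 6) truncated to
[0.05, 0.95]); and gene-level effects (all SNPs of a planted gene share
$\beta$), matching the gene as the unit of inference. Effects are
planted on the frequency scale with clamping rather than on the logit
scale — transparent in the weak-effect regime the method targets.

It does **not** emulate read-level artifacts (mapping error, indels,
base-quality structure), linkage between SNPs of a gene beyond the
shared effect, allele-frequency spectra shaped by demography, or
coverage that covaries across pools at a site. Passing calibration and
recovery checks on these simulations therefore demonstrates that the
statistics do what they claim under the model's assumptions — not that
real transcriptome pool-seq data meet those assumptions.

Default scale: 200 genes × 10 SNPs at 50× mean coverage, chosen as a
desk-scale stand-in for a transcriptome-wide scan that still leaves
~2,000 analysis SNPs, enough for a stable 9×9 covariance and an FDR
resolution of $10^{-4}$ at the top of the ranking.

## Numerical choices and degenerate inputs

* Biallelic reduction takes the two nucleotides with the largest pooled
  totals; N and deletion counts never contribute to an allele or to
  coverage $t$. Ties break by the fixed sync column order A < T < C < G.
* "One SNP per transcript" for the matrix set keeps the lowest-position
  qualifying SNP — deterministic and order-independent.
* The minor allele is defined globally (pooled across samples), giving
  one MAF trajectory per SNP; per-pool minor alleles would flip signs
  incoherently across pools.
* SNPs with $\bar p \in \{0, 1\}$, or (matrix set only) a zero-coverage
  pool, are flagged unusable and logged, not errors.
* The shrunk covariance adds $\epsilon I$ with
  $\epsilon = 10^{-8}\,\mathrm{tr}(\Omega)/S$ so the Cholesky
  factorization survives rank deficiency; whitening uses a triangular
  solve (verified against explicit inversion to $10^{-10}$).
* SNPs whose whitened vector is rank-constant have no defined rank
  correlation; they are excluded from scoring and counted in the log.
* Matrix SNPs may also appear in the analysis set by default
  (`disjoint_matrix = TRUE` excludes them); with one matrix SNP per
  transcript the overlap is a single SNP per gene.
* The raw $n/(ip)$ estimator is monotone non-increasing along the
  sorted observed scores wherever the null is dense (100 permutations of
  the same SNP set), except for sampling noise of order $10^{-3}$ at the
  bottom of the ranking where FDR ≈ 1; no monotonization is applied.

## A small worked example

```{r}
sim <- simulate_pools(sim_config(n_genes = 40, snps_per_gene = 8,
                                 planted_fraction = 0.1, beta = 0.15,
                                 seed = 8372))
scan <- run_scan(sim$records, sim$env, sim$design,
                 scan_config(p = 100, seed = 8372))
scan
head(scan$gene_table[order(-scan$gene_table$mean_z), ])
```

Genes whose SNP frequencies were simulated to shift with temperature
rise to the top of the mean-Z ranking; under the global null
(`planted_fraction = 0`) the same pipeline returns (essentially) nothing
at FDR ≤ 0.05 — the calibration property the permutation null is for.

## Known limitations

* Nine pools give rank correlations a coarse support; $Z$ takes few
  distinct values and single-SNP power is intrinsically low. Gene-level
  aggregation is the intended inference level.
* The covariance model corrects second-order structure only; strong
  skews or outlier pools are better handled upstream.
* The permutation space of the tied 3×3×3 design is small (1,680
  arrangements), bounding how fine the null tail can resolve.
* Empirical FDR at the gene level inherits the discreteness of both the
  permutation count and the gene count; values are floored at $1/(ip)$
  when nonzero.
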