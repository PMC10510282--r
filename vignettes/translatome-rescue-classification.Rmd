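---
title: "Methods: differential translatome analysis with additive p-value combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential translatome analysis with additive p-value combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapdiff)
```

# The experiment and the questions

TRAP-Seq (translating ribosome affinity purification followed by
sequencing) profiles the mRNAs engaged with ribosomes in a genetically
marked cell population. The design handled here is a 4 x 3 factorial on
the Apoer2 receptor: genotypes `WT`, `cKO` (conditional knockout) and two
cleavage-resistant knockins `D16p19` / `D16d19` (with/without the exon-19
proline-rich insert), crossed with lentiviral treatments `Cre` (baseline)
and Cre plus one of two Apoer2 intracellular-domain splice variants,
`ICD19` / `ICDd19`. Three questions drive the analysis, each about a
two-contrast pattern rather than a single comparison:

* **Basal**: which transcripts differ between a mutant genotype at the
  Cre baseline and `WT:Cre`?
* **Rescue**: which basal differences are reverted toward wild type when
  an ICD variant is reintroduced?
* **Effect**: which transcripts does an ICD move regardless of the basal
  genotype difference?

# The differential stage and its scope

Each two-group contrast is tested with a negative-binomial Wald test that
is an explicit, documented stand-in for a DESeq2 run: median-of-ratios
size factors (rescaled to geometric mean 1), gene-wise method-of-moments
dispersions on normalized counts pooled within `genotype:treatment`
groups, shrunk 50/50 on the log scale toward a fitted `a0 + a1/mu` trend
(floor `1e-8`; degenerate genes — zero mean or zero pooled variance — get
the floor outright and are excluded from the trend fit), and

$$\log_2\!FC = \log_2\frac{\bar x_B + 0.5}{\bar x_A + 0.5},\qquad
  se^2 = \frac{1}{\ln^2 2}\left[\frac{V(\bar x_A)}{(\bar x_A+0.5)^2}
  + \frac{V(\bar x_B)}{(\bar x_B+0.5)^2}\right],$$

with $V(\bar x) = n^{-2}\sum_i(\mu/s_i + \alpha\mu^2)$ the delta-method
variance of a group mean of normalized NB counts and a two-sided normal
tail on $\log_2\!FC/se$. There is no fold-change shrinkage, no outlier
refitting and no independent filtering; the pseudocount 0.5 keeps
zero-mean genes finite. The design choice behind this simplicity: the
contribution of the pipeline lies downstream of the DE fit, so the stage
is swappable — `as_contrast_result()` accepts any external table with
`gene_id`, `log2fc` and `p` (e.g. genuine DESeq2 output), and every later
stage consumes only that contract.

Two calibration caveats are worth stating plainly. First, a normal (not
t) tail at 5-6 replicates per group is slightly anti-conservative even
with the true dispersion; on null simulations with the package defaults
the rejection rate at 0.05 is about 0.06 and the Kolmogorov distance of
the p-value ECDF from uniform about 0.02-0.03. Second, raw p-values (not
BH-adjusted) feed the classification rules, matching the published
thresholds; adjusted values are reported per contrast for transparency
but are not consumed. Whether the original analysis used raw or adjusted
values at its 0.05 gates is not stated in its methods; raw is the
assumption here.

# Additive combination of p-values

Evidence across two contrasts is combined additively (Edgington's
method): with $s = \sum_{i=1}^k p_i$, the combined value is

$$p_{comb} = \min\!\left(1,\; \frac{s^k}{k!}\right)
  \quad\text{("paper" mode)},$$

which is exactly the Irwin-Hall CDF $P(\sum_i U_i \le s)$ of a sum of $k$
independent uniforms whenever $s \le 1$, so it is exactly calibrated at
any rejection threshold $\alpha$ with $(k!\,\alpha)^{1/k} \le 1$ — in
particular at $\alpha = 0.05$ for $k = 2$. For $s > 1$ the power formula
overshoots the true tail and eventually exceeds 1; values are truncated
at 1, and an `"exact"` mode computes the full Irwin-Hall
inclusion-exclusion sum instead. Default is the truncated formula, for
fidelity to the published procedure; the truncation itself is a package
decision (the original text does not say whether sums above 1 ever
occurred). Both modes are monotone in every input and exchangeable.

```{r combine-example}
additive_combine(c(0.05, 0.05))                 # (0.1)^2/2
additive_combine(c(0.75, 0.75), mode = "paper") # capped at 1
additive_combine(c(0.75, 0.75), mode = "exact") # Irwin-Hall: 0.875
```

The three combined statistics, per gene, mutant genotype $G$ and ICD
variant $I$ (all k = 2):

* **rescue**: combine $p(G{:}Cre \text{ vs } WT{:}Cre)$ with
  $p(G{:}I \text{ vs } G{:}Cre)$;
* **effect**: combine $p(G{:}I \text{ vs } WT{:}Cre)$ with
  $p(G{:}I \text{ vs } G{:}Cre)$;
* **vWT**: combine the two vs-wild-type p-values, defined only when both
  fold changes versus WT exceed 0.58 in magnitude with the same sign.

A "both-ICD" statistic combines the two single-ICD rescue (or effect)
values, again with k = 2 ("these p-values were combined" is read as the
already-combined ones; a flat k = 4 over the raw inputs is available
behind `both_mode = "flat"`, which for rescue counts the shared baseline
contrast twice). The two contrasts entering each combination share a
group, so they are not strictly independent; the combination is used as
a ranking/threshold device exactly as published, and this caveat is the
price of fidelity. Untested genes propagate as missing — a missing
p-value never silently enters a combination as 1.

# Classification rules

With thresholds `p < 0.05`, `|log2FC| > 0.58` (the printed constant, not
`log2(1.5)`), reversion delta 0.5 and relaxed magnitude 0.5 — all strict
comparisons, all configurable in `run_pipeline()`:

* **rescued** (per ICD): rescue p < 0.05, baseline |log2FC| vs WT > 0.58,
  and the |log2FC| vs WT with the ICD at least 0.5 smaller in magnitude
  than without it. "Closer to zero" is read literally as a magnitude
  reduction, so overshooting past zero (say +1.0 to -0.2) still counts;
  the published rule does not address overshoot.
* **effected** (per ICD, with direction): effect p < 0.05 *or* rescue
  p < 0.05, and |log2FC| > 0.58 for the ICD group against both WT and the
  genotype baseline; direction is the sign against the genotype baseline.
* **basal** (per genotype): |log2FC| vs WT > 0.58 and the smallest
  *available* of {baseline p, rescue p (either ICD), vWT p (either ICD)}
  below 0.05. Using "any available" ICD route when only one is defined is
  a package decision; the source does not specify. Rescued transcripts
  are basal by construction (their rescue p is one of the routes), and
  the pipeline asserts this invariant in its tests.
* **shared module** (relaxed): genes basal-significant under the full
  criteria in at least one mutant genotype whose baseline |log2FC|
  exceeds 0.5 with a consistent sign in all three.

When one ICD's rescue p-value is undefined, both-ICD labels stay
undefined rather than promoting the single defined ICD.

# The synthetic world

`simulate_experiment()` generates the full factorial with planted ground
truth so that recovery is measurable. Defaults, chosen once as a
realistic stated world and not tuned against any test outcome:

| parameter | default | why |
|---|---|---|
| replicates/group | 5 | within the study's 4-9 animals per condition |
| baseline means | log-uniform 100-10000 | the moderately-to-highly expressed fraction that survives standard independent filtering; fold-change thresholds at 5 replicates are only meaningful there |
| dispersion trend | `0.02 + 2/mu` | asymptotic biological CV ~14%, typical of inter-animal bulk tissue replicates; Poisson-plus behaviour at low counts |
| planted \|log2FC\| | 1.5 | comfortably above the 0.58 gate, as published hits are |
| rescue reversion | 1.0 | full reversion to wild type |
| library factors | log-uniform 0.5-2 | routine depth variation |
| class mix | 70% null, 5% per effect class | 10% rescued-by-both in total |

Counts are gamma-Poisson draws (`rnbinom` with `size = 1/alpha(mu)`)
with means `baseline * 2^lfc * s_j`; class counts follow the requested
proportions exactly (largest-remainder quota); identical configs and
seeds are bit-identical. The generator does *not* emulate 3'UTR bias of
amplified RNA, pooled samples (each sample is independent; pooling is a
wet-lab artifact with no stated statistical model), sex or batch
covariates, or correlated gene modules. A green recovery test therefore
establishes that the rules detect the planted pattern under honest NB
noise — not that the pipeline reproduces the published transcript
counts, which depend on deposited in-vivo data and are out of reach at
desk scale. (Those published counts are also internally inconsistent in
one place — 237 up + 680 down described as 605 total — so no attempt is
made to match them.)

# Numerical choices and degenerate inputs

* Dispersion floor `1e-8`; trend fit by ordinary least squares of the
  raw moment estimates on `1/mean`, with the intercept clamped positive
  and the slope non-negative, falling back to a flat median trend when
  fewer than 10 informative genes or no mean spread.
* Genes with all-zero counts in a contrast's two groups are
  `tested = FALSE` (`p = 1`, `log2fc = 0`) and excluded from BH; they
  propagate as missing through combination and come out unclassifiable,
  never as silent negatives.
* Ties and boundaries: all threshold comparisons are strict, so a gene
  at exactly 0.58 (or p exactly 0.05) does not pass.
* All result tables have deterministic ordering (gene id, then
  genotype; binary pattern order for overlap partitions), so reruns are
  byte-identical.

# Enrichment stand-in

The published enrichment used web tools (ToppFun, ClueGO, Metascape,
DAVID, GSEA) that are database-backed and not reproducible offline. The
package ships the database-free core instead: exclusive-region counts
for 2-6 gene sets (`overlap_partition()`, the numbers behind a supervenn
figure) and an upper-tail hypergeometric over-representation test with
BH adjustment over user-supplied sets (`hypergeom_enrichment()`,
GMT or two-column input). This is deliberately *not* a reimplementation
of any of those tools.

# Known limitations

* The Wald stand-in is slightly anti-conservative at small n (above);
  users wanting exact DESeq2 behaviour should feed DESeq2 tables through
  `as_contrast_result()`.
* The combination assumes independent contrasts; shared reference groups
  violate this mildly, exactly as in the published procedure.
* The basal "any available route" and the both-ICD nesting are stated
  interpretations of ambiguous prose; both are flagged here and
  switchable where alternatives exist.
* Headline transcript counts from the original in-vivo dataset are not
  reproducible from simulation and are not targets of any test.
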