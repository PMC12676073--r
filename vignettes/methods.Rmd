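---
title: "Methods: detecting homoeolog transcriptional compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting homoeolog transcriptional compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeocomp)
options(homoeocomp.log_level = "WARN")
```

## The question and the design

Polyploid wheat carries most genes in homoeologous copies: triads
(A/B/D, hexaploid) or dyads (A/B, tetraploid). `homoeocomp` asks whether
a homozygous loss-of-function point mutation in one homoeolog triggers
*active transcriptional compensation* — significant upregulation of the
non-mutated copies — or whether redundancy is purely passive. The
experimental design it analyses is a TILLING panel: EMS-mutagenised lines
sequenced alongside a wild-type control (3 biological replicates each),
with each line carrying homozygous G→A / C→T transitions. Premature
termination codon (PTC) mutations are the treatment; synonymous mutations
in the same populations are the negative control, since they should not
perturb protein function and hence should not elicit compensation.

The unit of inference is the *(line, group) context*: a homoeolog group
with exactly one qualifying mutated homoeolog in that line. A context is
**compensated** when at least one non-mutated homoeolog is significantly
upregulated versus wild type. The mutated homoeolog's own status never
triggers the call — NMD-driven downregulation of the PTC transcript and
upregulation of its partners are separate phenomena, and conflating them
would count degradation as compensation.

## Variant consequence calling and the filtering cascade

Consequences are called on the coding strand: the variant's CDS position
is found from the gene model (1-based GFF3 intervals, splicing and strand
handled at the parser boundary only), the affected codon is translated
before and after with the standard genetic code, and the change is
classified as PTC (new stop where the reference had none), synonymous,
missense, or `other`. `other` absorbs stop-loss, start-loss and
stop-to-different-stop changes: the analysis needs only the PTC and
synonymous classes, and a mutation inside the reference stop codon is not
a premature stop even when it is "synonymous at the stop" — it is
excluded rather than misfiled. Pre-annotated consequences (a VEP-style
term in a configurable INFO key, default `CSQ`) are accepted as an
alternative to internal calling; multi-allelic records are split with
only the first alternate considered, and only single-nucleotide
substitutions are used.

The cascade then keeps a variant for a line when all of the following
hold, in order, with record counts logged after each filter:

1. position inside some gene model's CDS;
2. consequence ∈ {PTC, synonymous};
3. gene belongs to a homoeolog group (strict 1:1:1 or 1:1 membership;
   group tables with duplicated genes are rejected outright);
4. wild type is homozygous reference — this removes cultivar-specific
   SNPs that segregate between the reference and the mutagenised
   background;
5. the line is homozygous for the alternate allele.

Variants shared between two mutant lines (but absent from WT) are
retained in both lines. When one gene carries several qualifying variants
in a line, one assignment is kept (PTC over synonymous, then 5'-most).
Groups with more than one mutated homoeolog in the same line are excluded
and counted — including the PTC-in-A, synonymous-in-B case, which would
otherwise contaminate the negative-control class with a group under
genuine PTC treatment.

## Differential expression

The DE engine is deliberately a minimal, self-contained negative-binomial
Wald pipeline rather than a wrapper around a large framework: the
downstream decision uses only `padj < alpha` and the direction of the
fold change, so the engine is validated by simulation calibration, not by
concordance with any particular implementation. There is no Cox–Reid
adjustment, no fold-change shrinkage and no independent filtering.

**Size factors** are median-of-ratios: for sample $j$,
$s_j = \mathrm{median}_g\, K_{gj} / (\prod_{j'} K_{gj'})^{1/m}$ over
genes expressed in every sample; an informative error suggests a
pseudo-reference when no such gene exists.

**Dispersion.** With $\mathrm{Var} = \mu + \alpha\mu^2$, the gene-wise
estimate is method-of-moments on normalized counts,
$\hat\alpha_g = \max\{0, (s^2_g - \bar\mu_g)/\bar\mu_g^2\}$, where
$s^2_g$ pools Bessel-corrected within-condition variances. Gene estimates
are shrunk toward a trend $\alpha(\mu) = a_0 + a_1/\mu$ and floored at
$10^{-8}$. Two numerical choices matter and were made deliberately:

* the trend is fitted by **least squares on the unfloored** estimates
  (one symmetric 6-sigma trim). The raw moment estimates are strongly
  right-skewed at 4 residual df; a robust (median-type) fit estimates a
  quantity below the true mean dispersion and, in null simulations,
  inflated the type-I error to ≈ 0.065 on its own. A conditional-mean fit
  on estimates that are mean-unbiased keeps the trend unbiased. Fitting
  on unfloored values avoids the upward truncation bias of
  $\max(0,\cdot)$.
* the shrinkage **weight on the gene-wise estimate defaults to 0.2**, not
  the even split one might first reach for. With 3 replicates per
  condition the gene-wise estimate is extremely noisy, and plugging that
  noise into the Wald standard errors is anti-conservative by Jensen's
  inequality (genes with underestimated dispersion get overstated
  significance). At weight 0.5 the null rejection rate at
  $p < 0.05$ was ≈ 0.069–0.070 across seeds (5100 null genes); at 0.2 it
  is ≈ 0.054–0.058, inside the package's calibration criterion of
  $0.05 \pm 0.01$. The weight is exposed for designs with more
  replicates, where the gene-wise estimate deserves more trust.

**Wald test.** Per gene, one NB mean per condition with log link and
size-factor offsets, fitted by Newton iteration on the score
$\sum_i (y_i - s_i q)/(1 + \alpha s_i q)$; the statistic is
$\log_2\mathrm{FC} / \mathrm{SE}$ with
$\mathrm{SE}^2 = (I_{\mathrm{mut}}^{-1} + I_{\mathrm{WT}}^{-1})/\ln^2 2$
from the Fisher information $I = \sum_i \mu_i/(1+\alpha\mu_i)$, referred
to the standard normal (two-sided). Group means are floored at half a
count per library to keep log fold changes finite for genes expressed in
only one condition; genes with zero counts everywhere get an undefined
fold change, $p = 1$, and are excluded from the BH multiplicity count.
BH adjustment is transcriptome-wide per line-vs-WT contrast, not
restricted to homoeolog-group genes.

## Compensation summaries and the class comparison

Per-line rates use that line's evaluable contexts as denominator; the
headline pooled rate counts **unique groups** (a group mutated in several
lines enters the denominator once and the numerator once if compensated
anywhere). Both are reported — per-line rates answer "how often does a
line show compensation", the pooled rate answers "how many genes can be
compensated at all".

PTC and synonymous proportions are compared with a Pearson chi-squared
test on the 2×2 compensated-by-class table, Yates-corrected by default to
mirror the ubiquitous default of the statistical environment this kind of
analysis is run in; the uncorrected statistic is available
(`correct = FALSE`, CLI `--no-yates`). A warning is raised when an
expected cell is below 5. Note that the Yates correction is
*conservative by construction* on discrete tables: in the package's own
calibration experiment (1000 simulated class-equivalent null experiments,
50 groups each) the corrected test rejected at 2.3% for a nominal 5%,
while the uncorrected test rejected at 4.8%. Uniformity of the p-value
under the null is therefore asserted for the uncorrected statistic, and
only one-sided conservatism for the default.

## Expression-bias categories

WT relative expression per group is the mean TPM across WT replicates per
homoeolog, normalized to sum to one (averaging before normalization, not
per-replicate classification with voting). The category is the nearest
ideal point by Euclidean distance — triads: balanced
$(\tfrac13,\tfrac13,\tfrac13)$, dominant $(1,0,0)$-type, suppressed
$(0,\tfrac12,\tfrac12)$-type; dyads: balanced $(0.5, 0.5)$ and dominant
$(1,0)$ / $(0,1)$, the tetraploid modification of the triad scheme. Exact
ties (detected up to floating-point noise, $10^{-9}$) are flagged and
resolved by a fixed order: balanced, then dominant A/B/D, then suppressed
A/B/D. Groups with summed WT TPM ≤ 0.5 are not classified; the threshold
follows the convention of the triad-classification literature and is
configurable because it is not restated in every study.

## RT-qPCR

Relative expression is the Pfaffl ratio
$E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with
$\Delta Ct = \overline{Ct}_{\mathrm{calibrator}} - Ct_{\mathrm{sample}}$;
the calibrator is the WT mean per target (the calibrator handling is a
package convention — published Ct tables rarely state theirs). Technical
replicates are averaged to one value per biological replicate before the
genotype effect is tested with a fixed-effects one-way ANOVA.

## The synthetic world

The generator emulates the stated experimental design, not arbitrary
RNA-seq: one WT and one mutant line, 3 replicates each; strict triads or
dyads; exactly one focal EMS mutation (coding-strand G→A: TGG→TAG for
PTC, CTG→CTA for synonymous) per affected group, placed in real emitted
gene models (alternating strands, single- and two-exon structures) so the
generator and the consequence caller check each other; NB counts with a
single global dispersion. Defaults are the stated world:

| parameter | default | basis |
|---|---|---|
| `n_replicates` | 3 | the sequencing design |
| `baseline_mean_log2_range` | (6, 9) | highly expressed seedling-leaf genes were selected for study |
| `nb_dispersion` | 0.05 | typical biological-replicate RNA-seq overdispersion |
| `nmd_fold` | 0.15 | observed NMD-affected fold changes span 0.045–0.18; the default sits in that range but is a choice, not a calibrated estimate |
| `compensation_rate` | 0.025 | the observed hexaploid headline rate |
| `compensation_fold` | 2 | a clearly detectable two-fold response |
| `ptc_fraction`, `syn_fraction` | 0.4, 0.4 | both classes well populated |

`wt_shared_snp_rate` and `heterozygous_rate` (default 0) exist purely to
exercise the mutant-not-WT and homozygosity filters.
`syn_compensation_rate` (default 0) deliberately breaks the
"synonymous mutations are never compensated" rule to build
class-equivalent nulls for calibration experiments.

What the simulator does **not** emulate: read-level noise and mapping
ambiguity between near-identical homoeologs, correlated expression within
a group, per-gene dispersion heterogeneity, multi-tissue designs, and
background (non-focal) mutations. A green parameter-recovery test
therefore establishes that the statistical machinery recovers truth under
the stated noise model — not that mapping artefacts on real wheat data
are handled.

## Numerical and degenerate-input choices

* Coordinates: GFF3/VCF stay 1-based inclusive; conversions happen once,
  at parser boundaries.
* NB mean fitting: Newton steps clamped to ±2 on the log scale, means
  floored at half a count per library; convergence tolerance $10^{-10}$.
* Dispersion floor $10^{-8}$; degenerate (constant or empty) genes land
  on the floor rather than erroring.
* `adjust_bh` enforces step-up monotonicity and the cap at 1; `NA`
  p-values pass through without inflating the multiplicity count.
* Chi-squared with a zero margin returns statistic 0 / p 1 rather than
  NaN; a class with zero groups is an error.
* All randomness flows from the single configured seed
  (`simulation_config(seed=)`); identical configurations are
  byte-identical, which the suite asserts on file hashes.

## Known limitations

* The DE engine's residual anti-conservatism (null rejection ≈ 0.055 at
  $p<0.05$ with 3 replicates) is inherent to plug-in dispersion Wald
  tests at this sample size; it is measured and bounded by the
  calibration tests rather than hidden.
* Power to detect compensation depends on expression level; at the
  default two-fold effect and means ≥ 2^6 per-homoeolog detection is
  near-ceiling, but weakly expressed groups in real data will be
  under-called, biasing compensation rates downward.
* The unique-group pooled rate treats a group compensated in one line out
  of several as compensated; alternative poolings (e.g. per-context) are
  reported alongside rather than chosen for the user.
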