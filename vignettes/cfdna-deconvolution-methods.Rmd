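---
title: "Methods: fragment-level cfDNA methylation deconvolution"
author: "cfdecon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-level cfDNA methylation deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdecon)
```

## The problem

Plasma cell-free DNA (cfDNA) is a pool of short fragments (modal length
about 167 bp, one nucleosome plus linker) released by dying cells across
the body. DNA methylation is tissue specific and largely stable, so the
joint methylation state of the CpG sites carried by a single sequenced
fragment is a fingerprint of that fragment's tissue of origin — and, in
cancer, of whether it came from tumor or normal cells. cfdecon estimates
two quantities from bisulfite sequencing of plasma:

* the **tumor burden** $\theta$: the fraction of cfDNA fragments derived
  from tumor, given a panel of tumor-vs-normal marker regions;
* the **tissue composition**: the fractions of cfDNA attributable to each
  of $N$ reference tissue classes, plus an explicit *unknown* class for
  fragments the reference panel cannot call.

## The fragment likelihood

Everything rests on one closed form. A marker region's methylation level
in class $c$ is modelled as $p \sim \mathrm{Beta}(\alpha_c, \beta_c)$.
Conditional on $p$, the $n$ CpG states observed on one fragment are
i.i.d. Bernoulli($p$). Marginalizing $p$, the probability of the observed
ordered state string with $k$ methylated sites is

$$
P(\text{fragment}\mid c)
 = \frac{B(\alpha_c + k,\; \beta_c + n - k)}{B(\alpha_c, \beta_c)},
$$

computed in log space via `lbeta()` (`fragment_loglik()`). Two deliberate
choices:

* **No binomial coefficient.** The datum is the specific ordered CpG
  string, not the count; the coefficient is constant across classes and
  cancels in every ratio and mixture weight, so including it would only
  shift all log-likelihoods equally.
* **$n = 0$ contributes 0** (empty product). Such fragments are
  uninformative; in classification they tie across all classes and land
  in *unknown*.

Joint modelling of neighboring CpGs is what gives fragment-level methods
their sensitivity: a fragment with 6 concordantly methylated CpGs is far
stronger evidence than 6 independent single-CpG calls, because the
beta-Bernoulli marginal rewards within-fragment concordance.

## Tumor burden: two-class mixture MLE

Given per-fragment likelihoods $L_t$ (tumor) and $L_n$ (normal), the
cfDNA pool is a two-component mixture and

$$
\hat\theta = \arg\max_{\theta\in[0,1]}
 \sum_i \log\!\left[\theta L_{t,i} + (1-\theta) L_{n,i}\right].
$$

`estimate_tumor_burden()` maximizes by exhaustive grid search, default
step $10^{-4}$, computed stably by rescaling each likelihood pair by its
maximum. The objective is unimodal in $\theta$, but a grid is robust,
trivially auditable, and cheap at this scale; `refine = TRUE` adds a
golden-section polish inside the bracketing grid interval. Ties are
broken toward smaller $\theta$ — a flat profile (every fragment equally
likely under both classes) yields $\hat\theta = 0$, the conservative
call. Optional trimming (`trim_fraction`) drops the fragments with the
most extreme $|\log L_t - \log L_n|$ beyond the $1-q$ quantile before
optimization; it is **off by default** because the mixture itself is the
model of heterogeneity, and trimming is exposed only as a robustness
device against outlier fragments (mapping artefacts, conversion
failures).

## Multi-tissue deconvolution with an unknown class

With $N \ge 2$ tissue classes, each fragment is assigned by the
**top-two fold-change rule** (`assign_fragment()`): let $L_{(1)} \ge
L_{(2)}$ be the two largest class likelihoods (natural scale, computed
as `exp()` of a log difference); the fragment is assigned to the top
class iff $L_{(1)}/L_{(2)} \ge$ `fold_change` (default 2), and otherwise
— including an exact tie — to *unknown*. Tissue fractions are the raw
assignment proportions, so the vector including *unknown* sums to 1;
ambiguous mass is reported, never silently redistributed. Raising the
threshold can only move fragments into *unknown*, which the tests assert
as a monotonicity property. The ratio is thresholded on the likelihood
scale (not log): "fold change 2" means one class explains the fragment
twice as well.

A consequence worth knowing: reported known-class fractions are biased
low by roughly `fraction * unknown_share` relative to the truth in a
world with no genuinely unknown tissue. With a well-separated,
CpG-dense marker panel the unknown share is ~1% and this bias is
negligible; with weak panels it is not, and the unknown fraction itself
is the diagnostic to watch.

## Ingestion conventions

* Read and fragment intervals are 0-based half-open (BED); Bismark call
  positions are 1-based and converted on ingestion.
* Calls from the original-bottom (OB) strand report the G of the CpG and
  are shifted by −1, so both strands index the forward-strand C and
  mate union is well defined.
* Paired-end mates are merged to the interval union; mates on different
  chromosomes are rejected and tallied (`rejects` attribute).
* A CpG reported by both mates with conflicting states is **dropped and
  counted** (`conflicts` attribute) — arbitrating by mate would assume
  strand- or quality-ordering the input formats do not carry.
* `methState` uses `1` = methylated, `0` = unmethylated, in genomic
  order; the on-disk table has the fixed column order
  `chrom, start, end, length, n_cpg, methState`.
* Because this table does not carry per-CpG positions, downstream
  likelihoods use each fragment's full $(n, k)$ even when the fragment
  only partially overlaps its marker. Marker regions are hundreds of
  bases wide and fragments short, so partial overlap is the rare case.

## The synthetic world

`simulate_fragments()` draws, per fragment: class from the mixture;
marker uniformly from the panel; $p \sim \mathrm{Beta}(\alpha_{mc},
\beta_{mc})$; $n \sim U\{n_{\min},\dots,n_{\max}\}$; each CpG state
Bernoulli($p$). Fragment lengths are round-Normal(167, 20) truncated to
[80, 400] bp — typical plasma cfDNA geometry. Markers are
non-overlapping 1 kb windows on a toy chromosome `chrS`, and fragments
are placed entirely inside their marker. `emit_bismark_dialect()` splits
each fragment into two mates covering the first and last two thirds, so
the middle third is reported by both mates and the duplicate-agreement
path is exercised everywhere; decoy conflicts (a CpG at an even offset,
where the generator never places a true CpG, reported with opposite
states by the two mates) exercise the conflict path without perturbing
the ground truth.

Two canonical worlds are frozen as constructors:

* `two_class_config(theta)`: tumor markers Beta(8, 2) in tumor vs
  Beta(2, 8) in normal on every marker, CpG count $U\{3..8\}$ — the
  hyper-methylated cancer-marker setting used for burden recovery tests.
* `multi_tissue_config()`: three tissues whose per-marker means are a
  random permutation of $\{0.02, 0.5, 0.98\}$ at concentration 50, CpG
  count $U\{8..16\}$. This encodes "well-separated": real tissue marker
  panels are *selected* for exactly this contrast and CpG density. The
  values were fixed by a design analysis before the recovery tests were
  written: they give a per-fragment ambiguity rate of about 1%, which is
  what makes ±0.03 fraction recovery a meaningful bar rather than a
  lottery. With the generic module default $U\{3..8\}$ and milder means,
  ambiguity reaches 5–15% and no assignment rule could meet that bar —
  a property of the information content of short fragments, not of the
  implementation.

What the generator deliberately does **not** emulate: sequencing error,
incomplete bisulfite conversion, non-CpG contexts, genome-sequence-aware
CpG spacing, mapping artefacts, or marker-selection noise. A green
recovery test therefore establishes correctness of the inference
machinery under its own model assumptions — not performance on real
plasma, which depends on marker quality and error modes outside this
package's scope.

## Numerical choices

* Beta fitting is method of moments (closed form, deterministic), with
  variance floored at $10^{-6}$ and clamped to $0.99\,m(1-m)$ where the
  moment equations would give non-positive shapes; values of exactly 0/1
  are winsorized to $[10^{-4}, 1-10^{-4}]$ so likelihoods stay finite.
  The fitted mean equals the sample mean identically. Numeric MLE is
  available (`method = "mle"`) but the moment fit is the default:
  marker summarization needs stability across thousands of markers more
  than asymptotic efficiency.
* Marker files store shapes as `alpha:beta` with ≥ 6 significant digits
  (`%#.6g`); classes are matched by header name, never column position.
* All mixture arithmetic is done in log space with per-pair rescaling;
  fold-change ratios are `exp()` of log differences, so a zero second
  likelihood yields `Inf` and a confident assignment rather than 0/0.
* Fragments with zero likelihood under *both* burden classes are dropped
  with a warning (they would send the whole objective to $-\infty$);
  if all fragments are such, it is an error.

## Known limitations

* No confidence intervals on $\theta$ or the fractions; the profile is
  returned for inspection but uncertainty quantification is out of scope.
* The unknown class absorbs ambiguity but is not a calibrated estimate
  of unrepresented-tissue abundance.
* Supervised deconvolution against a pretrained model, and the curated
  reference marker atlases themselves, are out of scope; users supply
  their own marker panels or fit them from reference beta values.
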