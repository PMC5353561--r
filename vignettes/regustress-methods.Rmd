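---
title: "Methods: quantifying ethanol-stress response and adaptation from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ethanol-stress response and adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regustress)
```

# Scope and data model

`regustress` analyses normalized log2 gene-expression matrices from two
kinds of bacterial ethanol experiments:

* **acute stress** (NEA, non-ethanol-adapted): treatment-versus-control
  contrasts at known ethanol concentrations, with replicate groups;
* **adaptation** (EA, ethanol-adapted): strains evolved in ethanol for
  thousands of hours, each sampled at a series of time points and
  compared with one parent strain.

The central container, `ExpressionStudy`, is a thin extension of
`SummarizedExperiment`: one `log2expr` assay plus per-sample annotations
(`condition`, `replicate`, `strain`, `time`, `ethanol`).  The package
deliberately consumes *normalized* matrices — array preprocessing,
probe-to-gene mapping and download from repositories are out of scope,
and exactly one row per gene is assumed.  Missing values are rejected at
validation; identifiers are case-sensitive strings with no aliasing.

# The expressed/not-expressed gate

Every proportion the package reports is computed over *expressed* genes
only.  A gene is expressed when its mean log2 level across all samples
of the study is at or above `detectionThreshold` (closed lower bound;
default 4 log2 units, i.e. well below the U[6, 12] baseline range the
synthetic generator uses).  There is no universally accepted detection
cut-off for normalized arrays, so the threshold is an explicit
configuration knob rather than a constant, and genes that fail it are
carried through every table as `not_expressed` so that denominators are
auditable.

# Differential expression

## Acute contrasts (NEA rule)

For each gene, the linear fold change is
$\mathrm{FC} = 2^{\,\bar t - \bar c}$ where $\bar t$ and $\bar c$ are
group means of log2 values; computing the ratio on the log scale keeps
the 1.2 gate scale-consistent.  A gene is called *up* when
$\mathrm{FC} > 1.2$ **and** a Wilcoxon rank test yields $p < 0.05$;
*down* symmetrically with $\mathrm{FC} < 1/1.2$.  All inequalities are
strict, and no multiple-testing correction is applied by default
(`adjust = "BH"` is available), matching the procedure the rule is
modeled on.

Two numerical decisions deserve explanation:

* **Which Wilcoxon test.**  The contrast groups are unpaired and of
  unequal size (8 vs 4 in one design), so a signed-rank test is
  ill-defined; the rank-sum (Mann–Whitney) test is the default.  A
  paired `signedrank` variant (pairing by replicate order, truncated to
  the shorter group) remains available for users who read the procedure
  the other way.
* **Approximate, not exact, p-values by default.**  At the smallest
  design in scope, 3 vs 3 replicates, the exact rank-sum null
  distribution has only 20 tails: the smallest achievable two-sided
  p-value is 0.1, so an exact test can never call *any* gene at
  $\alpha = 0.05$ and the rule would be vacuous precisely where it is
  needed.  The default therefore uses the large-sample normal
  approximation *without* continuity correction, under which complete
  3-vs-3 separation gives $p \approx 0.0495 < 0.05$.  The price is
  anti-conservativeness at $n = 3$: the achievable test sizes are
  quantized, and the realized null DEG rate at 3 vs 3 is near 0.08
  rather than 0.05 (the fold-change gate absorbs part, not all, of the
  excess).  At the 8-vs-4 design the same default is conservative
  (measured null rate ≈ 0.04, see the null-calibration test).  Users
  wanting strict level control at tiny $n$ should use
  `rankTest = "ranksum_exact"` and accept that no calls survive at
  $n = 3$; the two behaviours cannot be had simultaneously — that is a
  property of rank tests, not of the implementation.  Degenerate input
  (all values tied) is assigned $p = 1$.

## Evolved-versus-parent designs (EA rule)

With a single parent sample there is no within-group variance to test,
so the rule is unanimity-based.  On the linear scale,
$d_i = 2^{e_i} - 2^{p}$ for each evolved strain $i$; a gene is *up* when
every $d_i > 0$ and $\operatorname{mean}(d_i)/2^p > 0.20$, *down*
symmetrically.  One discordant strain abolishes the call.  The 20 %
threshold is read as a linear-scale relative difference (that is the
natural reading of “20 % compared to the parent level”); a
`eaScale = "log2"` option takes the differences on the log scale and
converts the mean back ($2^{\bar d} - 1$) for the same gate.

# Gene-set response profiling

`setDegProportions()` counts, for each set and contrast, the expressed
members called up or down.  Display percentages round **half away from
zero**, which is the convention that reproduces integer percentages
computed from printed numerators and denominators (20/26 → 77 %,
12/13 → 92 %).  `setResponseLevel()` reduces a set to one scalar per
contrast: mean log2 fold change (default for correlations),
up-minus-down proportion, mean treatment-group expression, or the
percent change of the set's mean linear level (the per-strain metric
used for stress-response decline profiles).  How a regulon's many genes
should be reduced to one number before correlating with dose is
genuinely underdetermined; the method token is recorded with every
result rather than asserting one true summary.

Dose and process correlations default to Pearson (Spearman selectable);
contrasts sharing an ethanol concentration stay distinct points, and a
constant input yields a flagged `NA`, never a silent zero.  Enrichment
is a one-sided hypergeometric tail with optional Benjamini–Hochberg
adjustment across sets; the universe defaults to *expressed* genes, the
standard practice, and is an explicit argument because enrichment
results are notoriously sensitive to it.

# Transcription-unit aberrancy

For transcription factors annotated as ethanol-binding proteins, the
package asks whether the expression state of their transcription units
contradicts the regulatory logic.  Only TUs whose *sole* regulator is
the TF in question are scored — with a second regulator the expectation
is confounded.  A TU's call is summarized from its member genes
(default: majority of expressed members; `any` and `all` selectable),
and the four-case rule is:

| sign | TF | TU | verdict |
|---|---|---|---|
| activation | ns | down | aberrant |
| activation | up | not up | aberrant |
| repression | ns | up | aberrant |
| repression | up | up | aberrant |

“Not up” is implemented as `ns` **or** `down`.  The rule enumerates only
`ns`/`up` TF states; a down-regulated TF is classified `indeterminate`
and excluded from both numerator and denominator rather than silently
scored — inventing verdicts for unlisted states would fabricate method.
The per-TF aberrancy level is the percentage of scorable sole-regulator
TUs judged aberrant; zero scorable TUs gives a flagged undefined row.

# Adaptation trends

Monotonicity is assessed on the per-time-point log2 fold change versus
the parent (not on raw levels, not on call sequences).  A series is
`monotone_up` when every consecutive difference is ≥ `-tieTolerance`
and at least one exceeds `tieTolerance` (default 0); constant series
are `non_monotone` by convention.  With zero tolerance the class is
invariant under strictly increasing transforms and reversal swaps the
directions.  *Step-wise* is reported as a stricter flag: monotone with
at most one non-strict step (≥ 3 strict steps out of the 4 differences
in a 5-point course); the two notions are kept separate because
progressive multi-step change is a stronger claim than mere
monotonicity.  Monotone tallies are emitted both per strain and pooled,
since either counting unit is defensible.

Tolerance-annotated genes (`overexpression_tolerant` /
`knockout_tolerant`) are expected to trend up / down respectively;
`concordanceWithAnnotation()` reports the percentage of annotated,
differentially expressed series matching expectation.  The
duplication-region test pairs each expressed region gene's values at two
time points of one strain and applies a one-sided Wilcoxon signed-rank
test for an upward shift; genes are the natural pairing unit, and
all-zero differences yield $p = 1$.

# The synthetic generator

The generator exists so every stage is testable with planted truth and
no downloads.  Its defaults are fixed to the study design it emulates:
seven acute contrasts at 2.5/5/3/15/15/15/15 % v/v ethanol with
replicate groups 3+3, 8+4, 8+4 and four 3+3; six evolved strains
sampled at 384–2496 h against one parent; 4,305 genes.  Baselines are
uniform on [6, 12] log2 units with a configurable fraction generated
below the detection gate; noise is i.i.d. Gaussian on the log2 scale
(the standard idealization of normalized log-intensities), with a
variance-matched $t_5$ option for robustness checks.  Planted structure:

* acute DEGs shifted by ±1.0 log2 units (the smallest effect the
  1.2-fold+test rule should comfortably detect at sd 0.25);
* TF states (up or unchanged) with sole-regulator TUs made consistent
  or aberrant per the truth table above;
* dose-responsive sets shifted linearly in ethanol percent (0.05 log2
  per %), the simplest structure that makes dose-correlation recovery
  testable;
* evolution-arm trajectories accumulating ±0.2 log2 per step, with the
  tolerance-concordant fraction planted as an exact count (0.91 of
  annotated genes) rather than a Bernoulli rate, so the planted
  statistic is the design parameter itself; evolution arrays use sd
  0.05, reflecting replicate-averaged per-strain values;
* a duplication-region emulation: one strain's region genes shifted up
  from 1,824 h onward.

What the generator does **not** emulate: probe-level physics,
inter-gene correlation, batch effects, heteroskedastic intensity-
dependent variance, or genomic sequence.  Passing recovery tests on
these data therefore demonstrates algorithmic correctness under the
stated noise model, not performance on real arrays.

All randomness descends from one integer seed via fixed per-stage
offsets, so identical configs produce byte-identical fixture files and
pipeline outputs (the manifest records an md5 digest of every output).

# Problem sizes in tests

The test and acceptance workloads use scaled-down instances chosen to
keep the statistical questions honest while remaining quick: null
calibration at 5,000 genes on the 8-vs-4 design; end-to-end recovery
pooled over 20 seeds of 150–200-gene studies at the spec conditions
(log2 effect 1.0, sd 0.25, 3 vs 3); the full pipeline at 200–400 genes.
These sizes are the package's own choices; all scale linearly if users
want larger reference runs.

# Known limitations

* The default rank test is anti-conservative at 3-vs-3 designs (see
  above); interpret single-contrast DEG lists from tiny designs
  accordingly.
* The EA rule's unanimity requirement makes it stringent but brittle to
  a single outlying strain; it reports no p-value because it tests
  nothing distributional.
* Aberrancy scoring inherits the ambiguity of summarizing multi-gene
  TUs; the majority rule is robust and order-invariant but can mask a
  split TU.
* Enrichment is a plain hypergeometric stand-in, not an ontology-aware
  method; it shares the universe-sensitivity of all such tests.

# Worked example

```{r example, eval = FALSE}
cfg <- system.file("extdata", "example_config.yaml",
                   package = "regustress")
manifest <- runPipeline(cfg, "run1")
buildReport("run1")
read.delim(file.path("run1", "report_set_response.tsv"))
```
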