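---
title: "Methods: cross-species tissue-enrichment overlap testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species tissue-enrichment overlap testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoverlap)
```

## The analysis in one paragraph

Given replicate RNA-seq abundances for a tissue and for whole bodies in
species A, `orthoverlap` selects tissue-enriched genes, maps them through
single-copy orthogroups into species B, and asks whether they overlap an
independently defined species-B gene set more often than sampling without
replacement predicts. The answer is a Monte Carlo p-value with an exact
hypergeometric tail computed alongside, so the resampling estimate can
always be checked against the closed form.

## Enrichment filtering

**TPM.** Counts are normalised per sample as
$\mathrm{TPM}_g = 10^6 (c_g/\ell_g) / \sum_h (c_h/\ell_h)$ with
$\ell_g$ the effective length in bases. Each sample column then sums to
$10^6$ by construction; the suite asserts this to $10^{-3}$. TPM is a
*relative* unit: when a planted (or real) enriched set recruits many
reads in the tissue group, every realised TPM fold change is pulled below
the underlying count-level fold because the tissue library grows. This
compositional effect is real, visible in the synthetic data, and the
reason the generator keeps planted baseline means in a bounded range (see
below).

**Abundance floor.** Genes with cumulative TPM over all samples strictly
below `min_cumulative_tpm` (default 0.1) are removed; a gene exactly at
the threshold is kept. The floor is applied before testing; the
differential table keeps all genes with a `passed_abundance` flag, so
both counts are recoverable from one object.

**The test.** The upstream tool used by the original analysis platform
is proprietary and its test unnamed, so the package commits to a
two-sided Welch t-test on $\log_2(\mathrm{TPM} + 1)$: standard, robust to
unequal group variances, and reproducible anywhere. Group variances get a
floor of $10^{-8}$ on the log scale so zero-variance genes keep a defined
statistic; a gene identical in both groups gets $p = 1$. The
implementation is vectorised over the gene matrix and is checked against
`stats::t.test()` gene by gene in the unit tests.

Calibration has two regimes, and the suite tests both. When the
log-scale data are Gaussian the Welch test is essentially exact, and the
observed fraction of $p \le 0.05$ on a 2,000-gene null lies within three
binomial standard deviations of 0.05. On negative-binomial counts with
three replicates per group the test is *conservative* (observed level
around 0.03): low counts are discrete and skewed, and the pseudocount
compresses small values. The suite therefore asserts validity (level not
exceeded) on NB nulls rather than exactness; users should expect the raw
p-filter to be slightly strict, never liberal, at small replicate
numbers.

**Fold change** is the ratio of group-mean TPMs with a stabilising
pseudocount (default 0.01; set 0 for the raw ratio). The pseudocount for
the ratio is deliberately smaller than the log-test pseudocount of 1:
the former only guards division by zero, the latter tempers log-variance
at low abundance.

**Selection** requires all three criteria with inclusive boundaries:
fold change $\ge$ `min_fold` (default 5; 2 reproduces the broader
differential regime), $p \le$ `max_p` (default 0.05, raw by default —
an optional Benjamini–Hochberg column exists but is off, since the
filtering convention this mirrors used raw p-values), and the abundance
flag. Selection is monotone in both thresholds, which the suite checks
over threshold ladders.

## Orthology

Orthogroup tables are consumed in the OrthoFinder `Orthogroups.tsv`
dialect (tab-separated, `", "`-joined gene lists, empty cell = no
genes); gene identifiers are compared verbatim after trimming
surrounding whitespace, because no normalisation rule can be assumed for
assembler-generated IDs. Restriction to single-copy orthogroups (exactly
one gene per species) defines the universe $N$. Projection of a gene set
returns the orthogroups whose gene for that species is in the set; genes
without a single-copy orthogroup are dropped and counted (`n_unmapped`),
not raised as errors — the expected funnel narrows at this step. The
overlap is intersected at the orthogroup-ID level, which is the natural
formalisation of "occurring in the same single-copy orthogroup".

## The overlap null and its two p-values

Each Monte Carlo iteration draws $n$ of $N$ orthogroups uniformly
without replacement (base R's `sample.int`, a partial Fisher–Yates, so
uniformity is exact) and counts draws landing in the $K$ marked
orthogroups; the observed count is compared with $k_{obs}$ using
$\ge$ (enrichment; a depletion alternative is exposed). Two estimators
are reported:

* raw: $\hat p = (\#\{\text{null} \ge k_{obs}\})/B$;
* corrected: $(\#\{\text{null} \ge k_{obs}\} + 1)/(B + 1)$, the
  headline value, since a resampling p of exactly 0 is an artefact of
  finite $B$.

The exact tail $P(X \ge k_{obs})$, $X \sim$ Hypergeom$(N, K, n)$, is
computed through `stats::phyper` (log-space stable) and verified in the
tests against exhaustive subset enumeration at $N = 10$
($P(X \ge 3) = 66/252$ for $N{=}10, K{=}4, n{=}5$) and against the Monte
Carlo estimate over a small-parameter grid at $B = 50{,}000$ within four
binomial standard errors.

**Calibration of the corrected estimator.** When $k_{obs}$ is itself a
null draw, the corrected p-value is *super-uniform*: the overlap
statistic is discrete, ties are counted as exceedances, and the add-one
correction shifts mass upward. A two-sided Kolmogorov–Smirnov test
against U(0,1) would reject on discreteness alone, so the suite runs the
one-sided KS (no anti-conservative excess of small p-values) at level
0.01 on 500 replicates — the check the "calibrated, never liberal"
property actually supports.

The seed is stored in every result and reruns are bit-identical; the
RNG state of the calling session is restored afterwards.

## Contamination screen

Per query, the best (minimum) e-value within the in-group and out-group
subject sets feeds the alien index
$AI = \ln(E_{in} + 10^{-200}) - \ln(E_{out} + 10^{-200})$; the floor
keeps logs finite when a search reports $E = 0$, and a group with no hit
receives the sentinel $E = 1$ so single-sided queries score strongly
negative. The cited tool family does not restate its formula in one
place, so the definition above (natural logs, strict cutoff at 40) is
the package's documented choice, configurable rather than asserted as
identical to any specific release. $AI$ is antisymmetric and invariant
under common scaling of both e-values far above the floor; flagging uses
strict $AI >$ cutoff, so a query exactly at 40 is not flagged. Queries
with no hits at all stay in every denominator and are never flagged.

## The synthetic generator

`simulate_two_species()` emulates the data *structure* of a two-species
comparison, not read-level sequencing: a configurable orthogroup
composition (single-copy; multi-copy with 2–4 genes on one side;
species-specific genes as single-species orthogroups); per-gene
negative-binomial counts (baseline means log-uniform over
`nb_mean_range`, default 1–1000; dispersion `nb_dispersion`, default 0.1
so that $\mathrm{Var} = \mu + 0.1\mu^2$); gene lengths log-uniform
300–10,000 bases so TPM is deliberately *not* proportional to counts; a
planted enriched set whose tissue-group means are multiplied by
`planted_fold`; a planted species-B target set positioned to realise
`planted_overlap` exactly; and a BLAST best-hit table with a planted
contaminant fraction (out-group e-values $\le 10^{-40}$ against in-group
$\ge 10^{-2}$). Feasibility is validated before generation — a planted
overlap larger than either projected set is an error, never a silent
truncation — and a fixed seed gives byte-identical output files.

Planted enriched genes draw their baseline means from
`planted_mean_range` (default 50–200): high enough that the planted
effect dominates counting noise, bounded so the extra tissue reads shift
the TPM composition only modestly. With unbounded planted means the
planted genes can approach half the tissue library, dragging every
realised fold toward the selection boundary — an instructive artefact of
relative abundance units, but not a useful regime for ground-truth
recovery checks.

What the generator does **not** emulate: read-level error, splice
isoforms, GC or length bias in counting, batch effects, correlated genes,
or realistic BLAST score distributions. Passing the end-to-end tests
therefore demonstrates that the pipeline's logic and statistics are
correct on data satisfying its model assumptions — not that any
particular real dataset meets them.

## Problem sizes and numerical choices

The test suite runs at desk scale: 60–2,500 orthogroups for module
tests; the end-to-end recovery uses 1,000 single-copy orthogroups, 60
planted enriched genes (fold 12, dispersion 0.02, five replicates per
group — the strong-signal regime in which full recovery is expected),
50 targets, planted overlap 20, and $B = 10{,}000$; the calibration
sweep uses 500 replicates of $B = 500$ at $N = 500$. The study-scale
null ($N = 8{,}682$, $K = 88$, $n = 430$, $k_{obs} = 31$,
$B = 10{,}000$) runs in a few seconds; its exact tail is $\sim 10^{-16}$,
so zero exceedances is the essentially certain outcome at any seed and
the corrected p is $1/(B+1) \approx 10^{-4}$.

Numerical conventions collected in one place: log-test pseudocount 1;
ratio pseudocount 0.01; log-scale variance floor $10^{-8}$; alien-index
floor $10^{-200}$; no-hit sentinel e-value 1; boundary semantics — fold
and p thresholds inclusive, abundance removal strictly below threshold,
AI cutoff strictly above; ties in "best overall hit is out-group" resolve
to `FALSE`.

## Limitations

* The Welch-on-log choice is a documented stand-in for an unnamed
  proprietary test; numerical agreement with that platform is not
  claimed, and gene lists filtered at identical thresholds may differ.
* Raw-p filtering (no multiplicity correction) mirrors the analysis
  convention this package reproduces; treat the enriched list as a
  screening set, not as FDR-controlled discoveries.
* Exactly two species are supported; multi-species orthogroup tables
  must be reduced upstream.
* The overlap null treats orthogroups as exchangeable; it does not model
  expression-level-dependent detectability of orthologs, which would
  require a stratified null.
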