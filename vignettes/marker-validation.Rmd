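---
title: "Validating single-cell annotations against in situ reference transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating single-cell annotations against in situ reference transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insituanno)
```

## The problem

Cell-type annotation in single-cell RNA-seq is usually driven by marker
genes, but in most non-model species there is no high-confidence marker
catalog to draw on. Wood-forming (differentiating xylem) tissue in *Populus*
is a sharp example: it contains three cell types — libriform fibers and
vessel elements (axial system) and ray parenchyma (radial system) — and
published marker sets for them disagree. When markers are borrowed from
*Arabidopsis* orthologs or from earlier studies, the annotation they produce
may be wrong in ways that are invisible from the single-cell data alone.

Laser capture microdissection (LCM) offers an independent anchor: excising
each cell type directly from tissue sections yields cell-type-pure bulk
("in situ") transcriptomes whose identity is guaranteed by morphology, not
by markers. `insituanno` implements a two-round correlation procedure that
uses such references to score how well each claimed marker actually tracks
its claimed type.

## The two-round procedure

Let $X$ be the genes-by-cells expression matrix and $L_s$ the profile of LCM
reference sample $s$ (each sample carries a cell-type label and a replicate
index; the default design is 3 types $\times$ 3 replicates).

**Round one** (`compute_cell_similarity`). For every cell $c$ and reference
sample $s$, compute a correlation coefficient over the shared gene space:
$$ S_{cs} = \mathrm{cor}\big(X_{\cdot c},\, L_s\big). $$
$S_{cs}$ measures how much cell $c$ resembles the in situ transcriptome of
$s$. Spearman is the default: ranks absorb the strong mean–variance
mismatch between sparse single-cell counts and deep bulk profiles. Pearson
on log-CPM is available as an alternative.

**Round two** (`concordance_analysis`). For every candidate marker gene $g$
and reference sample $s$, correlate across cells:
$$ R_{gs} = \mathrm{cor}_c\big(X_{g\cdot},\, S_{\cdot s}\big). $$
If $g$ genuinely labels type $T$, cells expressing $g$ highly should be
exactly the cells that resemble $T$'s references, so $R_{gs}$ should be
positive for $T$'s replicates and lower (often negative) elsewhere.

Because references are kept per replicate, each marker gets $n$ replicate
correlations per type (3 by default) — a natural unit for a between-type
two-sample t-test. Student's pooled-variance test is the default; Welch is
available. Significance is rendered as stars with strict thresholds:
`***` for $p < 0.001$, `**` for $p < 0.01$, `*` for $p < 0.05$, `ns`
otherwise (so $p = 0.05$ exactly is `ns`).

**The call rule** (`call_marker_type`). Let $T^\*$ be the type with the
largest mean $R$. If that mean is not positive, the marker annotates
nothing ("none"). Otherwise the call is $T^\*$ together with every type not
significantly below it ($p \ge \alpha$, default $\alpha = 0.05$). A
singleton is a unique call; anything larger is ambiguous; exact ties in the
mean are declared ambiguous rather than broken by order. A marker is
*consistent* only when its call is unique and equals its claimed type —
this is the per-source accounting that `evaluate_catalog` reports, exposing
markers that annotate the wrong type or several types at once.

Two genuinely open choices are worth naming. First, the second round could
use type-averaged similarity columns instead of per-replicate ones; we keep
replicates because they are the only construction that supplies groups
($n = 3$) for the t-test under a triplicate LCM design. Second, the
between-type comparison could be pairwise or one-vs-pooled-others; pairwise
is the default and `pooled = TRUE` switches to the other reading. No
multiple-testing correction is applied by default (the stars are
raw-threshold stars); `p_adjust = "BH"` adds Benjamini–Hochberg values in a
separate column.

## Dataset overlap

When two single-cell datasets of the same tissue are compared
(`expressed_gene_overlap`), the comparison is over their expressed-gene
complements: gene sets detected at `min_count` in at least `min_samples`
cells. Two set statistics are always reported together so the choice is
auditable: the intersection over the smaller set (`min_denominator`, the
conventional "overlap rate") and the Jaccard index (intersection over
union, never larger than the former). The overlap is over transcriptome
space, not cell barcodes — independently sampled datasets of the same
tissue share genes, not cells.

## The synthetic-data generator

The generator emulates the study design the pipeline is built for: $K = 3$
cell types; per-type bulk references in triplicate with lognormal replicate
noise (`replicate_noise_sd = 0.2`, a typical bulk replicate CV of ~20%);
and single cells drawn per type from a negative-binomial count model, the
field-standard overdispersed model for UMI counts.

* Baseline gene means are lognormal (`base_mean_log_sd = 1`, a realistic
  spread of expression levels across genes).
* Each type receives `markers_per_type` disjoint marker genes whose linear
  mean is multiplied by $2^{f}$ in that type only, so the planted
  `log2_fold_change` $f$ is the expected log-scale contrast.
* Counts for a cell of type $T$ are NB with mean
  $\mathrm{depth} \times p_T$ ($p_T$ the type profile normalized to sum 1)
  and dispersion 0.5; depth defaults to 5000 total counts per cell.
  Per-cell depth is held fixed — library-size variation would only blur the
  planted contrasts without changing what the tests measure.
* One integer seed drives each generator function; identical seed and
  parameters give bit-identical output.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, cell-cycle structure, zero-inflation beyond NB, or any real
read-level artifact. Passing tests on synthetic data therefore demonstrate
that the procedure's logic and statistics behave as designed under its own
model — not that any particular real dataset is well annotated.

### The compositional ceiling

One generator behavior deserves emphasis because it mirrors real biology.
Sequencing depth is a budget: when planted markers are given extreme
fold-changes (say $2^8$) while depth per cell is fixed, the markers absorb
a large share of each cell's reads and every other gene is proportionally
depressed in the marker-bearing type. Two consequences follow. The
empirical log2 ratio of a marker's counts between types undershoots the
planted $f$ unless markers are a small fraction of the library (the
recovery tests use geometries where that fraction is negligible). More
subtly, the marker-bearing cells' global profiles are distorted enough that
their round-one similarity to *their own* references stops exceeding other
cells', and the round-two correlation collapses toward or below zero. The
procedure is therefore at its best for markers with realistic (2–16 fold)
enrichment; a "marker" carrying half the library is outside its operating
range, in simulation and in reality alike.

## Numerical and degenerate-input choices

* Gene ids match by exact, case-sensitive string equality; the aligned gene
  space is ordered lexicographically in the C locale so results do not
  depend on the session locale.
* Constant expression vectors have no defined correlation; affected cells
  or markers are flagged `NA` and counted, never silently dropped or set to
  zero. Markers absent from the cell matrix are skipped with a message.
* All-zero columns carry no information and are dropped by normalization
  with a warning; CPM columns sum to $10^6$ within numerical tolerance.
* Degenerate t-tests (both groups constant) return $t = 0, p = 1$ when
  equal and an infinite statistic with $p = 0$ when not.
* `run_pipeline` echoes every option, default and seed into
  `run_log.json`, and two runs of the same config are byte-identical.

## Problem sizes used in the test suite

The packaged checks run the full study design — 2000 genes, 20 markers per
type, fold 3, 300 cells per type, seeds 1–5 — for recovery (every planted
marker must receive the unique correct call in at least 95% of cases) and
null calibration (markers planted at fold 0 must receive unique calls at
most 10% of the time at $\alpha = 0.05$), alongside smaller instances for
the formula-level oracles (brute-force correlation and textbook t
formulas, agreement to $10^{-10}$). These sizes were chosen as the smallest
at which the operating characteristics are stable and measurable.

## Limitations

The validation is only as good as the references: LCM profiles carry their
own dissection impurities and bulk-vs-single-cell platform effects that the
correlation procedure absorbs but cannot remove. The call rule with $n = 3$
replicates per type has limited power — a real but weak marker may land in
"ambiguous" — and the positivity gate makes "none" calls common for genes
whose expression is dominated by technical variation. Nothing in the
package decides what the *true* markers of a tissue are; it only measures
whether claimed markers behave concordantly with in situ references.
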