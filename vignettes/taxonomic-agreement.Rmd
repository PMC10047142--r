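---
title: "Measuring hierarchy-aware inter-annotator agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hierarchy-aware inter-annotator agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(taxagree)
```

## The setting

Several annotators independently read the same set of free-text clinical
reports (e.g. chest X-ray reports) and assign labels from a shared labeling
scheme. Each assignment carries a *polarity*: a finding can be asserted
present (positive) or explicitly absent (negative). The labeling scheme is a
forest: labels have parents, so two annotators can describe the same finding
at different levels of specificity — one writes *infiltrate*, the other
writes its child *consolidation*.

This package answers two complementary questions about such a panel:

1. **Exact agreement** — treating each (label, polarity) as an independent
   binary decision per report, how well does an annotator agree with a
   reference? Measured by the Matthews correlation coefficient (MCC).
2. **Taxonomic agreement** — if near-miss disagreements along an
   ancestor–descendant chain are given partial credit, how many of an
   annotator's labels can be matched to another annotator's labels at all?
   Measured by maximum-weight bipartite matching of per-report label sets.

## The label hierarchy

A hierarchy is a node table (`label_id`, `display_name`, `parent_id`,
`category`) validated into a forest — duplicate ids, unknown parents and
cycles are rejected. Two labels are *lineally related* when one is an
ancestor of the other; otherwise they are *cross-branch*. `lineal_distance()`
counts parent edges along the chain and is `NA` exactly for cross-branch
pairs. Each polarity may restrict the scheme to a *polarity universe* (the
set of labels that may be asserted absent is typically smaller than the set
that may be asserted present).

```{r}
h <- parse_hierarchy(system.file("extdata", "cxr_hierarchy.json",
                                 package = "taxagree"))
label_relation(h, "infiltrate", "consolidation")
lineal_distance(h, "lung", "consolidation")
```

## Exact agreement: micro-averaged MCC

For one annotator, one reference, one label and one polarity, every report
falls into exactly one confusion cell: TP (both used the label), FP (only
the annotator), FN (only the reference), TN (neither). The MCC is

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Conventions, chosen deliberately:

* **Micro-averaging** pools the four counts across the *entire* polarity
  label universe — including labels neither annotator ever used, which
  contribute true negatives — and computes a single MCC from the pooled
  counts. A macro average (mean of per-label MCCs over labels used at least
  once) is available via `average = "macro"`, and `per_label_mcc()` exposes
  the per-label values.
* **Zero denominator**: when any factor under the square root is zero the
  coefficient is defined as 0, the standard "no better than random"
  convention for degenerate margins.
* **Exactness**: the denominator is computed as one square root of the
  exact integer product whenever that product is representable in double
  precision (below $2^{53}$), so perfect agreement is exactly 1 and perfect
  complement exactly −1; split square roots are used only beyond that, to
  avoid overflow.
* Polarities are never pooled: positive and negative agreement are separate
  statistics.

```{r}
tbl <- simulate_panel(simulation_config(h, n_reports = 50, seed = 7))
micro_mcc(tbl, "rad_novice", "truth", "positive", hierarchy = h)
```

## Consensus annotators

`apply_consensus()` builds a virtual annotator by k-of-n voting per
(report, label, polarity) — e.g. a gold standard as 2-of-3 among senior
annotators, or a 4-of-6 panel majority. Voting is deliberately
hierarchy-blind: a vote for *consolidation* is not a vote for *infiltrate*.
Partial credit across the hierarchy belongs to the matching layer, not to
consensus formation.

## Taxonomic agreement: maximum-weight matching

Per report and polarity, the two annotators' label sets form the two sides
of a bipartite graph. An edge connects identical labels (weight
`exact_weight`, default 2) or lineally related labels (weight
`lineal_weight(d)`, default $1/(1+d)$ at lineal distance $d$). Cross-branch
pairs get no edge, so they can never be matched; labels left without a
partner are counted as *unmatched* — the unit of disagreement. The matching
maximizes total weight (engine: `igraph::max_bipartite_match()`; the test
suite checks it against an independent exhaustive search).

The default weights make an exact pair strictly better than any
rearrangement of its endpoints into two lineal pairs, so exact agreement is
never sacrificed for partial credit. Ties in total weight are broken
deterministically: prefer more matched pairs, then the lexicographically
smallest pair sequence, so results are reproducible across platforms.

```{r}
match_report(c("infiltrate", "pleural_effusion"),
             c("consolidation", "infiltrate"), h)
```

`accumulate_pair()` sums matched/unmatched counts over all reports for one
annotator pair; `pairwise_matrix()` assembles the symmetric matched-count
matrix over a roster; `agreement_matrix()` projects accumulated pair counts
onto the subtree under one category root.

## Label-usage accounting

`label_frequencies()` counts label uses per polarity, and `pareto_cover()`
reports the smallest prefix of most-used labels whose cumulative share
reaches a target fraction (default 80%). Count ties are broken by label id
so the prefix is deterministic.

## The synthetic panel generator

The study conditions the generator emulates are its defaults: 200 reports,
a six-annotator panel of mixed experience plus a ground truth, skewed label
frequencies (weights $\propto$ rank$^{-\text{skew}}$), a mix of label-dense
and label-free reports, and negative findings drawn from a small set of
frequent labels. Each simulated annotator has four behavioral parameters:

* `p_detect` — probability a true finding is annotated at all;
* `p_drift` / `drift_up_share` / `drift_q` — probability the label drifts
  to a lineal relative, the share of drifts toward ancestors, and the
  geometric distribution of the drift distance;
* `fp_rate` — Poisson-expected spurious labels per report, drawn from the
  same skewed marginal, so over-annotators overuse the common labels;
* `neg_consistency_boost` (< 1) — shrinks the miss, drift and spurious
  rates for negative findings, encoding that explicit absences are
  annotated more consistently than positive findings.

All randomness flows from one master seed; each annotator draws from a
private substream derived by hashing its id, so adding an annotator never
changes anyone else's draws. The profile defaults are chosen to reproduce
qualitative patterns only (orderings and directions), not any quantitative
result; no quantitative annotator-behavior parameters are known for the
real panels this mimics.

## One-call pipeline

`run_full_analysis()` takes a YAML file or list naming the hierarchy, the
annotation table, the consensus rules and an output directory, and writes
MCC tables, matched/unmatched matrices, per-category agreement matrices,
Pareto tables and a JSON manifest. Re-running on identical inputs produces
a byte-identical bundle (the manifest records input checksums, not
timestamps).

## Scope and limitations

* Matching is per-report and one-to-one; it does not model one annotator
  summarizing two sibling findings under their common parent (that parent
  can match only one of the two).
* Consensus voting is hierarchy-blind by design (see above).
* MCC treats labels as independent binary decisions; the pooled TN count
  grows with the universe size, so micro-MCC values are only comparable
  across analyses that use the same label universe.
* The exhaustive matching oracle is for testing and is exponential; it
  refuses sides larger than 8 labels.
* The generator models label assignment only — not report text, annotation
  time, or correlated errors between annotators.
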