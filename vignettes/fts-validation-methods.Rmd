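---
title: "Validating a family-distress screener against a triangulated criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a family-distress screener against a triangulated criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftsvalid)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
and the choices we made where the design was genuinely open.

## The criterion reference

Screening instruments are usually validated against a gold standard. In
settings where none exists for family relational distress, a criterion
reference can be *constructed* by triangulating several imperfect
sources. The package implements a three-source rule:

* **Leader source** — a community leader rates the family's functioning
  on a 4-point scale (1 = worst); ratings of 1–2 flag the family.
* **Self source** — every participating member rates the family on the
  same scale; *any* rating of 1–2 flags the family. The rule is
  deliberately sensitive: one member perceiving distress is treated as
  signal, not noise.
* **Clinical source** — a consensus GARF score (1–99, five bands from
  Most Dysfunctional 1–20 to Most Functional 81–99) of ≤ 60 — the three
  dysfunctional bands — flags the family.

A family flagged by two or more sources is a case; by none, a non-case;
by exactly one, dropped from further analysis (the sources disagree and
the truth is unknowable at this design's budget). The rule is a
partition, and it is monotone: adding a flag can only move a family
toward caseness. Both properties are asserted in the test suite.

Degenerate inputs are rejected, never repaired: non-integer or
out-of-range GARF scores, ratings outside 1–4, an empty self-rating set,
and duplicate family ids are all errors. The study design this mirrors
had complete sources for every family; we decided (rather than guessed
an imputation) that a missing source should stop the analysis. GARF
domain subscores (organizational structure, emotional climate,
problem-solving) are carried through but never used by triangulation;
only the overall consensus enters the rule.

## Item coding and gradient screening

Candidate items come in two formats. *Ladder* items take integer
responses 1–10 on a visual 10-step ladder. Positively worded ladder
items are reverse coded (`11 − raw`) so a high code always means more
distress. The reverse-coding key is fixed in
`inst/extdata/fts_items.csv` from the item wording (e.g. "How much love
is in your family?" reverses; "How often does your family have
quarrels?" does not); the source material does not print such a key, so
the fixture documents ours.

*Communication* items ask how the family responds to a specific
stressor and are coded onto 0–3. The numeric map is a design decision:
qualitative evidence names avoidant and aggressive communication as
distress indicators, so we code "Quarrel" → 3, "Not talk about it" → 2,
"Talk calmly" → 0 and "You have not had the problem" → 0. Code 1 is
unused by the default map; the map is an argument of `code_response()`
and can be replaced wholesale. Under the endorsement rule below only
the 2/3 versus 0/1 boundary matters, so any alternative map that keeps
quarreling and avoidance on the distressed side is observationally
equivalent at the screening stage.

Endorsement is a code of 6–10 (ladder) or 2–3 (communication). The
**gradient score** of an item for a reporter group is

$$\Delta = \hat p_{\text{case}} - \hat p_{\text{non-case}},$$

the difference in endorsement proportions among informants from case
and non-case families. Adults are pooled across families, one row per
informant, without weighting — endorsement percentages are reported at
the informant level, and at this design's scale (one or two adults per
family) weighting schemes are indistinguishable anyway. Missing
responses are excluded item-wise, so each item keeps its own
denominator; proportions are fractions internally and percentages only
in reports. `gradient_table()` is checked against a brute-force
counting oracle, and satisfies two symmetries the tests assert:
swapping the groups negates every gradient, and identical response
multisets give exactly zero.

## Cross-validated variable importance

Gradients look at items one at a time. The second screen trains
tree-based classifiers — a CART tree, bagged trees, and a random forest
— to predict family caseness from the whole coded battery, separately
for adult and child reporters, and ranks items by how much the models
rely on them.

Resampling is repeated stratified k-fold cross-validation, by default
10 folds and 5 repeats, with folds assigned to *families*, not
informants. Grouping matters: informants from one family share a label
and correlated responses, and ungrouped folds would leak that
information across the split. The fold table is attached to the result
and the suite asserts no family ever straddles a split.

Importance is each model's built-in measure, averaged over the
cross-validation training fits and scaled so the best item in each
model scores 100: for the CART tree, the split-goodness sum that also
credits surrogate splits; for the bagged and random forests, the Gini
impurity decrease accumulated over all splits. We considered held-out
permutation importance and rejected it after implementation: with
several strongly discriminating, mutually redundant items, greedy trees
(especially bagged trees, where every tree sees all predictors) use
only the strongest item, so permuting a genuinely discriminating but
unused item changes nothing and its permutation importance is exactly
zero. Built-in measures credit surrogate and deeper splits and do not
suffer this masking; the planted-item recovery test (below) is where
the difference shows.

Missing codes are imputed to the per-item median before model fitting —
trees need complete inputs, and the median cannot move a value across
the endorsement boundary for any item with a clear majority side.
Everything is deterministic given the seed.

Rankings are aggregated as the mean rank per item across models (ties
broken by mean scaled importance, then item id), with top-20 membership
per reporter group. The final selection orders items by a composite,
auditable rule — the count of evidence wins among {top-20 adult, top-20
child, adult gradient ≥ 0.15, child gradient ≥ 0.15}, then mean
gradient, then item id — and truncates to the target size (30). Manual
*theory flags* can force items in or out, replacing the original
expert-judgment step with an explicit, recorded override. The 0.15
gradient threshold is a screening convention (15 percentage points
separates "discriminates" from sampling noise at this scale); both it
and the top-k cut are configuration, not constants.

## Scoring and internal consistency

Each coded response is rescaled to [0, 1] by the unique affine map of
its code range — ladder `(c − 1)/9`, communication `c/3` — and the
30-item total therefore spans 0–30, higher meaning more distress. When
an informant answers at least 90% of the items, the total is prorated
by `30/n_answered`; below that the score is marked invalid. The
completeness threshold is configurable; the source design is silent on
missingness, and prorating keeps the 0–30 metric comparable across
informants without imputing content.

Internal consistency is **standardized alpha**,
$k\bar r / (1 + (k-1)\bar r)$ with $\bar r$ the mean off-diagonal
inter-item Pearson correlation. The tests verify it against an
algebraically independent route (Cronbach's formula on z-scored items)
and its closed-form boundary cases; zero-variance items are an error
naming the item, since they have no defined correlation.

## Diagnostic validity

The unit of analysis is the informant: each adult and each child is
scored separately against their family's label, which is why error
counts can exceed family counts. The classification rule is
*distressed ⇔ total ≥ τ*. Candidate thresholds are the midpoints
between consecutive distinct observed totals plus one sentinel beyond
each extreme, which enumerates every achievable confusion matrix
exactly once. The reported cutoff minimizes |Se − Sp| (ties: larger
Se + Sp, then the smaller threshold); published cutoffs of this kind
fall between attainable scores, so the ≥-versus-> choice is
observationally irrelevant there, but it must be fixed and is.
Youden's index is available as an alternative.

AUC is the Mann–Whitney estimator (ties count ½), which equals the
trapezoidal area under the empirical ROC — the suite asserts the
equality on hundreds of random instances, alongside invariance under
strictly increasing score transforms and agreement with the pROC
package. Its confidence interval uses the Hanley–McNeil standard error
and is deliberately **not truncated** to [0, 1]: small samples with
high AUC can push the normal-approximation upper bound above 1, and
truncating would misrepresent the estimator this mirrors. Sensitivity
and specificity get Clopper–Pearson exact intervals (via beta
quantiles, hitting 0 and 1 exactly at the boundaries). Child–adult
agreement is the Pearson correlation of totals paired by family, with
an optional adult-role filter; fewer than three pairs is an error.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating situation the pipeline
assumes, with defaults matching the study's shape:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 30 | balanced community nomination |
| `prevalence` | 0.5 | P(latently distressed) — leaders nominated high/low distress in equal proportions |
| `p_two_adults` | 0.47 | families contributing a second adult |
| `leader_se`, `leader_sp` | 0.85, 0.85 | leader flag accuracy by state |
| `garf_means`, `garf_sds` | 50/75, 10/10 | consensus GARF by state (rounded, clipped to 1–99) |
| `self_flag_probs` | 0.60/0.35/0.25 vs 0.05 | P(member self-rates ≤ 2) by role and state; female adults most likely to report distress in case families |
| `child_adult_latent_correlation` | 0.85 | within-family severity coupling |
| `item_loading` | 0.9 | item-response loading on informant severity |

Item responses follow a two-stage model: endorse with the state- and
group-specific probability, then fall uniformly within the endorsing
(6–10 / 2–3) or non-endorsing (1–5 / 0–1) range. The two stages are
driven by a Gaussian copula on an informant *severity* latent
(`z = a·sev + √(1−a²)·ε` against the threshold `Φ⁻¹(1−p)`), which
preserves the stated marginal endorsement probabilities exactly — the
law-of-large-numbers test checks this at roughly 12,000 informants to
±0.02 — while correlating responses within an informant and, through
the severity coupling, between each child and their family's adults.
With the default loading of 0.9 the scale is internally consistent
(high alpha) and child totals track adult totals near the configured
latent correlation; at loading 0 the model degenerates to independent
two-stage draws.

`planted_battery()` assigns known endorsement parameters to the 66-item
template: 30 positive discriminators with gradients cycling 0.3–0.6
(the quarrels analogue planted at 0.59 vs 0), 30 null items, 6 negative
discriminators. Ground truth (latent state, severities) is returned in
a separate table that no analysis stage reads.

What the generator does **not** emulate: item content and wording
effects, response styles (acquiescence, extreme responding),
informant-specific reporting biases beyond the severity latent,
within-family self-rating agreement patterns, and demographic structure
beyond roster shape. Passing recovery tests therefore show the
*machinery* is correct under the assumed structure, not that the
instrument performs identically on real families.

A separate fixed fixture, `figure3_fixture()`, encodes the published
source-concordance pattern (8 families flagged by three sources, 4 by
two, 5 by one, 13 by none; per-source totals 13/11/13). The printed
marginals under-determine the joint pattern; the fixture fixes one
allocation — 3 of the 4 two-source families as leader + self, the most
common two-source concordance, and 1 leader + clinical; single-source
families split 1/2/2 — and the caseness counts the tests assert depend
only on the per-category totals, not on that allocation. Triangulating
the fixture yields 12 cases, 13 non-cases and 5 dropped families, so 25
of 30 enter the analysis (the arithmetic 12 + 13 is what the package
reports as retained).

## Problem sizes and determinism

The test suite runs the heavy recovery checks at sizes chosen to make
their sampling error small relative to the asserted tolerance while
staying desk-scale: the Gaussian cutpoint recovery uses 2,000 scores
per group (the equal-Se/Sp point of N(12, 2²) vs N(6, 2²) is 9 with
Se = Sp = Φ(1.5) ≈ 0.933); planted-item recovery uses 20 replicates of
100 informants over 66 items with full 5×10 grouped cross-validation;
the child–adult correlation recovery uses 500 families; the
law-of-large-numbers check uses 5,000 families with a reduced item
loading so informant-level draws are nearly independent. Every
stochastic component takes an explicit seed, the generator is
byte-reproducible given its configuration, and `run_pipeline()` writes
a manifest with a configuration hash and per-file checksums so a rerun
can be verified file-for-file.

## Known limitations

* The pipeline reproduces a *methodology*, not the original dataset:
  the study's raw responses are unavailable, and its final item choice
  included human judgment that theory flags can encode but not rederive.
  The shipped item table is authoritative for the instrument itself.
* The composite selection rule is one defensible formalization of a
  judgment process; alternative weightings of gradient versus
  importance evidence are not explored.
* Informant-level ROC analysis treats informants from one family as
  independent given the label; with 1–3 informants per family the
  effect on interval coverage is modest but real, and the reported
  intervals should be read accordingly.
* The accuracy headline weights informants equally; family-weighted
  accuracy can be obtained by passing family-mean scores to
  `evaluate()`, and the two differ when family sizes do.
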