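---
title: "Morphological typing of the circle of Willis: rules, statistics, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological typing of the circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowillis)
```

## The problem

The circle of Willis (COW) is the arterial ring at the base of the brain that
links the anterior circulation (the two anterior cerebral arteries, joined by
the anterior communicating artery, ACoA) with the posterior circulation (the
two posterior cerebral arteries, joined to the carotid system by the posterior
communicating arteries, PCoA). Its ability to redistribute blood flow after an
occlusion depends on which segments exist and how well they are developed, and
anatomical variation is the norm rather than the exception: in the large
healthy-male MRA cohort this package models, only about one subject in eight
has a fully closed ring.

`cowillis` implements the complete typing system for that kind of survey as a
deterministic, testable pipeline: per-subject vessel measurements in, category
labels and population statistics out.

## The classification rules

All rules operate on luminal diameters in millimetres. Two conventions apply
throughout:

* **Absence threshold.** A vessel narrower than 0.5 mm cannot sustain
  effective collateral perfusion and is treated as absent, as is a vessel that
  the angiogram does not visualize at all (`NA` in the data model). A recorded
  diameter of exactly 0 is rejected at validation as ambiguous — absence is a
  distinguished state, not a zero width.
* **Most severe class wins.** Where a side satisfies two grades at once
  (possible, e.g. 1.8 mm versus 0.85 mm satisfies both the mild-variation
  difference band and the half-contralateral rule), the more severe grade is
  assigned, because the grades form an escalating severity scale.

### ACA-A1 grading (`classify_a1`)

Each A1 segment is graded against its contralateral partner:

| grade | rule |
|---|---|
| `absent` | not visualized, or diameter < 0.5 mm |
| `hypoplasia` | diameter < half the contralateral, **or** the smaller side of a pair differing by > 1.0 mm |
| `mild_variation` | the smaller side when the left–right difference lies in [0.5, 1.0] mm (inclusive at both ends) |
| `normal` | otherwise; the larger side of an asymmetric pair is normal, as is the surviving side when the contralateral A1 is absent |

Boundary conventions were genuinely open and are fixed as follows: a
difference of exactly 0.5 mm is already mild variation (normal development
requires a difference *below* 0.5 mm), a difference of exactly 1.0 mm is still
mild variation (the band is read as inclusive), and a pair differing by more
than 1.0 mm whose smaller side is nevertheless at least half the contralateral
(e.g. 3.0 vs 1.7 mm) is graded hypoplasia on the smaller side — this case is
not covered by the verbal rules and assigning it to hypoplasia keeps the four
grades exhaustive.

### Anterior type (`classify_anterior`)

Types I–III have a closed anterior ring (ACoA patent): I both A1 normal, II
worst side mild variation, III worst side hypoplasia. A1 absence decides type
IV regardless of the ACoA. Without a patent ACoA, balanced development is V1
and unbalanced V2. An ACoA recorded as `unclear` (obscured on imaging) is kept
as its own state in the data layer but folds into "not patent" for typing,
which places those subjects in the nonintegral anterior fraction — consistent
with how the source cohort counts its 29 obscure cases.

### PCA side type (`classify_pca_side`)

`adult` when the P1 segment carries the PCA (P1 diameter at least the
ipsilateral PCoA; equality is adult because fetal configurations require a
strictly smaller P1). The fetal-type (FTP) subtypes: `ftp_I` P1 present but
narrower than the ipsilateral PCoA; `ftp_II` additionally below half the
contralateral P1; `ftp_III` (pure FTP) P1 absent, the PCA formed by PCoA
extension; `ftp_IV` dual PCA fed by both the basilar and the internal carotid
artery. A side with neither P1 nor PCoA (and no dual PCA) has no posterior
supply at all and is rejected as an impossible record rather than forced into
a category.

### Posterior type (`classify_posterior`) and ring category (`classify_cow`)

The posterior types a–k combine the two side types with PCoA presence
(diameter ≥ 0.5 mm); `k` (any dual PCA) takes precedence. The ring is
`integral` when both half-rings are complete (anterior I–III and posterior
a–c), `nonintegral` when neither is, `partial` otherwise. Within integral
rings, a developmental-variation flag marks hypoplasia anywhere on the ring:
anterior type III or posterior type b/c. On the published cross-tabulation
this flag audits exactly: 105 of the 275 integral subjects are flagged,
leaving the 170 nonvariation-integral subjects.

## The statistics

Three procedures are implemented from first principles, because reproducing
the published values depends on their exact conventions:

* **Pearson χ²** (`pearson_chi2`): \(\sum (O-E)^2/E\), expected counts from
  the observed margins, *no* continuity correction anywhere — the 2 × 2 values
  11.578 and 148.174 are only reproducible without Yates' correction.
* **Linear-by-linear association** (`linear_by_linear`): the one-df trend
  statistic \((N-1)\,r^2\) with \(r\) the count-weighted correlation of the
  row and column scores. The \((N-1)\) factor (not \(N\)) is required to
  reproduce 13.340 and 9.188. Default scores are consecutive integers (rows
  1..R, columns 0..C−1, the first column typically being a reference/"none"
  category); the statistic is invariant under affine rescaling of either
  score vector, so the defaults are conventions, not assumptions. Constant
  scores over the observed cells are rejected as degenerate.
* **Tie-corrected rank-sum** (`ranksum_ordered`): the Wilcoxon–Mann–Whitney
  normal approximation on ordered categories, midranks per tie block,
  variance \(\frac{n_1 n_2}{12}\left[(N+1)-\frac{\sum_k (t_k^3-t_k)}{N(N-1)}\right]\),
  no continuity correction. This reproduces Z = 9.944 and the mean ranks
  2130.10 / 2362.90 on the A1 side comparison exactly.

p-values are kept at full precision; a published "P = 0.000" is interpreted as
p < 0.0005 in assertions.

### A known non-reproducible value

The published Z for the left/right P1 status comparison is 2.576 with
p = 0.01. The tie-corrected statistic on the printed counts — under the very
convention that reproduces the other rank-sum exactly — is 2.4668
(p = 0.0136), confirmed independently by `wilcox.test(exact = FALSE,
correct = FALSE)` on the expanded data. Since 2.5758 is precisely the
two-sided normal quantile for p = 0.01, the published Z appears to have been
back-derived from the rounded p-value. The package computes and reports
2.4668; the mismatch is recorded in the packaged `discrepancies.tsv` and the
corresponding acceptance expectation is deliberately left failing rather than
weakened.

## Printed-table fixtures

The published count tables ship as plain-text fixtures
(`cow_printed_table("T1")` … `"S34"`). Each statistic is computed from its own
source table, as in the original analysis; the suite does not force a single
master cohort to satisfy every table simultaneously, because the published
tables are not perfectly mutually consistent (see `discrepancies.tsv`). One
genuine ambiguity was resolved during packaging: the cross-tabulation's V2 row
prints five values with unclear column alignment, and allocating them to
columns d, e, f, g, j is the unique choice under which every column sum equals
the separately printed posterior census — so that allocation is shipped as
documented data.

`reconstruct_from_crosstab()` expands a count table into a deterministic
ordered cohort of categorical profiles (row-major, stable ids) with
representative per-side fields, placing single-sided variation on the right;
cross-tabulating the result returns the input table exactly. Side-level tables
(the A1-by-side table and the normal-versus-variation-lateral table) are
therefore *not* expected to reproduce from this reconstruction — they come
from their own fixtures.

## The synthetic generator

`sample_cohort(cohort_spec(...))` emulates a survey cohort at measurement
level. Anterior and posterior labels are drawn independently from prevalence
vectors whose defaults are the published cohort's margins (n = 2246); the
per-class diameter models are uniform draws from sub-intervals chosen strictly
inside each class's decision region — for example, a mild-variation side is
the contralateral diameter (2.0–2.4 mm) minus a uniform offset in
[0.5, 1.0] mm, which can never cross the half-contralateral hypoplasia
boundary. These interval choices are generator defaults made once to guarantee
the label-recovery invariant (every sampled record classifies back to its
drawn labels, checked over all 66 label pairs and a hundred-plus seeds); they
are not claims about real diameter distributions. A single integer seed drives
one random stream, and the generator restores the caller's RNG state.

What the generator deliberately does **not** emulate: radiologist measurement
noise, within-subject correlation between anterior and posterior morphology,
the joint distribution of ACoA shape with anterior type (shape is sampled as
`single_tubular` whenever patent), and image formation. Passing round-trip
tests therefore demonstrates that the classifier partitions its input space
correctly — not that it is robust to real-world measurement error near the
decision boundaries, where a 0.05 mm perturbation can legitimately change the
class.

## Sizes and numerical choices

The test suite runs at desk scale by design: the deterministic reconstruction
is the full 2246-subject cohort (it costs milliseconds), the round-trip
property uses cohorts of 25–50 records per label pair across 132 seeds, and
the statistical oracle comparisons use 10–25 random tables per property.
Agreement with reference implementations is asserted at 10⁻¹² (the
computations are closed-form); published values are asserted at their printed
precision (three decimals for statistics, two for percentages). Degenerate
inputs have defined behaviour: zero-variance rank data yields Z = 0, empty
margins and degenerate scores raise errors naming the offending category.

## Limitations

* The typing rules encode one survey's criteria; other COW classification
  schemes (e.g. the 0.8 mm completeness threshold used in earlier MRA work)
  are out of scope.
* ACA-A2 variants (combined stem, third A2) and the persistent trigeminal
  artery are carried as pass-through annotations only.
* The bilateral-variation rule for the side-pairing table (milder side acts
  as the "normal lateral", ties broken to the left) is needed only for
  synthetic cohorts; the published cohort has exactly one variation side per
  affected subject.
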