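---
title: "Kano-model needs assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano-model needs assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanoneeds)
```

## The model

A Kano questionnaire asks each need twice: a *positive* (functional) question
— how would you feel if this need were met — and a *negative* (dysfunctional)
question — how would you feel if it were not. Both use the same five-point
scale: Like (1), Should be (2), Does not matter (3), Can accept (4),
Dislike (5). The answer pair is looked up in a fixed 5 × 5 matrix
(`kano_matrix()`) that assigns one of six attributes:

* **M** (must-be): satisfaction barely rises when the need is met, but falls
  sharply when it is not;
* **O** (one-dimensional): satisfaction moves proportionally in both
  directions;
* **A** (attractive): absence does not dissatisfy, presence delights;
* **I** (indifferent): little effect either way;
* **R** (reverse): fulfilment dissatisfies;
* **Q** (questionable): a contradictory pair, e.g. Like/Like.

The matrix layout is fixed (rows = positive answer, columns = negative
answer): the Like row is Q A A A O, the middle three rows are R I I I M, and
the Dislike row is R R R R Q, giving the cell multiset
{A: 3, O: 1, M: 3, I: 9, R: 7, Q: 2}. `validate_kano_matrix()` asserts this
multiset at construction, so a transposed or corrupted matrix cannot enter
the pipeline silently.

For each need, attribute counts over the valid respondents yield the Berger
better/worse coefficients:

$$SI = \frac{A + O}{A + O + M + I}, \qquad
  DSI = -\,\frac{O + M}{A + O + M + I},$$

where R and Q answers are excluded from the denominator (they carry no
directional satisfaction information) but are retained in every frequency
output. Satisfaction sensitivity is the Euclidean distance of the need's
$(SI, |DSI|)$ point from the origin, $S = \sqrt{SI^2 + DSI^2} \in
[0, \sqrt 2]$: a need with large $S$ moves satisfaction strongly in at least
one direction.

Needs are then classified by quadrant relative to the *centroid* — the
arithmetic means of $SI$ and $|DSI|$ over the needs: high/high is O,
high SI/low |DSI| is A, low/low is I, low SI/high |DSI| is M. Priorities
follow the attribute hierarchy M > O > A > I, and within an attribute,
descending $S$. Two ranking columns are emitted: the global sensitivity rank
(descending $S$ over all needs, regardless of attribute) and the
within-attribute priority rank; they answer different questions and both
appear in the standard reporting table.

## Numerical and tie-break conventions

* All coefficients are computed at full precision; display rounding is
  half-up (0.8095 → 0.810) to 3 decimal places for coefficients and 2 for
  percentages, matching the field's table conventions. `run_pipeline()`
  writes both display-rounded and full-precision variants of every table.
* Points exactly on a centroid line count as "high" on that axis (`>=`).
  This is deterministic and documented; no need in the bundled reference
  profile lies on a boundary.
* Equal-$S$ ties in either ranking resolve in catalog order; none occur in
  the reference data, so the rule is a convention, not a fitted choice.
* `modal_attribute()` (used for per-subgroup labels, where a single-need
  centroid is undefined) breaks count ties by the fixed order
  M > O > A > I > R > Q, i.e. toward the more conservative (baseline)
  attribute.
* `percentages_to_counts()` reconstructs integer counts from printed
  percentages by nearest-integer (half-up) rounding and *fails* unless the
  counts sum exactly to `n` — a reconstruction that needs residual
  redistribution would signal inconsistent inputs, and we prefer an error to
  a silent repair.

## The bundled reference profile, and one inconsistency

`ccec_need_catalog()` and `ccec_frequencies()` ship the reference needs
assessment of grassroots CDC collaborative development in the
Chengdu–Chongqing Economic Circle: 13 needs under 4 primary needs, with
per-need attribute percentages and published coefficients for its 110 valid
questionnaires. Reconstructing counts from the percentages
(`ccec_counts()`) and running `kano_analysis()` reproduces the published
coefficients, sensitivities, centroid, quadrant memberships (4 M / 3 O /
3 A / 3 I) and both ranking columns — with one exception worth recording:
the published Q10 coefficient pair (0.298, −0.362) cannot be derived from
the published Q10 percentage row at n = 110, which reconstructs to counts
(A = 8, I = 58, M = 14, O = 23, Q = 4, R = 3) and hence
(31/103, −37/103) = (0.301, −0.359). No integer count vector consistent with
the printed Q + R share yields the published pair, so we treat it as a
transcription artefact in the source table. Q10's sensitivity (0.469), rank
(12) and quadrant (I) are identical under either pair, so nothing
downstream changes.

A related detail: the reference table's "average" coefficient row
(0.482, −0.586) equals the mean of its *rounded, printed* coefficients.
The mean of the full-precision reconstructed coefficients is
(0.4827, −0.5854) — the difference again traces to Q10 — and every quadrant
membership is identical under both centroids.

## Questionnaire screening

The validity principle behind the reference study's 110/117 retention is
stated, but not its operational rule. `screening_config()` makes the rule
explicit and configurable; the defaults are:

1. `MISSING_ITEM`: any unanswered paired item excludes the respondent;
2. `STRAIGHT_LINE_IDENTICAL`: identical positive and negative answers on
   *all* needs excludes (such a questionnaire is contradictory throughout);
3. `EXCESS_QUESTIONABLE`: more than `q_max = 0.5` of items classifying to Q
   excludes. A single Q item must not exclude — valid samples retain
   per-item Q rates of a few percent — so the threshold operates on the
   respondent-level Q fraction, exposed for sensitivity analysis.

Exclusions carry reason codes, and `screen_respondents()` returns an exact
partition of its input, so the effective rate is always `|valid|/|input|`.

## Subgroup comparison and psychometrics

Per-subgroup labels use the modal attribute; per-subgroup SI/DSI use the
same formulas on the subgroup counts. Between-group differences use the
Pearson chi-square test (via `stats::chisq.test`, continuity correction off
by default) on a group × attribute table. Because the R/Q columns are often
too sparse, the category scheme is configurable: all six attributes
(`"full"`), the four analyzable attributes (`"drop_rq"`), or a 2 × 2
target-vs-rest collapse. Published subgroup chi-squares in this field rarely
state their scheme or degrees of freedom, so we expose the choice rather
than hard-code a guess; any category with zero total raises an error
instructing collapse rather than producing a NaN statistic.

Instrument adequacy uses three standard statistics on the respondent × item
score matrix (`item_scores()`; positive-question codes by default, with
negative or concatenated scoring selectable, since reliability reports in
this field rarely state which side fed the analysis):
Cronbach's $\alpha = \frac{k}{k-1}\left(1 - \sum_i s_i^2 / s_T^2\right)$;
the KMO measure $\sum r^2 / (\sum r^2 + \sum q^2)$ with anti-image partial
correlations $q$ from the inverse correlation matrix; and Bartlett's
sphericity $\chi^2 = -\left(n - 1 - \frac{2k+5}{6}\right)\ln\det R$ on
$k(k-1)/2$ degrees of freedom. Degenerate inputs (zero total variance,
singular or identity correlation) raise errors naming the remedy instead of
returning boundary values.

## Delphi statistics

Kendall's coefficient of concordance is computed with mid-rank ties:
$W = 12S \,/\, (m^2(n^3-n) - m\sum_j T_j)$ with $T_j = \sum (t^3 - t)$ over
the tie groups of expert $j$. A panel in which every expert is fully tied
carries no ranking information and returns $W = 0$. Significance uses the
large-sample approximation $\chi^2 = m(n-1)W$ on $n-1$ degrees of freedom,
with a warning for $n \le 7$ indicators where the approximation is poor.
In tests, the tie-corrected Friedman statistic (`stats::friedman.test`)
serves as an independent cross-check, since $\chi^2_F = m(n-1)W$.

The expert authority coefficient uses the standard decomposition
$C_r = (C_a + C_s)/2$ — judgement basis and familiarity supplied as data per
expert, never imputed from a hard-coded sub-scale — with the conventional
0.70 threshold for high panel authority. Indicator revisions between rounds
(merge/delete/add) are expert decisions; `round_ledger()` only book-keeps
them and derives the after-set mechanically.

## What the synthetic generator emulates — and what it does not

`generate_study()` draws, per respondent and need, a latent attribute from
that need's categorical profile, then realises it as an answer pair drawn
uniformly from the matrix cells carrying that attribute (`attribute_to_pair()`;
the cell sampler is pluggable for future empirical cell weights, but no
within-cell response model is identifiable from aggregate frequency tables).
Classification is therefore exact by construction: the round-trip
classify(inverse-sample(x)) = x holds for every attribute and seed, and the
returned latent tallies equal the tabulated counts whenever no records are
overwritten. Defaults reproduce the reference study conditions: 110
respondents, per-need profiles equal to the reference percentage rows,
demographic marginals equal to the reference strata, and an
`invalid_fraction` of straight-line records (identical answers at level 3,
"Does not matter") injectable for screening tests — `invalid_fraction =
7/117` at `n = 117` reproduces the 94.02% effective rate.

Deliberate simplifications: demographics are sampled independently across
fields (only marginals are available as ground truth), and respondents are
independent across needs — no respondent-level correlation structure links a
person's answers on different needs, because nothing in aggregate frequency
tables identifies one. Passing tests on synthetic data therefore validate
the *computational chain* (classification, screening, coefficients, ranking,
subgroup and Delphi statistics), not distributional claims about real
questionnaire behaviour such as acquiescence bias, demographic–attitude
correlations, or item-order effects.

## Problem sizes and test design

The test suite runs the full pipeline at the reference scale (n = 110–117
respondents, 13 needs), cell-uniformity checks at 9 000 draws, the
Monte-Carlo envelope for the generator at 30 replicates of n = 110, the
round-trip identity over 1 000 seeds, and dominant-attribute recovery (mass
0.6, adversarial runner-up under the modal tie order) over 200 replicates of
n = 200 — sizes at which binomial sampling error is well below the asserted
envelopes while the whole suite stays interactive (~10 s).

## Limitations

The package implements one specific, widely used Kano evaluation procedure;
analytical-Kano, fuzzy-Kano and importance-grid variants are out of scope.
Chi-square subgroup results depend on the chosen category scheme, which is a
genuine analyst degree of freedom — report the scheme alongside any p-value.
The quadrant classification depends on the need set through the centroid:
adding or removing needs can relabel others, so labels are meaningful only
relative to a stated catalog.
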