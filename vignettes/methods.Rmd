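---
title: "Models and design choices in trialpub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in trialpub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialpub)
```

## The problem

Results presented in conference abstracts of randomized controlled trials
influence clinical and systematic-review decisions, yet abstracts are
lightly reviewed and often preliminary. Two related questions arise for a
cohort of abstracts followed over time: whether the abstract's main-outcome
result agrees with the paired full publication, and whether characteristics
of the abstract — author conflicts of interest (COI), funding, reported
statistical significance — predict whether and when full publication
occurs. `trialpub` implements this analysis pipeline end to end over
structured cohort records.

## Main-outcome selection

Each document's "main outcome" is chosen by a fixed hierarchy: (1) a single
designated primary outcome; (2) if several are designated, the one reported
earliest in Results; (3) otherwise an outcome mentioned in the title or
objective; (4) otherwise the first outcome in Results. Order of first
appearance in Results (`results_order`) is the tie-breaker throughout, so
selection is invariant to how the outcome list happens to be stored. Two
choices the rule table leaves open are fixed here: when several outcomes
are title/objective-mentioned, rule 3 takes the earliest-reported among
them (consistent with the spirit of rules 2 and 4); and identical
`results_order` values are an error rather than a silent tie-break, since
the hierarchy has no defined answer there.

## Significance classification

A result is *significant* when at least one reported between-arm comparison
indicates significance at level $\alpha$ (default 0.05): a p-value below
$\alpha$ (strict — $p = 0.05$ does not qualify, the level being stated
without a boundary convention), a 95% CI excluding the null value of its
measure (1 for ratio measures, 0 for difference measures; closed endpoints,
so an endpoint exactly at the null does not qualify), or an explicit
statement that an arm was significantly favored accompanying reported data.
A result is *not significant* only when every reported comparison is
interpretable and non-significant; anything less — including the authors
claiming significance while reporting no estimate, CI, or p-value — is
*not reported*. Document-level ("any outcome") aggregation uses the
dominance order significant > not significant > not reported, mirroring the
at-least-one-comparison logic. One-sided tests are not distinguished: all
reported p-values are treated identically.

## Discordance scoring

Pairs are comparable when the main-outcome domain matches (labels are
lower-cased, punctuation-stripped, whitespace-collapsed, then passed
through an optional synonym map — a configurable stand-in for human
adjudication of outcome-domain equivalence, which is not mechanically
reproducible), the time point matches exactly after conversion to days (no
tolerance window), and both documents report results.

Qualitative discordance is a flip in effect direction (side of 1 for ratio
measures, sign for differences; per-arm summary pairs are first reduced to
a difference), in 5%-level significance status (assessed on the main
outcome's overall classification in both documents), or in which arm is
significantly favored. Otherwise the signed percent difference
$(\mathrm{abstract} - \mathrm{publication})/\mathrm{publication} \times
100$ is banded on its absolute value: $<10$, $[10, 20]$ (closed on both
edges — the source bands are printed without boundary conventions; the
choice is configurable), $>20$. *Exact agreement* means equality at the
coarser of the two reported precisions, because the underlying comparison
is between printed values: 1.5 versus 1.47 agrees, 1.50 versus 1.47 does
not. When only p-values are comparable, a p-value difference without a
significance flip is "quantitative — amount unclear"; identical p-values
are scored exact agreement with a percent difference of 0 (a choice the
definitions leave open). Estimates on incommensurable measures (a ratio
against a difference) are also "amount unclear": no conversion beyond
identical-measure re-scaling is attempted.

## Risk-ratio estimation

Crude RRs come from 2×2 exposure-by-publication tables,
$\mathrm{RR} = (a/n_1)/(c/n_0)$, with the Katz log-scale standard error
$\sqrt{1/a - 1/n_1 + 1/c - 1/n_0}$ and Wald intervals. Zero numerator
cells are reported as inestimable rather than continuity-corrected. The
default comparator is the complement of the exposed set within the
analyzable cohort; an explicit-reference mode covers exposures with named
referents. Records for which an exposure is undefined (per-author COI
before individual disclosure existed, i.e. the 2001 cohort year) are
excluded from that table, not coded unexposed.

Model-based RRs use a binomial likelihood with log link, fitted by Fisher
scoring with step-halving (tolerance $10^{-8}$ on the maximum coefficient
change, 100 iterations). The log link can push fitted probabilities to 1;
non-convergence or a boundary fit is an explicit error with diagnostics,
never a silent fallback to another link. With a single binary covariate
the MLE equals the closed-form crude RR, which the tests exploit in both
directions (closed form vs IRLS vs a brute-force likelihood grid).

The interaction model adds main effects and products of the exposure with
(1) whether main-outcome significance was reported and (2) whether it was
significant. Exponentiated coefficient sums give the exposure RR within
each of the three significance strata, with delta-method intervals. The
overall interaction is tested by a joint Wald chi-square on the two
interaction coefficients (2 df). The source analysis labels this an
F test; exact F machinery is not defined for log-binomial models, so the
asymptotically equivalent Wald form is used and the deviation is recorded.

## Time to publication

Events occur at `months_after_presentation` (publication at or before
presentation is coded month 1); unpublished abstracts are censored at
their cohort-year follow-up horizon (defaults 146/134/122/110 months for
cohort years 2001–2004, configurable). The product-limit estimator uses
the standard tie convention (events before censorings at the same month).
The log-rank test is the usual observed-minus-expected quadratic form over
shared risk sets with hypergeometric covariance, $\chi^2$ on groups − 1
df. The descriptive median/IQR/range of time to publication is computed
over published abstracts only — the natural reading of a published-cohort
summary — with linear interpolation between order statistics (R quantile
type 7), fixed for reproducibility.

## Assumption-based sensitivity analysis

Among the $m$ abstracts whose main-outcome significance is not reported, a
fraction $f \in \{0, 0.25, 0.5, 0.75, 1\}$ is relabeled significant —
exactly $\mathrm{round}(f \cdot m)$ of them (half away from zero; the
source is silent on rounding), drawn uniformly without replacement under a
seed — and the rest not significant; the significant-vs-not RR of
publication is then re-estimated. Fractions 0 and 1 are deterministic.
Intermediate fractions depend on an unrecoverable original seed, so the
package reports their across-seed distribution (mean, percentiles, range)
rather than pretending a single draw is canonical; draws are independent
per assumption. On the margins fixture the across-seed *mean* RR is
monotone non-increasing in $f$ and bracketed by the endpoints; individual
draws can exceed the $f = 0$ endpoint — the same sampling noise that makes
any single published draw an imperfect anchor.

## The synthetic generator, and what a green test establishes

`generate_cohort()` draws exposures independently at the stated marginal
prevalences (first-author COI 33% where individually disclosed,
significance reported 44.4%, significant-given-reported 51.3%, funding
margins, selection-rule mix 9.6/62.0/28.5%), publication from a log-linear
risk model whose default coefficients are the published RRs (1.44
significance reporting, 1.31 first-author COI, 0.76 no funding) with the
intercept solved in closed form so the implied mean publication proportion
is 0.448, publication times from a log-normal targeted at median 18 months
(IQR 11–33, the spread parameter solved from the quartile ratio) truncated
to [1, 90], and, for comparable published pairs, a discordance category
from the published 86-pair mixture realized by construction. Parameter
sets implying publication probabilities above 1 are rejected at
construction.

The generator is a closed loop with the pipeline: every drawn label is
recoverable by the corresponding classifier, and the pair fixture verifies
itself against `classify_pair()` before returning. What a green test
therefore establishes is internal consistency — estimators recover the
parameters of the stated world, at the stated sample sizes, with the
stated error rates. It does not establish anything about features of real
cohorts the generator deliberately omits: correlation between exposures
(the joint distribution is unpublished, so independence is assumed),
within-author correlation across abstracts, free-text outcome labels, or
informative censoring. The deterministic `margins_fixture()` reproduces
all published 2×2 margins simultaneously; joint counts the margins do not
constrain are completed by a fixed interleaving, so stratified quantities
computed from it are *a* consistent completion, not the original data.

## Known limitations

- The printed RR 0.97 for significant-vs-not among reporting abstracts is
  not reproducible from the printed counts (which give ≈ 1.03) and is
  excluded from acceptance checking.
- The assumption-1 RR on the printed margins is 1.3049 (its CI reproduces
  the printed 1.07–1.60 exactly), which prints as 1.30 against the
  published 1.31 — treated as a rounding artifact of the same computation.
- Outcome-domain matching is mechanical; the synonym map substitutes for
  human adjudication and is declared as such.
- No confounder-adjusted multivariable models and no competing-risks or
  parametric survival machinery: the analysis mirrors its source design.
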