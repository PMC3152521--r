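---
title: "Methods: decision-tree cost-utility modelling of insomnia treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-utility modelling of insomnia treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insomod)
```

## The model

`insomod` implements a prevalence-based, one-year economic evaluation of
insomnia treatment in New Zealand, combining cost-effectiveness and
cost-utility analysis from a societal perspective. Its core is a decision
tree describing where a person with insomnia first seeks care — pharmacist,
general practitioner (GP), health practitioner, psychologist or alternative
health practitioner — and what happens next: no further action, a course of
treatment, or one level of on-referral. Each node of the tree is an *event*
with a resource footprint (consultations, medicine courses, round trips),
and each branch carries a probability.

The calculus is standard decision-tree rollback:

* cost of an event: $c_e = \sum_r v_{er}\,u_r$, the volumes of each
  resource used by the event times the unit cost of the resource;
* probability of a pathway: the product of the branch probabilities along
  it, $\pi_k = \prod_{j \in k} p_j$;
* cost of a pathway: the sum of the event costs along it,
  $C_k = \sum_{e \in k} c_e$;
* expected tree cost: $\mathbb{E}[C] = \sum_k \pi_k C_k$.

The tree "cost" is deliberately the probability-*weighted* sum, i.e. the
expected (average) cost per person entering the tree, not the plain sum of
pathway costs: only the expectation is consistent with an average
per-patient treatment cost, and it is what the recursive rollback
$E(\text{node}) = c_{\text{node}} + \sum_{ch} p_{ch}E(ch)$ computes. The
test suite checks the pathway formulation against that independent
recursion on batches of random trees.

Benefits enter on two scales. Successful treatment removes the excess
health-resource use of insomniacs: with national per-capita spend $TP$,
prevalence $I_p$ and an insomniac to non-insomniac cost ratio $R$, the
mixture identity $TP = I_p X + (1-I_p)Y$, $X = RY$ gives the non-insomniac
mean $Y = TP/(1 + I_p(R-1))$ and the per-capita avoidable cost
$\Delta = X - Y$. With the packaged inputs ($15{,}313\,\$M$, $4.292\,M$
people, $I_p = 0.13$, $R = 1.18$) this yields $Y \approx 3486$,
$X \approx 4114$ and $\Delta \approx 627.52$. Second, successful treatment
yields a utility gain; with a one-year horizon and no discounting the
utility difference *is* the QALY gain, so net benefit per QALY is
$(\Delta - \mathbb{E}[C])/g$ where $g$ is the utility gain.

Population scaling multiplies per-person values by the number treated,
`at_risk * prevalence * p_seek` (2.317 M people aged 20–59, 13%
prevalence, 15% of sufferers seeking care ≈ 0.045 M).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| unit costs | packaged table | NZD 2009, GST-excl. | national fee estimates per resource |
| utilisation volumes | packaged matrix | consultations/courses/trips | micro-costing footprint per event |
| cost excess `R - 1` | 0.18 (range 0.05–0.25) | ratio | literature range for insomniac cost excess after dropping outliers |
| utility gain | (0, 0.157, 0.373) | utility | pooled utility-difference dataset: mean is base, max is high, 0 is a conservative floor |
| prevalence | 0.13 | proportion | national symptom-based estimate |
| `p_seek` | 0.15 | proportion | survey-based share of sufferers seeking treatment |
| `fraction` | 0.25 | relative | default symmetric half-width of triangular PSA ranges |

The published transport unit cost ($16.71) differs in the last cent from
its stated derivation ($0.56/\text{km} \times 29.83\,\text{km} = 16.7048$);
`transport_unit_cost()` recomputes the product, but the packaged table
carries the printed 16.71, which is the input the downstream pathway totals
are consistent with.

## What is synthetic, and why

Every quantitative input above is published *except* the downstream branch
probabilities of the tree: the published model reports the first-contact
proportions (pharmacist 16.5%, GP 41.2%, psychologist 7.1%, nurse +
counsellor grouped as health practitioner 14.1%, herbalist + acupuncturist +
hypnotist grouped as alternative practitioner 21.1%; psychiatrists have no
entry branch and are dropped before renormalising — conveniently the five
retained categories total exactly 100) but not the treat/refer splits below
them. The package therefore separates *topology* (packaged YAML, node ids
matching the utilisation-table rows) from a *probability completion*:

* `default_completion()` — documented placeholder round numbers (80% chance
  of treatment at an entry provider, 40% on-referral after treatment, 30%
  pharmacist referral, uniform referral splits). These make the model run;
  they estimate nothing.
* `random_completion(seed)` — uniform simplex draws for property tests.
* `calibrate_completion()` — reverse-engineers treat/refer probabilities so
  that each entry branch's mean cost matches the published per-branch means
  ($36/$98/$213/$134/$280). Within a branch the mean is affine in the
  treat and refer probabilities, so the match is a closed-form solve (treat
  probability 0.5 tried first, refer solved; if infeasible, refer fixed at
  0.25 and treat solved — only the alternative-practitioner branch needs
  the fallback). The first-contact-weighted average of those means,
  $\sum_b f_b m_b \approx 144.94$, then reproduces the published $145
  average treatment cost *by construction*, which is exactly why the
  calibration is labelled `synthetic_calibrated` and reported as a
  consistency reconstruction, never as an estimate.

Every completion carries per-node provenance
(`paper_first_contact` / `synthetic` / `synthetic_calibrated`) that
propagates into trees, runs and written reports.

Because the first-contact split describes people who *do* seek treatment,
the default tree is the seek-treatment tree (`seek_split = "external"`):
its expected cost is the cost per person treated, and the 15% care-seeking
proportion enters through population scaling, mirroring the published
economic-evaluation table. `seek_split = "in_tree"` instead adds a root
chance node routing 85% to a zero-cost "do not seek treatment" end node,
for users who want the whole at-risk population inside the tree; the
downstream consequences of not seeking care (foregone offsets) are a
population-scaling matter either way.

## Probabilistic sensitivity analysis

The stochastic model samples every uncertain input from a triangular
distribution by inverse CDF, with one seeded `runif` stream and a fixed
parameter order (unit costs in table order, volumes row-major, branch
probabilities depth-first, then cost excess, utility gain, prevalence,
care-seeking), so a seed fixes the entire simulation bit for bit.
Defaults follow the published design: 10,000 iterations; symmetric ±25%
ranges unless a better range is stated; the cost excess uses its
literature triangular (5%, 18%, 25%) and the utility gain its
(0, 0.157, 0.373) specification. All inputs are sampled independently —
the source is silent on correlation structure.

Sampled sibling branch probabilities are renormalised per iteration to sum
to 1 (the source varies "all estimates subject to uncertainty" without
saying how probability coherence is maintained; renormalisation is the
least-informative repair). Iterations that would still produce an invalid
probability are counted and flagged, never dropped. Summaries use
linear-interpolation quantiles (`stats::quantile` type 7) — a convention
that had to be fixed for reproducibility.

Numerical care: completions pin each assignment's floating-point sum to
exactly 1 through the last sibling, and the vectorised simulation engine
accumulates pathway sums and products in the same order as the
deterministic enumerator, so the zero-variance PSA (`fraction = 0`)
reproduces the deterministic base case *bitwise* — the test suite asserts
this with `identical()`.

## What the tests do and do not show

The deterministic surface is fully pinned to published figures: the four
worked pathway costs ($33, $434, $502, $562), the health-cost split
(3,568 / 3,486 / 4,114 / 628) and the national scaling (0.045 M, $6.6 M,
$28.4 M, $21.8 M) are all recomputed exactly. Two published values are
*not* recoverable from printed inputs and are documented rather than
matched: net benefit per person recomputes to $627.52 - 145 = 482.52$
(prints as 483, not the published 482, which used unrounded internals) and
net benefit per QALY to $3{,}073$ (published $3{,}072$).

The stochastic surface cannot be pinned: the published 90% intervals
($41–$679 per person, $2 M–$33 M nationally, $240–$8,102 per QALY) depend
on the unpublished branch probabilities and on an unstated choice of which
inputs were varied. The package's reconstruction (calibrated completion,
defaults above, seed 1) gives intervals of the same order and the same
strong right skew in the per-QALY output — driven, as in the source, by
the utility gain's low tail near 0 — but the exact endpoints differ.
Property-based acceptance stands in for figure replication: oracle
equivalence on random trees, probability conservation, sampler
unbiasedness at $10^5$ draws against the analytic mean
$(\text{low}+\text{mode}+\text{high})/3$, bitwise zero-variance collapse,
PSA mean matching the base case under symmetric unit-cost-only variation
(linearity of expectation), and the cost-split round trip to $10^{-10}$.

Passing these tests shows the *machinery* is right. It does not validate
the placeholder probabilities against New Zealand care-seeking behaviour,
nor the independence assumption between sampled inputs, nor anything about
comorbidity-attributable costs, productivity losses or accident
externalities, all of which are out of scope by design.

## Problem sizes and degenerate inputs

The suite runs random-tree batches at depth ≤ 5 and branching ≤ 4 (100
trees for the acceptance properties), $10^5$ sampler draws, and PSA runs of
2,000–4,000 iterations; the acceptance script uses the full 10,000. The
whole suite completes in a few seconds on one core.

Degenerate inputs are defined, not accidental: a single-end-node tree is
valid with expected cost equal to its event cost; zero-probability
zero-cost branches change nothing; an all-zero utilisation row is a valid
zero-cost event; a zero QALY gain makes cost per QALY `NA` with a warning
(never `Inf`); a zero base in `make_default_range()` degenerates to a
fixed parameter with a warning; `R = 1` or `Ip = 0` collapse the cost
split in the obvious ways. Validation tolerances default to `1e-9` for
trees built in code and `1e-6` for hand-entered configurations.

## A worked run

```{r worked}
run <- run_deterministic(run_config(completion = "calibrated"))
run$branch_means
round_half_up(run$tree_cost)
run$evaluation
```

```{r psa}
pr <- run_psa(run_config(completion = "calibrated", n_iterations = 2000,
                         seed = 1))
pr$summary
```

## Known limitations

* The downstream branch probabilities are stand-ins; any conclusion
  sensitive to them should be re-run with user-supplied completions.
* One level of on-referral only, one-year horizon, no discounting, no
  comorbidity attribution, no indirect costs — inherited scope limits.
* Calibration matches branch means exactly but is not unique: the uniform
  referral split and the tried-first treat probability are conventions.
* Triangular distributions and input independence are modelling choices
  made for data-poor settings, not empirical findings.
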