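---
title: "Scaled preference rankings from binary choice tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaled preference rankings from binary choice tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary preference tests — a mouse choosing between two liquids, a macaque
between two bottles, a person between two pictures — tell us which of two
options is preferred, but not by how much, and not how a whole set of
options relates. prefrank combines all pairwise tests of a set of options
into a *scaled* ranking: each option receives a worth value, the options'
worths sum to 1, and the distance between worths expresses preference
strength, not just order.

```{r}
library(prefrank)
d <- generate_choices(worth = c(juice = 5, milk = 3, water = 2, nacl = 1),
                      n_subjects = 12, style = "consumption", seed = 1)
oc <- d |> aggregate_sessions() |> apply_threshold(0.5)
fit <- fit_worth(oc)
tidy(fit)
```

## The model

Worth values come from the Bradley–Terry paired-comparison model: option
$i$ with positive ability $w_i$ beats option $j$ with probability

$$\Pr(i \succ j) = \frac{w_i}{w_i + w_j}.$$

The reported worth is the normalized ability $w_i / \sum_k w_k$, so a
worth value is a probability-scale position and all worths sum to one. The
same maximum is classically reached through a log-linear (Poisson) count
model; prefrank maximizes the Bradley–Terry likelihood directly, which
gives the identical MLE with less machinery. Log-abilities (`lambda`) are
identified by a sum-to-zero constraint so that no option plays the role of
an arbitrary reference.

### From quantities to outcomes

Raw records are quantities per side (milliliters, lick visits, or 1/0 for
a forced pick), one row per subject × pair × session. Two design choices
matter here:

* **Session aggregation.** Side-switched repeats exist only to cancel side
  bias; the two halves describe one comparison, so `aggregate_sessions()`
  sums quantities per subject and unordered pair before thresholding.
  Pairs are stored in a canonical orientation (lexicographic order of the
  labels, compared in the C locale so results do not depend on the
  session's locale).
* **The preference threshold.** With threshold $\theta \in [0.5, 1)$ and
  share $r = q_a / (q_a + q_b)$, the first option wins when $r > \theta$,
  the second when $r < 1 - \theta$, and everything in the *closed* window
  $[1-\theta, \theta]$ is a tie. Closed bounds make the familiar 50% rule
  ("a tie only at exactly 50:50") the $\theta = 0.5$ special case of the
  same rule, and a 65% threshold declares every split between 35:65 and
  65:35 a tie. Pairs where nothing was consumed carry no direction and are
  recorded as ties, with a warning — raw data cannot decide this case, so
  the package takes the least committal reading.

### Ties in the fit

Higher thresholds create ties, and the likelihood has to do something with
them. Three treatments are available:

* `half_win` (default): a tie contributes half a win to each side. Robust
  with the small subject counts typical of animal work, and the default
  because it neither discards information nor adds a parameter.
* `davidson`: an explicit tie parameter $\nu$, with
  $\Pr(\text{tie between } i, j) \propto \nu \sqrt{w_i w_j}$. This mirrors
  designs that carry an undecided response category.
* `drop`: ties are discarded.

With few subjects it is common for an option to win or lose *every*
decided comparison; the MLE then diverges. When this separation is
detected, a damping pseudo-count of 0.5 is added to every ordered pair
cell (and reported in the fit object); otherwise damping is 0. The
pseudo-count can always be set explicitly.

### Numerical details

The fitter runs a minorization–maximization iteration (monotone in the
likelihood) with convergence declared when the worth vector moves less
than `tol` (default `1e-10`). Near-boundary likelihoods make plain MM
slow; if the iteration cap is reached, the MM iterate is polished with
BFGS steps on the same objective and convergence is accepted when the
gradient norm is below `1e-6` times the total comparison count. The
`log_likelihood()` function exposes the exact objective, so optimality can
be (and in the test suite, is) verified against grid search and random
perturbations. A comparison graph that is disconnected at zero damping is
reported as an error naming the components rather than silently producing
arbitrary relative scales.

## Quality of a ranking

Two statistics summarize how trustworthy a pooled ranking is.

**Intransitivity ratio (I-ratio).** Each subject's thresholded outcomes
form a tournament. Among the 8 orientations of any option triple exactly
2 are directed cycles (A beats B beats C beats A, or the reverse), and
every larger intransitive circle contains at least one cyclic triple, so
counting cyclic triples suffices. The I-ratio is the percentage of cyclic
triples pooled over subjects; 0 means every subject is perfectly
transitive. The denominator is the full $\binom{n}{3}$ per subject —
including triples that contain ties or missing relations — so the ratio
stays comparable across thresholds that generate different numbers of
ties.

**Consensus error (CE).** For each pair, let $n_a$ and $n_b$ count the
subjects preferring each side; tied subjects express no direction and are
excluded (a `tie_split` option shares them half-and-half for sensitivity
checks). The pair's disagreement is

$$d = 200 \cdot \frac{\min(n_a, n_b)}{n_a + n_b},$$

so unanimity scores 0 and an even split scores 100. Each option's CE is
the mean disagreement over its pairs, and the overall CE the mean over
options. The doubling (200 rather than 100) is forced by the anchors: a
CE of 100% must mean "every pair splits the raters in half". CE is
sensitive to the number of raters and options — with few raters each
individual moves the statistic substantially — so it should be read as a
descriptive measure, not a test statistic.

```{r}
quality_report(oc)
```

## Positioning a new option by simulation

Adding an option to an existing ranking of $n$ options would require
$n$ new comparison series; the simulation module asks how far one can get
with fewer. The target's observed comparisons (against `tested_against`)
are kept; every missing subject × pair cell involving the target is filled
with a fair coin flip between the two win directions, worth values are
refitted, and the target's rank and the quality measures are recorded.
This loop runs `runs` times (default 200).

Randomization is per subject and pair — the only granularity at which
per-subject tournaments, and hence the I-ratio of a completed dataset,
remain well defined. Ties are excluded from the randomization by default
(`randomize_ties` adds them as a third equally likely outcome).

Two modes:

* **Uninformed**: every completion is kept.
* **Informed**: completions whose I-ratio exceeds `intransitivity_cutoff`
  (default 0.1, i.e. at most 10% cyclic triples) are discarded; the count
  of discarded runs is reported, and retaining zero runs is an explicit
  error suggesting a larger cutoff.

When the full dataset is available, the target's true rank is computed
internally by fitting the complete data — never supplied as a constant —
and the frequency of runs hitting that rank is reported as the frequency
of true positives. Results tables list the best retained run under the
lexicographic order (lowest I-ratio, then lowest CE), the convention for
reporting the best-achieved simulation.

```{r}
sim <- simulate_positions(oc, target = "water",
                          tested_against = c("juice", "milk"),
                          runs = 100, seed = 7)
glance(sim)
simulation_table(sim)
```

### How many runs are enough?

`determine_cutoff()` grows the number of completions on a doubling
schedule (2, 4, 8, ..., `max_runs`) and, at each checkpoint, regresses
per-run worth on option identity, testing the target against every other
option with Holm-adjusted contrasts. It stops at the smallest run count
where all adjusted $p \le 0.05$ *and* the target's 95% CI (normal
approximation, mean $\pm z \, s/\sqrt{k}$) overlaps no other option's;
reaching `max_runs` without separation flags the position as ambiguous.

Two caveats are worth stating plainly. First, the stopping rule couples a
significance criterion with a CI-overlap criterion; phrasing that compares
"an interval to a significance threshold" is ambiguous, and this
conjunction is our reading of it — both conditions are conservative, and
either alone would stop earlier. Second, the pooled residual variance of
the regression understates the run-to-run spread of options whose worths
are negatively correlated across runs (two near-identical options trading
wins), so for exact twins the ambiguity flag is reliable but not
guaranteed at small `max_runs`. A checkpoint whose accumulated completions
are all identical has no run-to-run variance at all; such degenerate
checkpoints cannot attest separation and are passed over.

## The synthetic-data generator

Every statistical claim in the test suite is exercised on generated data
with known ground truth, emulating the two study designs the package
targets:

* `forced_choice`: each subject sees every pair `trials_per_pair` times
  and picks a side with Bradley–Terry probability; a picture-rating
  design. An optional `tie_rate` emits equal quantities (no direction).
* `consumption`: per subject-pair, non-negative counts whose expected
  ratio follows the same probability; overdispersion enters through a
  gamma-mixed Poisson (`noise` is the gamma mixing variance; 0 means plain
  Poisson). Ties then arise implicitly through the threshold window, the
  way real 65%-threshold ties do.

The generator does **not** model side bias, session-order effects,
satiation, or subject-level covariates. Passing tests therefore show that
the estimators recover Bradley–Terry structure from realistic sample
sizes and noise — not that real assays are free of those artifacts; side
bias in particular is assumed to be cancelled by the side-switched design
before the data reach the package.

The `scenario()` presets encode the valence-range contrast: 7 options and
25 forced-choice subjects (a realistic picture-rating cohort), with
ground-truth worths decaying geometrically by 0.45 per rank
(`wide_valence`, clearly separated options) or 0.9 (`narrow_valence`,
options nearly equivalent). The hypothesis they probe — narrow valence
ranges produce more inter-subject disagreement and more intransitivity —
is checked as a paired Monte-Carlo comparison over 100 seed pairs in the
test suite.

## Problem sizes used in the checks

The shipped checks use deliberately desk-scale sizes: parameter recovery
uses 500 forced-choice subjects over 4 options; the valence contrast 100
paired scenarios of 25 subjects × 21 pairs; the simulation checks 5
options × 11 subjects with 25–200 runs; oracle comparisons enumerate all
64 four-option tournaments and 1,000 random tournaments on 5–7 options.
The acceptance script (`scripts/acceptance.R`) re-runs the same pipeline
end to end from a supplied seed and writes its numbers as JSON.

## Known limitations

* The paired-comparison model carries no subject effects or covariates;
  heterogeneous subpopulations show up only indirectly, as a high
  consensus error.
* CE and I-ratio are descriptive; no sampling distribution is attached,
  deliberately.
* The informed simulation conditions on an I-ratio cutoff; if the true
  data-generating process is itself strongly intransitive, that
  conditioning biases the completion toward transitive worlds.
* Reproduction of published species datasets requires those datasets to
  be placed under `inst/extdata/deposited/`; they are not redistributed
  with the package.
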