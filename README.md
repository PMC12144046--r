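# prefrank

Scaled preference rankings from repeated binary choice tests.

Preference tests — a mouse choosing between two liquids in a home-cage
system, a macaque between two bottles, a person between two pictures —
reveal which of two options is preferred, but not by how much. prefrank
is for researchers (animal welfare science, behavioral biology,
psychophysics) who run *all pairwise* binary tests over a set of options
and want:

* a **scaled ranking**: per-option worth values under the Bradley–Terry
  paired-comparison model, where option *i* beats *j* with probability
  *w<sub>i</sub>* / (*w<sub>i</sub>* + *w<sub>j</sub>*) and the reported
  worths are the abilities normalized to sum to 1;
* **quality statistics** for that ranking: the *intransitivity ratio*
  (percentage of option triples forming a directed cycle within a
  subject's choices, pooled over subjects) and the *consensus error*
  (scaled inter-subject disagreement per pair,
  *d* = 200 · min(*n<sub>a</sub>*, *n<sub>b</sub>*) / (*n<sub>a</sub>* + *n<sub>b</sub>*),
  averaged per option and overall; 0% = unanimity, 100% = every pair
  split evenly);
* **simulated positioning** of a new option from incomplete comparisons:
  missing subject × pair cells are randomly completed, worths refitted,
  and the target's rank distribution summarized — either *uninformed*
  (keep all completions) or *informed* (discard completions whose
  intransitivity ratio exceeds a cutoff, default 0.1) — plus a
  statistically determined number of randomization runs needed for a
  stable position.

Quantities (consumed amounts, lick counts, or 1/0 forced picks) are
turned into win/loss/tie outcomes at a configurable preference threshold:
at 50% only an exact 50:50 split ties; at 65% every split between 35:65
and 65:35 ties.

## Worked example

```r
library(prefrank)

d <- generate_choices(worth = c(juice = 5, milk = 3, water = 2, nacl = 1),
                      n_subjects = 12, style = "consumption", noise = 0.6,
                      seed = 1)
oc  <- d |> aggregate_sessions() |> apply_threshold(0.65)
fit <- fit_worth(oc)
fit
#> Bradley-Terry worth fit (half_win, damping = 0)
#>   option               lambda    worth  pos
#>   juice                1.0146   0.5219    1
#>   milk                 0.3438   0.2669    2
#>   water               -0.2336   0.1498    3
#>   nacl                -1.1248   0.0614    4
#> log-likelihood: -38.94436
```

Twelve subjects' noisy consumption counts, thresholded at 65%, recover
the generating order (5:3:2:1). The worth values sum to 1; juice's 0.52
says it would be picked over a random alternative about half the time the
pair includes it, and the juice–milk gap (0.26) is far larger than the
water–nacl gap (0.09) — preference strength, not just order.

```r
quality_report(oc)
#> Ranking quality
#>   consensus error (CE): 33.33%
#>   intransitivity ratio (I-ratio): 4.17% (2 of 48 triples)
#>   per-option CE:
#>     juice               24.44%
#>     milk                38.52%
#>     water               48.15%
#>     nacl                22.22%
```

A third of the achievable disagreement is realized (subjects disagree
most about water's position), and 2 of the 48 subject-triples are cyclic.

```r
sim <- simulate_positions(oc, target = "water",
                          tested_against = c("juice", "milk"),
                          runs = 100, seed = 7)
sim
#> Position simulation for 'water' (uninformed, 100 runs, 100 retained)
#>   tested against: juice, milk
#>   true position: 3; frequency of true positives: 0.76
#>   best run: position 3 (I-ratio 0.04, CE 28.70%)
```

Having observed water only against juice and milk, random completion of
its missing comparisons places it at its true rank (3rd) in 76 of 100
runs; the best run (lowest I-ratio, then lowest CE) also lands there.
`determine_cutoff()` estimates how many runs are needed before the
target's 95% CI separates from every other option, `tidy()`/`glance()`
return tibbles for all result objects, and `autoplot()` draws the worth
scale or the simulated CIs.

A thin command-line wrapper ships at `inst/cli/prefrank.R` with
subcommands `rank`, `quality`, `simulate`, and `generate` (thresholds
given as percentages, outputs as JSON + TSV).

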