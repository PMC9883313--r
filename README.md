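# probassoc

Data-driven association thresholds for animal social network analysis from
sequential individual-identification data.

## The problem

Social structure in wild populations is usually inferred from
*associations* — circumstances in which two identified individuals could
have interacted. When the raw data are a stream of photo-identifications
(or any time-ordered identification records), the analyst must decide how
close together two identifications have to be before the individuals count
as associated. That cut-off is usually arbitrary, and it matters: a
too-broad criterion drowns real structure in chance co-occurrence, a
too-narrow one misses genuine companions.

`probassoc` replaces the arbitrary cut-off with one estimated from the data
stream itself. Individuals are identified within *photographable clusters*
— the set of animals within identification range of the observer at a
moment — which they enter (immigration) and leave (emigration) as the
animals and the photographer move. If the emigration rate from a cluster is
μ per ordinal time unit per individual, the probability that two
individuals identified T units apart overlapped in the same cluster is

    P(overlap) = (1 + μT) · e^(−μT)

At a lag equal to the mean residence time (T = 1/μ) this probability is
2/e ≈ 0.736 — about 75% — *for every* μ. The mean residence time is
therefore a natural, data-driven association threshold.

The residence time is estimated through the lagged identification rate
(LIR): the probability that an identification made τ units after another
names the same individual. Within collection events, the LIR decays with
lag; fitting the emigration + reimmigration model

    R(T) = (1/a) · (1/c + (1/b)·e^(−(1/b + 1/c)·T)) / (1/b + 1/c)

by maximum likelihood with binomial loss yields `b`, the mean time in the
photographable cluster — the **probabilistic association threshold** —
along with `a` (effective cluster size) and `c` (mean time outside).

Associations scored per sampling day under this criterion (and under two
reference criteria, same-frame and same-encounter) are collapsed into
half-weight index (HWI) matrices and evaluated with the standard battery:
coefficients of variation with within-day permutation nulls, Mantel tests
against group (e.g. matriline) membership, leading-eigenvector modularity
clustering, and likelihood-based social differentiation. A simulator with
known residence dynamics and planted social units makes every step testable
without field data.

## Worked example

```r
library(probassoc)

# a society of 24 individuals in 4 social units, photographed over 20 days
# (60 collection events of ~50 frames); true mean residence time in the
# photographable cluster is 10 frames
cfg <- simulation_config(
  n_individuals = 24, n_units = 4, mean_residence = 10, mean_absence = 40,
  within_unit_cohesion = 0.9, between_unit_mixing = 0.05,
  frames_per_event = 50, events_per_day = 3, n_days = 20, n_years = 1,
  p_identify = 0.2)
records <- simulate_identifications(cfg, seed = 1)

# 1. lagged identification rate within events + residence-model fit
fit <- fit_residence_model(empirical_lir(records), seed = 1)
print(fit)

# 2. daily associations under the fitted threshold, full evaluation
units <- setNames(records$unit[!duplicated(records$individual)],
                  records$individual[!duplicated(records$individual)])
assoc <- daily_associations(records, "probabilistic",
                            threshold = fit$threshold$threshold)
report <- evaluate_social_structure(assoc, membership = units,
                                    n_permutations = 1000,
                                    n_trials = 1000, seed = 42)
print(report)
```

This prints:

```
Emigration + reimmigration LIR fit
  a = 2.329, b = 12.567, c = 86.080 (logLik -139.05, 10080 pairs)
  association threshold: 13 ordinal units (raw b 12.57)
Social-structure evaluation (probabilistic criterion, threshold 13)
  24 individuals over 20 days
  mean HWI 0.193 +/- 0.157 (non-zero 0.231 +/- 0.144)
  %HWI = 0: 16.7; %0 < HWI < 0.5: 76.4; %HWI >= 0.5: 6.9
  CV 0.815 (P = 0.000999), non-zero CV 0.622 (P = 0.000999)
  Mantel: matrix correlation 0.743, P = 0.000999
  communities: 4 clusters, Q = 0.214
  social differentiation S = 0.445
```

Reading the numbers: the fitted mean residence time (`b` ≈ 12.6 frames,
rounded to a 13-frame threshold) is close to the simulated truth of 10;
identifications within 13 frames of each other in the same event mark a
dyad as associated for that day. The CV permutation tests reject the
no-preference null at the smallest attainable P (1/1001 with 1000
permutations), the Mantel correlation of 0.74 shows associations
concentrate within the planted units, modularity clustering recovers
exactly the 4 planted units, and social differentiation of 0.45 indicates
moderately diverse association strengths.

Real data enter through `read_identifications("ids.csv")` (columns
`individual,event,ordinal,date`, attribute columns free-form), and
`run_pipeline(run_config(...))` chains every stage with one seed. A thin
command-line front end with verbs `simulate`, `lir`, `associate`,
`evaluate` and `run` is installed at `inst/scripts/probassoc`.

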