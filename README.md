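# shiftpdc

Data-mining of working-hour patterns in shift work, and their association
with sickness absence (SA). The package is written for occupational-health
researchers who hold payroll-style shift logs (employee, shift start, shift
end) plus dated sickness-absence indicators, and want a hypothesis-free
characterization of working-hour patterns over time:

1. **Cleaning and inclusion** — merge back-to-back payroll rows (1-minute
   rule), drop sub-3-hour artefacts, keep each employee's longest stretch
   without pauses of more than 4 days, require a span of at least 3×365
   days and full-time work (≥ 150×7.75 h in every sliding 52-week window),
   and build the per-employee 3-dimensional series
   (x<sub>t,w</sub>, x<sub>t,r</sub>, x<sub>t,s</sub>)<sub>t=1..T</sub>
   of shift length, between-shift rest, and start hour indexed by shift
   succession.
2. **Permutation distribution clustering (PDC)** — each dimension is
   delay-embedded into windows of length *m* (delay *t*), every window is
   reduced to its *codeword* (the stable argsort rank pattern), and the
   empirical codeword distribution is the employee's *codebook* for that
   dimension. The distance between employees is
   √(D<sub>w</sub>² + D<sub>r</sub>² + D<sub>s</sub>²), where each D is
   the symmetric alpha divergence (α = 0.5; four times squared Hellinger)
   between codebooks. Employees are agglomerated with complete linkage
   and the number of clusters is chosen by BIC over per-cluster codeword
   multinomials (AIC available).
3. **Assignment** — new or partial series are mapped onto an existing
   clustering by the nearest neighbour among reference codebooks,
   supporting prospective designs that split each series into a past half
   (exposure) and future half (outcome).
4. **Shift-ergonomics risk scores** — three burden scores on a 0–3 scale:
   total work per spell between days off, night shifts per 3-week window,
   and quick returns (rest < 11 h) per spell.
5. **Sickness-absence modelling** — Poisson regression of SA days with
   offset log(T/365); coefficients are reported as incidence rate ratios
   (IRR) with 95% Wald intervals, continuous covariates standardized by
   2 SD; cross-sectional and prospective model suites.
6. **Synthetic rosters** — a seeded generator for eight working-hour
   archetypes (regular M/E rotation, irregular morning work, irregular
   three-shift work with and without interruptions, regular and variable
   morning work, quickly and slowly rotating M/E weeks) with archetypal SA
   rates, so every stage is testable without registry data.

## Worked example

```r
library(shiftpdc)

coh  <- generate_cohort(c(regular_me = 15, regular_m = 15,
                          irregular_men_interrupted = 15),
                        days = 560, seed = 2024,
                        noise = list(dup_rate = 0, junk_rate = 0.02,
                                     split_rate = 0.02))
prep <- prepare_cohort(coh$shifts, min_span_days = 0,
                       require_full_time = FALSE)
res  <- pdc_cluster(prep$series, m = 4, t = 1, ks = 1:6)
res$solution
#> <cluster_solution> k = 3 (BIC), 45 employees; sizes: 15, 15, 15
```

BIC recovers the three generating archetypes exactly (ARI = 1). Scoring
the clusters and regressing simulated SA days on membership:

```r
labels <- res$solution$labels
arch   <- vapply(split(coh$labels[names(labels)], labels),
                 function(x) names(which.max(table(x))), "")
named  <- setNames(arch[as.character(labels)], names(labels))
scores <- cohort_risk_scores(prep$series)
outc   <- build_outcomes(prep$series, coh$sa, named,
                         demographics = coh$demographics, scores = scores)
fit_poisson(outc, reference_cluster = "regular_me")
#> <fit_result> Poisson IRR table
#>                               term   irr ci_low ci_high
#> 1                      (Intercept) 7.491  5.831   9.624
#> 2                            woman 1.137  0.880   1.469
#> 3                              age 1.034  0.859   1.244
#> 4 clusterirregular_men_interrupted 1.534  1.273   1.848
#> 5                 clusterregular_m 0.596  0.472   0.754
```

The intercept is the reference cluster's SA rate in days/year (generating
value 8.58); the irregular, interrupted three-shift cluster carries an
IRR of 1.53 against a generating rate ratio of 13.03/8.58 ≈ 1.52, and the
regular-morning cluster is protective (generating ratio 5.81/8.58 ≈ 0.68).
Past-half codebooks assign 100% of employees back to their full-data
cluster here:

```r
halves <- lapply(prep$series, function(ws) split_half(ws)$past)
qcbs   <- lapply(halves, employee_codebooks, m = 4, t = 1)
asg    <- assign_many(qcbs, res$store)
mean(asg$cluster == labels[asg$employee_id])
#> [1] 1
```

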