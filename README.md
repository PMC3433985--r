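# gobyclock

Waterfall-calibrated molecular clocks and population analyses for
landlocked stream gobies.

## The problem

Amphidromous gobies — fish whose larvae go to sea and migrate back
upriver — are blocked by waterfalls. A population trapped above a
growing waterfall becomes landlocked and diverges from the amphidromous
source species independently above each fall, producing repeated,
parallel origins of a freshwater form across the rivers of a single
island. Because waterfalls are built by steady bedrock erosion, waterfall
height doubles as a clock: regressing the mtDNA distance *D* of each
landlocked population (measured against the pooled source species) on
the height *h* of its waterfall,

    D = β₀ + C·h,

and combining the slope *C* (per metre) with an independent divergence
rate *R* (substitutions/site/year) gives the erosion rate

    E = R / C   [m/yr],

and an isolation age for every waterfall of known height:

    age = h / E.

`gobyclock` implements that inference chain end to end for population
geneticists and landscape-evolution researchers: alignment handling and
haplotype collapsing, Tamura–Nei (TN93) distances with continuous gamma
rate correction (shape 0.14), two-level AMOVA with a φST permutation
test, statistical parsimony haplotype networks, morphological character
tests (exact Mann–Whitney, Ward clustering, morphology-vs-genetics
regression, t tests from printed summaries), occupancy models that stay
finite under the perfect separation a waterfall dummy induces (Firth
bias-reduced logistic regression with exhaustive AIC subset selection and
AUC), Poisson random-intercept richness models, MANOVA on site
environments, and the erosion clock itself. A synthetic-data generator
with exact ground truth (`simulationConfig()` / `simulateSystem()`)
makes every stage testable by parameter recovery without any field data.

## Worked example

Fit the clock to the nine surveyed waterfalls (the packaged
`waterfallTable()`), using population-to-source distances that lie on
the published regression line, and the standard goby divergence rate of
3.8 % per million years:

```r
library(gobyclock)

wf    <- waterfallTable()
dated <- wf[!is.na(wf$age_printed_yr), ]
pts   <- data.frame(name = dated$name, height_m = dated$height_m,
                    distance = 0.0022 + 0.000057 * dated$height_m)
clockAnalysis(pts, rate = substitutionRate(3.8))
```

```
Waterfall clock fit on 8 populations
  D = 0.0022 + 5.7e-05 * h   (F[1,6] = 8.5e+31, r2 = 1.000, P = 1.1e-94)
  rate R = 3.8e-08 /yr  ->  erosion rate E = 0.67 mm/yr
  ages: Nakara=41850 yr, Mariudo=29100 yr, Pinai=88050 yr, Nishida=10800 yr,
        Kura=11400 yr, Geta=49050 yr, YuchinRight=66300 yr, YuchinLeft=63750 yr
```

The slope 5.7×10⁻⁵ per metre converts to an erosion rate of 0.67 mm/yr
— inside the independent geomorphological plausibility band of 0.3–1.0
mm/yr (`checkErosionRate(0.67)`) — and the ages say the landlocked
populations above 7–59 m falls have been isolated for roughly
11,000–88,000 years.

The same chain runs on a fully synthetic island with known truth:

```r
rep <- runPipeline(pipelineConfig(simulate = simulationConfig(), seed = 7))
print(rep)
```

```
gobyclock pipeline report (seed 7 )
  seqdata : 160 individuals, 84 haplotypes, 2086 bp
  AMOVA   : 99.4% among landlocked populations
  clock   : E = 0.44 mm/yr (r2 = 0.82)
```

A single simulated island is a noisy draw (substitution counts on a
2086-bp branch are small); the recovery experiment
`erosionRecovery(50, seed = 1)` runs 50 replicate islands and returns a
median estimate within a few percent of the true 0.67 mm/yr.

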