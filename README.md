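# ambientpain

Passive ambient sensors — passive-infrared (PIR) motion detectors and
magnetic door contacts — record a date/time-stamped event every time a
person moves through their home. For older adults living alone, that
stream is a continuous, camera-free record of daily behavior: when they
sleep, how often they get up at night, how long the walk from bed to
toilet takes, how much time they spend in a favorite chair, whether they
leave the house. `ambientpain` implements a pipeline that turns such
event streams into daily **behavior markers** and asks whether days
affected by pain (acute episodes or flares of chronic pain) can be told
apart from routine, relatively pain-free days — the kind of passive pain
assessment that matters for people who under-report pain or cannot
self-report at all.

Because real smart-home health datasets are private, the package ships a
calibrated **synthetic cohort generator** as a first-class, tested
component: it simulates a single occupant's routine at roughly 2,000
sensor ON events per day (~60,000/month) and injects pain events that
perturb behavior along six themes — overall activity level, nocturnal
bed–toilet transitions (a walking-speed proxy), favorite-chair time,
grooming, out-of-home time, and visitors.

## The markers

For each participant-day, the extractor builds 50 hourly ON-event count
series: 1 overall + 36 home locations + 13 daily-activity classes
(Bathe, Bed-Toilet Transition, Cook, Eat, Enter Home, Leave Home,
Personal Hygiene, Relax, Sleep, Take Medicine, Wash Dishes, Work, Other
Activity). Eleven statistical measures — mean, median, standard
deviation, maximum, minimum, zero crossings, mean crossings,
interquartile range, skewness, excess kurtosis, and signal energy — are
applied to every series, giving a **550-entry statistical block**
(11 × 50). Two further marker families are appended:

- **Schedule regularity** `R = 1 − mean_{d<d', h} TV(p_{d,h}, p_{d',h})`,
  where `p_{d,h}` is the hour-`h` categorical distribution of day `d`'s
  events over locations (or activities) and TV is total-variation
  distance; `R = 1` for perfectly repeated days.
- **Circadian rhythm strength**: the periodogram of the mean-centered
  concatenated hourly activity series over a window of `W` days, with
  strength `P(W) / Σ_{k≤N/2} P(k)` — the fraction of spectral power at
  the 24-hour period (1 for a pure 24-h cosine, 0 for a constant).

## The models

Labeled days (pain vs pain-free, matched 1:1 per participant, controls
drawn from nurse-style "normal weeks" nearest in time) feed four
analyses under **group-aware 3-fold cross-validation** — all days of one
pain event and its matched controls share a fold:

- a random-forest classifier (100 trees; vote fractions as scores),
  reporting pooled out-of-fold accuracy, sensitivity, specificity,
  AUROC, and AUPRC;
- a regression tree on the binary pain indicator, reporting the Pearson
  correlation of out-of-fold predictions with the indicator;
- an unguided isolation-forest baseline (100 estimators, contamination
  = pain prevalence), which never sees labels during fitting;
- an information-gain ranking of all 553 markers (single-threshold split
  entropy in bits), plus a paired permutation test comparing guided vs
  unguided per-day correctness.

## Worked example

```r
library(ambientpain)

# one simulated routine day
d <- simulate_day(routine_profile(), seed = 4)
sum(d$events$state == "ON")
#> [1] 1636   # ~2,000 ON events/day on average, ~60,000/month
traversal_time(d$events, "bed", "toilet")
#> [1] 29.1   # seconds, one nocturnal bed->toilet walk

# a small cohort end to end
cfg <- default_config(master_seed = 42, model_seed = 42)
cfg$cohort$n_participants <- 3L
cfg$cohort$monitoring_days <- 80L
cfg$cohort$n_pain_events <- 4L
res <- run_pipeline(cfg, out_dir = "runs/demo")
print(res$report)
#> evaluation_report: accuracy 0.953, sensitivity 0.938, specificity 0.969,
#>                    AUROC 0.995, AUPRC 0.995
res$report$pearson_r           #> 0.611
res$report$baseline_accuracy   #> 0.562   (unguided isolation forest)
res$report$comparison_p        #> 1e-04   (guided vs unguided, paired permutation)
head(res$report$ranking, 5)
#>                           marker      gain direction
#> 1            regularity_activity 0.5757570        -1
#> 2 act:Bed-Toilet Transition.mean 0.5567531         1
#> 3            regularity_location 0.5511355        -1
#> 4    loc:recliner.zero_crossings 0.5123745         1
#> 5                     overall.sd 0.5123745        -1
```

The ranking reads directly as clinical findings: on pain days the
schedule is less regular, nightly bed–toilet transitions are more
frequent (direction +1), favorite-chair occupancy changes shape, and
overall activity is lower (direction −1). The run directory contains the
cohort tables, the 553-column feature TSV, the report JSON, and the
ranking TSV, each stamped with the hash of the config that produced it;
rerunning the same config reproduces every file byte-for-byte.

A thin CLI wrapper with `simulate` / `annotate` / `run-all` subcommands
is installed at `inst/cli/ambientpain.R`.

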