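# odortask

Discrete-event simulation and analysis of automated olfactory training
protocols for head-fixed mice.

Automated rigs train water-restricted, head-fixed mice on odor-based
cognitive tasks with no experimenter in the loop: an olfactometer delivers
brief odor pulses, licks are detected capacitively, a pump delivers water,
and a protocol controller decides every trial. `odortask` reimplements that
controller as a pure-software discrete-event engine, with simulated mouse
agents standing in for the animal and hardware. It is aimed at behavioral
neuroscientists and rig engineers who want to design, audit, or regression-
test training protocols — timing, switching rules, termination conditions,
reward accounting — before (or instead of) running animals.

The package covers:

* **Four paradigms** — delayed non-match to sample (DNMS), delayed paired
  association (DPA), go/no-go (GNG), and GNG reversal — as one trial
  skeleton with per-paradigm contingency maps and standard default timing
  (1-s odors; 4–5 s / 8–9 s delays; 0.5–1.5 s or 0.5–1.0 s response
  windows; 10/16/5-s ITIs; 24-trial balanced blocks).
* **Three training phases** as state machines: automatic lick teaching
  (10 µL bout opener, 4 µL per three licks, 2-s quiet timeout, 200 µL bout
  cap, 400 µL session target), automatic shaping (self-learning vs.
  program-teaching trials switching on a 5-misses-in-30-trials sliding
  rule, ending at 100 hits), and the full task.
* **Simulated agents**: silent, continuous 8-Hz licker, per-type Bernoulli,
  and a Rescorla–Wagner learner (`V ← V + α(r − V)` on licked trials only)
  that reproduces the qualitative learning-curve shape: rising performance
  and CR rate, ceiling hit rate, and dip-and-recovery after reversal.
* **Olfactometer kinetics**: first-order rise/decay per odorant calibrated
  from the measured 95% rise latency and 1/e decay constant
  (τ_r = L95 / ln 20), with closed-form inversion.
* **The analysis toolkit**: blocked performance and rates,
  d′ = Φ⁻¹(hit rate) − Φ⁻¹(false-choice rate) with extreme rates clipped to
  1/(2n) and 1 − 1/(2n), licking efficiency, 100-ms-binned lick-rate curves
  with span-5 smoothing, trials-to-criterion (> 80% in a sliding 24-trial
  window; NRC when never reached) and well-trained detection (three
  consecutive qualifying windows).

Sessions are logged as plain-text event streams (integer-ms timestamps,
one event per line) with a companion trial-table CSV and JSON summary;
round trips are lossless and runs are byte-identical per seed.

## A worked example

```r
library(odortask)

cfg   <- default_config("DNMS")
agent <- delta_rule_learner(alpha = 0.1, p0 = 0.6)
rec   <- run_task_session(cfg, agent, seed = 1, n_trials = 96)
rec
#> <session_record> phase: task  paradigm: DNMS  seed: 1
#>   trials: 96  hits: 44  reward: 220 uL
#>   events:799 terminated by:completed

block_stats(rec$trials$outcome)[, c("block", "performance", "hit_rate",
                                    "cr_rate", "d_prime")]
#>   block performance hit_rate cr_rate d_prime
#> 1     1       0.708    0.917   0.500   1.383
#> 2     2       0.792    0.917   0.667   1.814
#> 3     3       0.750    1.000   0.500   1.732
#> 4     4       0.625    0.833   0.417   0.757

licking_efficiency(rec)
#> [1] 0.6567164
trials_to_criterion(rec$trials$outcome)
#> [1] 43
```

Ninety-six trials of a delta-rule learner: the hit rate is already near
ceiling while correct rejections hover around chance, so performance sits
in the 0.6–0.8 range — the early-training signature. The learner's first
24-trial window strictly above 80% correct ends at trial 43; about 66% of
its licks earned water.

The same workflow is available from a shell:

```sh
odortask simulate --paradigm dnms --phase task --agent delta \
         --agent-param alpha=0.1,p0=0.6 --n-trials 96 --seed 1 --out runs/
odortask analyze --in runs/dnms_task_seed1 --out summary.csv
odortask reverse --in gng_config.json --out gng_reversed.json
```

## Package layout

* `R/` — configuration, event logs, contingency maps, trial scheduling,
  the three phase engines, agents, olfactometer kinetics, analysis, I/O,
  CLI.
* `tests/testthat/` — unit, property and end-to-end suites (independent
  oracles included alongside).
* `vignettes/odortask-methods.Rmd` — the model and design decisions in
  detail.
* `exec/odortask` — the command-line launcher.
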