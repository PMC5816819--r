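---
title: "Simulating automated olfactory training: protocols, agents, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated olfactory training: protocols, agents, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odortask)
```

## What this package models

Automated training rigs for head-fixed mice run olfactory tasks end to end
without an experimenter in the loop: an olfactometer delivers brief odor
pulses, a capacitance sensor registers licks, a peristaltic pump delivers
water, and a protocol controller decides — trial by trial — what happens
next. `odortask` is a software-only reconstruction of that controller as a
discrete-event engine. Simulated mouse agents stand in for the animal, so
every protocol rule can be exercised, timed and audited on a desk.

Four paradigms are covered, sharing one trial skeleton (odor(s), response
window, fixed inter-trial interval or ITI):

* **DNMS** (delayed non-match to sample): sample odor, 4–5 s delay, test
  odor; licking is rewarded when the test differs from the sample.
* **DPA** (delayed paired association): sample from {S1, S2}, 8–9 s delay,
  test from {T1, T2}; the pairs S1–T1 and S2–T2 are rewarded.
* **GNG** (go/no-go): a single cue; lick after the Go cue for water,
  withhold after the No-go cue.
* **GNG reversal**: the GNG map with every cue's go/no-go role swapped.

Within each paradigm, three training phases form the automated curriculum:
*lick teaching* (learn to lick the port at all), *shaping* (learn the trial
structure on rewarded trials only), and the *full task*. Nothing is ever
punished; an error simply goes unrewarded.

## The protocol state machines

### Trial anatomy and classification

A trial starts with a 1-s odor pulse (two pulses separated by the delay for
the two-odor tasks). The response window opens 0.5 s after the offset of
the final odor and closes at 1.5 s (1.0 s for DPA). A go trial with at
least one lick in the window is a **Hit** and triggers an instantaneous
5 µL water delivery at the triggering lick; with none it is a **Miss**. A
no-go trial with an in-window lick is a **False Choice**, otherwise a
**Correct Rejection**. Licks outside the window never change an outcome.

Two numerical conventions matter here:

* **Integer milliseconds.** All event times are integer ms from session
  start. This mirrors microcontroller event streams and makes event
  ordering exact; configurations and analyses speak seconds.
* **Half-open windows.** The response window is `[start, end)`: a lick
  exactly at the start counts, exactly at the end does not. Protocol
  descriptions state the window without boundary semantics; half-open
  intervals compose without double counting, and the choice is covered by
  explicit boundary tests.

Trials are scheduled in blocks of 24 — divisible by the 4 odor-sequence
types of DNMS/DPA and the 2 cues of GNG — with every sequence type equally
frequent inside every block and a seeded shuffle deciding the order. The
delay is drawn per trial, uniformly over the configured range and rounded
to the ms grid. A uniform per-trial draw is the least-informative reading
of a stated "4–5 s" range; a constant delay is one configuration edit away
(`delay_range_s = c(4.5, 4.5)`).

### Lick teaching

Each bout opens with the water port advancing and a 10 µL delivery; from
then on every third lick earns a 4 µL drop. A bout ends when 2 s pass
without a lick or the bout's volume strictly exceeds 200 µL; bouts repeat
until the session total reaches 400 µL. Descriptions of this protocol vary
between ~5 µL and 4 µL for the per-three-licks drop; the package defaults
to 4 µL and leaves the variant one configuration field away (`drop_uL`).
Two plumbing parameters have no protocol-level counterpart and were fixed
once at field-plausible values: a 1-s
inter-bout gap (port travel time) and a 20-bout session cap so that a
never-licking agent cannot run a session forever.

With a continuous 8-Hz licker the arithmetic is exact: a bout crosses the
cap at 10 + 4·48 = 202 µL after 144 licks, and the second bout's 404 µL
total ends the session.

### Shaping

Shaping presents only go-type trials. Trials come in two modes:

* **self-learning** — reward is lick-triggered, the port does not move;
* **program-teaching** — the port advances and water arrives automatically
  at window start, not triggered by licking.

The engine switches to program-teaching when the animal has missed 5 times
within the last 30 trials (a sliding window; both a 30- and a 35-trial
window circulate for this rule — `miss_window_trials` decides, defaulting
to 30) or when the previous teaching trial was missed. One in-window lick during a teaching trial hands the next trial
back to self-learning; that hand-back takes precedence over the miss
buffer, which otherwise would pin the mode at teaching until the misses age
out — precedence is the only reading under which teaching and self-learning
can alternate trial by trial, which is how the protocol is intended to
behave. A session ends at 100 cumulative Hits. An automatic delivery
alone does not make a Hit: a trial counts as a Hit only if an in-window
lick occurred, so the hit-target accounting always reflects behavior, never
the pump.

### Safety caps

Pathological agents must not hang a session, so two caps bound every run:
1000 trials and 2 h of simulated time (mirroring the 1–2 h a mouse spends
in the apparatus daily). Both live in the configuration. Longitudinal
experiments that compress several training days into one call (e.g. the
600-trial learning-curve run below) raise `max_session_s` explicitly and
say so.

## Simulated agents

Agents replace the animal, not model it. The package makes no claim that
any agent parameter fits a real mouse's learning curve; agents exist so
that protocol logic, logging and analysis can be tested against policies
with known ground truth.

* `silent_agent()` never licks — every balanced block scores exactly 0.5.
* `continuous_licker(rate_hz = 8)` licks on a fixed session-wide grid,
  through ITIs too. 8 Hz sits in the typical rodent licking range (~6–9 Hz)
  and guarantees in-window licks for any window ≥ 125 ms.
* `bernoulli_agent(c(go =, nogo =))` licks once mid-window with a per-type
  probability; (1, 0) is the perfect agent.
* `delta_rule_learner(alpha, p0)` keeps a Rescorla–Wagner value `V` per
  odor sequence, starting at `p0`, licks with probability `V`, and after a
  licked trial moves `V` toward the outcome: `V ← V + α(r − V)`, `r = 1`
  iff rewarded. Unlicked trials learn nothing, because the task gives no
  feedback for withheld licks — the minimal learner consistent with a
  no-punishment design. Go values climb to ceiling, no-go values decay,
  which reproduces the qualitative learning-curve shape seen in trained
  animals: performance and CR rate rise while the hit rate saturates; after a GNG reversal, performance dips
  and then recovers as licked errors re-teach the swapped map.

All agents draw randomness from the session's RNG stream, so a
`(config, agent, seed)` triple reproduces a byte-identical session record.

## The olfactometer model

Odor delivery is modeled as a first-order system per phase, calibrated from
two measured constants per odorant: the rise latency `L95` (time to 95% of
the concentration plateau after valve opening) and the decay constant
`τ_d` (time to 1/e after closure). One latency and one decay constant are
all that is characterized per odorant, so a single exponential per phase is
the right model order; the implied rise constant is `τ_r = L95 / ln 20`.
Plateaus are normalized to 1 — photoionization readouts are relative — and
the vapor volume ratio rides along as metadata. The stock panel:

```{r}
odorant_panel()
```

`time_to_fraction()` inverts each phase in closed form, so calibration
round-trips to numerical identity: the 95% rise time of the calibrated
trace *is* `L95`, and the 1/e decay time *is* `τ_d`.

## Analysis toolkit

All statistics operate on classified outcomes or raw event logs:

* **Blocked measures** (24-trial blocks): performance
  `(hits + CRs)/total`, hit rate `hit/(hit+miss)`, false-choice and CR
  rates over no-go trials.
* **d′** = Φ⁻¹(hit rate) − Φ⁻¹(false-choice rate), with extreme rates
  clipped to `1/(2n)` and `1 − 1/(2n)`. The clipping `n` is the *block's*
  go or no-go count — the standard correction defines `n` as the number of
  possible trials of that side without fixing per-block vs. per-session;
  per-block is used because d′ is reported per block.
* **Licking efficiency** = rewarded / all licks, where a lick is rewarded
  iff its timestamp coincides with a pump trigger. Lick-level reward
  attribution is ambiguous in the efficiency formula as usually stated;
  one trigger per Hit makes the ratio well defined.
* **Lick-rate curves**: 100-ms bins averaged across trials, scaled to Hz,
  smoothed by a span-5 centered moving average whose window shrinks
  symmetrically at the edges (spans 1, 3, 5, …), replicating the classic
  smoothing routine's edge behavior.
* **Trials to criterion**: the index of the last trial of the first
  24-trial window whose correct rate is *strictly* above 80% (so 20/24
  qualifies, 19/24 does not); `NA` means NRC (not reaching criterion). The
  phrase "trial numbers before reaching" could also mean `index − window`;
  the chosen reading makes the minimum value 24 and matches how NRC is
  used. **Well-trained** requires three consecutive window positions
  (stride 1) above criterion.
* **Cross-subject summaries** report mean ± SEM per block with N = number
  of simulated sessions.

## A worked session

```{r}
cfg <- default_config("DNMS")
agent <- delta_rule_learner(alpha = 0.1, p0 = 0.6)
rec <- run_task_session(cfg, agent, seed = 1, n_trials = 96)
rec
block_stats(rec$trials$outcome)[, c("block", "performance", "hit_rate",
                                    "cr_rate", "d_prime")]
```

Records round-trip losslessly through three plain-text files (line-per-event
log, trial-table CSV, JSON summary with the config snapshot and seed), and
`odortask_cli()` / the `odortask` script wrap the same functions for shell
use.

## What the simulations do and do not show

The generator's defaults are the protocol's standard parameters; problem
sizes in the test suite are desk-scale by design (24–600 trials per
session, 5–20 seeds per property). Passing tests establish that the
*protocol logic* — scheduling balance, switching rules, termination
conditions, reward accounting, formula implementations — behaves exactly as
specified, and that the learning-curve *shape* emerges for a simple
reinforcement learner. They do not validate any quantitative claim about
real mice: real licking has burst structure, satiety and motivation drift,
inter-animal variability and day boundaries that no agent here models, and
animal-level statistics (ANOVAs across real subjects) are deliberately
out of scope.

Known limitations, kept on purpose: no punishment modeling (the protocol
has none); no pneumatic-network simulation behind the kinetic model; no
inter-day water-supplementation bookkeeping beyond the session totals;
teaching bouts ignore licks that arrive after a bout closes (the port has
retracted). The bout horizon (600 s), lick-contact duration (30 ms) and
pump-pulse duration (50 ms) are plumbing constants exposed in the
configuration.
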