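# relapsetraj

Relapse trajectories in schizophrenia from patient-registry data.

For patients with schizophrenia, the number of prior relapses is a strong
risk factor for the next one, and intervals between relapses tend to
shorten as episodes accumulate. `relapsetraj` implements, end to end, the
registry analysis that quantifies this trajectory, for epidemiologists and
biostatisticians working with administrative health data:

1. **Relapse proxies** — operational rules that identify relapse episodes
   from registry events: a psychiatric hospitalisation of ≥7 days with a
   7-day (or, redefined, 30-day) post-discharge merge window; an overnight
   psychiatric stay followed by an antipsychotic treatment switch (new ATC
   N05A treatment line within 30 days of discharge); a burst of ≥8
   outpatient psychiatric visits in a fortnight.
2. **Cohort construction** — ICD-10/ICD-9 code classifiers (F20.0–F20.9 /
   295.0–295.9 excluding 295.7 for schizophrenia; F01–F69, F90–F98 /
   290–316 for psychiatric care), inclusion criteria (≥2 diagnosis records,
   ≥1 filled N05A prescription, ≥1 overnight psychiatric discharge), index
   date at the first overnight psychiatric discharge, and incident /
   ≥1-diagnosis / include-prevalent variants.
3. **Recurrent-event analysis** — counting-process data with the
   time-varying prior-relapse count k, age class, gender and calendar year;
   at-risk time for the (k+1)-th relapse starting at the end of the k-th
   episode (discharge + quiet window); the cause-specific Cox model

   &nbsp;&nbsp;&nbsp;&nbsp;λ(t | k, x) = λ₀(t) · exp(β_k + γ'x),&nbsp;&nbsp;HR_k = exp(β_k) vs k = 0,

   with death and end of follow-up censored, Efron ties, Wald 95% CIs; and
   the Aalen-Johansen estimator of the cumulative incidence F_rel(t) of the
   next relapse on gap time (clock reset at each episode end) with death as
   a competing risk, from which the median time to next relapse per stratum
   is read off.

Because national registers cannot be redistributed, the package includes a
**synthetic-registry simulator** (`simulate_cohort()`) with known ground
truth: gap-time relapse hazards h₀·rᵏ, a competing death process,
hospital-stay realisation of every true relapse, antipsychotic dispensation
streams with post-relapse switches, and noise records. Every pipeline stage
is validated against this ground truth or against brute-force oracles.

## Worked example

```r
library(relapsetraj)

sim  <- simulate_cohort(sim_params(n_patients = 2000, seed = 1))
traj <- relapse_trajectory(sim$bundle, proxy = "primary", cox_timescale = "gap")
traj
```

```
<relapse_trajectory> proxy: primary | cohort variant: incident_2dx
  2000 patients -> 1880 included -> 1516 with >= 1 relapse; 10165 relapse events analysed
Relapse risk by number of prior relapses (proxy: primary )
  k  n at risk   events    median time (years)  HR (95% CI)
  0       1880     1516                   1.40      1 (ref)
  1       1505     1264                   0.94 1.52 (1.41-1.65)
  2       1243     1096                   0.63 2.34 (2.16-2.54)
  ...
  5        871      816                   0.18 7.54 (6.88-8.26)
```

Each row is a prior-relapse stratum: `n at risk` counts patients who enter
it, the median is the gap time by which half the stratum has relapsed again
(Aalen-Johansen, death as competing risk), and the HR compares the stratum's
cause-specific relapse hazard with patients who have no relapse since their
index hospitalisation. Under the generator's truth (h₀ = 0.5/year,
r = 1.5) the expected values are HR_k = 1.5ᵏ and median_k = ln2/(0.5·1.5ᵏ)
= 1.39, 0.92, 0.62, … years — the fitted column reproduces them.

`autoplot(traj$cif)` draws the per-stratum cumulative-incidence curves;
`autoplot(traj$cox)` the hazard-ratio forest; `tidy(traj$cox)` /
`glance(traj$cox)` give broom-style tables. A thin CLI over the same
functions is installed at `inst/cli/relapsetraj`
(`simulate`, `episodes`, `run-all`).

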