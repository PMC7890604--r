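---
title: "Computed versus structured diagnoses: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computed versus structured diagnoses: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxdelay)
```

# The problem

Structured ICD diagnosis codes are the workhorse of EHR-based cohort
definition, but they are written by humans inside clinical workflows: a
patient can satisfy every measurement-based criterion for hypertension,
hyperlipidemia, or diabetes long before — or without — a corresponding code
appearing in the history or problem list. `dxdelay` measures that
completeness gap and its latency. Two quantities per condition summarize it:
the fraction of measurement-defined ("computed") cases that never acquire a
code, and, among cases coded only after the computed diagnosis, the delay
distribution estimated under right censoring.

# The computed-diagnosis rule

**Same-day minimum.** All measurements of one kind on one calendar day are
collapsed to their minimum before thresholding. This is deliberately
conservative: a day counts as abnormal only if even its most favorable
reading is abnormal. For blood pressure the systolic and diastolic daily
minima are taken *independently*, possibly from different readings — the most
restrictive reading of the rule. Only outpatient blood pressures are used
(inpatient readings reflect acute physiology); labs are accepted from every
encounter setting.

**Signals and the 30-day pair.** A day whose aggregated value meets the
condition's inclusive threshold (systolic ≥ 140 mmHg or diastolic ≥ 90 mmHg;
LDL ≥ 130 mg/dL; HbA1c ≥ 6.5 %) is a *signal*. One elevated reading is
common and nonspecific; the rule therefore requires two signals at least 30
days apart, and dates the computed diagnosis at the second. Formally, with
signal dates $d_1 < d_2 < \dots$, the diagnosis date is the earliest $d$
such that some earlier signal $d'$ satisfies $d - d' \ge 30$ days. Because
$d_1$ is the minimum, this reduces to the earliest signal $\ge 30$ days
after $d_1$ — but the implementation is tested against a brute-force
all-pairs oracle rather than trusting that reduction.

**Tunable parameters.** Thresholds (mmHg, mg/dL, %), the separation (days,
default 30), lab code sets (LOINC plus institution-local codes), and the
encounter-type codes counted as outpatient (default `AV`, `OA`) are all
configurable via `condition_spec()` and `cdm_colmap()`. Defaults are the
standard clinical cutpoints listed above.

# Structured diagnoses

Codes are normalized (uppercased, stripped; dotless strings of ≥ 4
characters get a dot after position 3, so `E780` and `E78.0` are the same
code) and matched by their first 3 or 5 characters against per-condition
parent groups (`code_groups()`). Matching never crosses code systems. The
shipped HTN ICD-10 set includes `I27` (pulmonary hypertension) and the
pregnancy-related groups `642`/`O13`; these are part of the study definition
this package operationalizes and are reproduced as shipped defaults rather
than silently corrected — the table is editable per study. The first
matching record per patient defines the structured-diagnosis date; when
several sources record on the same first date, provider-entered beats
billing beats claims, reflecting how directly each source expresses clinical
intent.

# Classification and time-to-diagnosis

Each computed-diagnosis patient is classified by where the structured date
falls relative to the two signal dates:

| category | condition |
|---|---|
| `pre_existing` | dx **strictly before** the first signal |
| `early` | first signal ≤ dx **<** second signal |
| `eventual` | dx ≥ second signal (event; duration = dx − second signal) |
| `never` | no dx (censored; duration = last encounter − second signal) |

The boundary reading — "prior to" and "after" strict, "between" half-open —
is an interpretation (the source description does not say how exact ties
were handled); it is the unique reading that makes the four categories an
exhaustive partition, which the pipeline asserts on every run. Patients with
a structured code but no computed diagnosis are reported as diagnostics
(`n_structured_only`) and enter no denominator.

Pre-existing and early patients are excluded from the time-to-diagnosis
analysis (their coding was not *prompted* by the computed diagnosis). On the
remaining cohort the Kaplan–Meier product-limit estimator is computed
directly — `km_estimate()` implements $S(t) = \prod_{t_i \le t} (1 - d_i /
n_i)$ with the standard events-before-censorings tie convention — rather
than delegated, so the package has no runtime survival dependency and the
test suite can compare it to `survival::survfit()` as a genuinely
independent oracle (agreement required to 1e-12). Greenwood standard errors
and log-log intervals are available but off by default; the analysis this
reproduces reported none. The last encounter date comes from the encounter
table only; a measurement date without an encounter row never extends
follow-up, and a censoring time that would be negative is floored at zero
with a warning.

# The synthetic world

Real extracts of this kind are protected health information, so the
generator (`synth_generate()`) is a first-class, tested module rather than a
fixture. It emulates exactly the structure the analysis assumes:

- **Encounters** are a homogeneous Poisson process (default 6/patient-year,
  a typical ambulatory contact rate) over the *full* window
  `[data_start, diagnosis_cutoff]`; settings are drawn from a categorical
  mix (78% outpatient). Measurements attach only to encounters on or before
  the measurement cutoff — blood pressures at outpatient encounters
  (default probability 0.85), labs at any setting (default 0.12–0.15,
  labs being ordered far less often than vitals are taken). Keeping
  encounters running past the measurement cutoff mirrors the real
  asymmetric-cutoff design and is what gives never-diagnosed patients long
  censoring times.
- **Values** are drawn half-normally above or below the threshold so the
  abnormal/normal intent survives rounding: diseased patients exceed the
  threshold with probability `p_abnormal` (default 0.9), healthy patients
  with `p_exceed` (default 0.02) — false positives are included on purpose,
  since suppressing isolated exceedances is precisely what the 30-day pair
  rule is for.
- **Diagnosis model.** After the measurement stream is realized, the
  generator derives the *realized* signal dates and places the structured
  code relative to them: `pre_existing` (uniform before the first signal),
  `early` (uniform between the signals), `never` (absent), or `eventual`
  at the second signal plus a delay drawn from Exponential(mean) or
  lognormal — no distributional form is claimed for real recording delays;
  both options are offered. The source is drawn from a provider/billing/
  claims mix (default 0.65/0.30/0.05, matching the observation that claims
  are rarely first). A share of emitted codes (default 20%) is written
  dotless to exercise normalization. The per-condition latent category
  probabilities default to values loosely anchored to the reported world
  (HTN often pre-existing or never-coded; DM almost always coded). The
  latent *early* probability is a generator extension — the analysis needs
  that category exercised end-to-end — and defaults to 0.15; it was chosen
  once, a priori, not fitted.
- **Determinism.** Every patient draws from a substream seeded
  deterministically from the master seed, so runs are byte-identical and
  patient subsets are stable.

**The truth ledger** records, per diseased patient-condition (and per
healthy patient with a false signal pair), the realized signal dates, the
latent category, the *expected observable* category, and a degeneracy flag.
Degeneracies are the documented, inevitable gaps between intent and
observation: a drawn delay landing past the diagnosis cutoff (the record
"does not exist yet", so the subject is censored — the spec-level reading of
clipping), a pre-existing code unplaceable because the first signal falls on
`data_start`, a diseased patient whose measurement draws never pair, and a
healthy patient whose false positives do. The end-to-end replay test
asserts that the pipeline reproduces the expected category for *every*
subject and that intended-versus-observed mismatches coincide exactly with
the flagged set.

**What a green run does and does not establish.** The generator matches the
analysis's structural assumptions by construction — stationary encounter
rates, independent conditions, no coding-practice drift, no site effects, no
correlation between disease severity and visit frequency, no unit errors.
Green tests establish that the machinery is correct and that parameters are
recoverable in a world obeying those assumptions; they say nothing about how
far a real institution's data depart from them.

# Numerical and degenerate-input choices

- Dates are day-granular; timestamps truncate on load. Window boundaries are
  inclusive at both ends, applied per record kind (measurement vs diagnosis).
- Unparseable dates, non-numeric values, empty codes, unmapped sources, and
  out-of-sanity-range vitals (≤ 0 or ≥ 400 mmHg) are dropped and *counted*
  in a load report — never silently coerced. No unit conversion is
  attempted.
- Empty inputs flow through: empty tables yield empty signal series, empty
  cohorts yield a flat KM curve at 1 (all-censored) or `NA` means with
  warnings (no events / no censorings).
- `probability_undiagnosed_at()` is right-continuous, returns 1 before the
  first observed time, and rejects negative times.

# Parameter recovery

The strongest acceptance property: in a 10,000-patient world with delays
drawn Exponential(mean 200 days), a 30% never-coded fraction, and ≥ 2,000
days of follow-up after every computed diagnosis, the pipeline's mean delay
among the diagnosed must sit within 5% of the analytic truncated-exponential
expectation $\mathrm{E}[D \mid D \le T_i] = \mu - T_i q_i/(1-q_i)$,
$q_i = e^{-T_i/\mu}$, averaged over realized follow-ups with weights
$1-q_i$, and the KM plateau at 2,000 days within ±0.02 of the cure fraction
0.30. Both tolerances are Monte-Carlo-scaled and were fixed before the
tests were first run.

# Known limitations

- Conditions are processed fully independently; comorbidity correlation and
  multi-condition interactions are out of scope, as are medication-based
  phenotypes, remission, and competing risks (death censors only via the
  last encounter, as in the source design).
- The ICD groups are parent-prefix sets, not terminology-service
  expansions; ICD-9↔10 equivalence mapping is not attempted.
- The synthetic demographics are placeholders; nothing downstream uses age
  or sex.
- Mean delay among the eventually diagnosed is a truncated-sample summary —
  it conditions on the code appearing within follow-up and will understate
  the delay a longer window would reveal; the KM curve is the unbiased
  object under the censoring assumptions.
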