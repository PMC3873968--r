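---
title: "Methods: Markov cohort modelling of endoscopic gastric cancer surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort modelling of endoscopic gastric cancer surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

In populations with low to intermediate gastric cancer (GC) risk,
population-wide endoscopic screening is hard to justify, but *surveillance* —
scheduled oesophagogastroduodenoscopy (OGD) restricted to subjects with
precancerous gastric lesions — may be cost-effective. `gccea` implements a
five-arm Markov cohort comparison for a cohort aged 50–69:

1. **none** — no OGD intervention (reference);
2. **surveil2y** — baseline OGD classifies the population; lesion carriers
   ("high risk", prevalence $p$) receive OGD every 2 years;
3. **surveil1y** — as above with annual follow-up;
4. **screen2y** — the whole population is examined every 2 years;
5. **screen2y_surveil1y** — 2-yearly screening plus annual surveillance of
   the high-risk group.

The comparison is a standard cost–utility analysis: discounted lifetime cost
and QALYs per person, incremental cost-effectiveness ratios (ICERs) along the
efficiency frontier with strict and extended dominance, net health benefit
$\mathrm{NHB} = E - C/\lambda$, and the optimal arm at a willingness-to-pay
$\lambda$ ($46,200/QALY, 2011 Singapore GDP per capita, by default).

## Model structure and assumptions

States are: asymptomatic (utility 1; split into low/high risk in the
intervention arms), GC stages 1–4 (stage utilities 0.88/0.86/0.77/0.68,
tracked with a years-since-diagnosis counter), and death from GC or other
causes (utility 0). Cycles are annual; the cohort starts asymptomatic and
runs until 99% have died or age 110.

The central mechanism is **down-staging without incidence change**: scheduled
examinations shift incident cancers toward earlier stages but do not alter
when cancer occurs. Incident cases in a group with detection weight $w$ are
staged by the mixture $w \cdot d_{\text{prog}} + (1-w)\cdot d_{\text{usual}}$
of the programme-detected distribution (85:4:8:3) and the usual-care
distribution (7:17:33:43). In an OGD year $w = Se$ (sensitivity 0.93); in the
interval year of a 2-yearly schedule the early-detection effect persists at a
reduced fraction $f$ of the annual effect ($w = Se\cdot f$, with $f = 0.6$
for 2-yearly surveillance and $f = 0.4$ for 2-yearly screening); $w = 0$
without follow-up. Cycle 0 counts as an OGD year for scheduled groups.
Compliance is complete, lesions do not regress, and conditional on stage all
arms share the same survival experience — so the whole benefit flows through
the stage mix.

GC mortality is a constant excess hazard per stage derived from 5-year
survival (90/70/40/0%) by $p = 1 - S_5^{1/5}$, combined independently with
background mortality, $1-(1-p_{gc})(1-p_{bg})$; deaths are attributed to
causes in proportion to the $-\log(1-p)$ hazards (this attribution only
feeds the GC-deaths output). Stage 4's printed 0% survival is replaced by a
residual `stage4_epsilon = 0.001` so the hazard stays finite; a test checks
results are insensitive to this choice up to 0.01.

### The risk split is re-solved every cycle

Surveillance arms need incidence split by lesion status. Given population
probability $q$, prevalence $p$ and odds ratio $OR$, the pair
$(q_{low}, q_{high})$ solves the mixture constraint
$p\,q_{high} + (1-p)\,q_{low} = q$ together with
$\mathrm{odds}(q_{high}) = OR \cdot \mathrm{odds}(q_{low})$ — a quadratic in
$q_{low}$ solved in closed form (the test suite checks it against an
independent bisection solver). A split solved once at baseline would drift
from the population incidence after cycle 0, because the high-risk share of
the surviving asymptomatic pool changes over time. The engine therefore
re-solves the split each cycle at the *current* high-risk share, which makes
total incident mass exactly equal across all five arms — the
incidence-invariance assumption holds to machine precision by construction,
and the reference arm is nested exactly when the detection effect is
switched off.

### Costs

2012 US$. Each delivered OGD costs `endoscopy_cost / (1 - pi)` where
`pi = 0.40` is the programme overhead share of the operating budget
(baseline OGD $350 at entry of the surveillance-enrolling arms; follow-up
and screening OGD $340). The pure screening arm's first round is an ordinary
$340 screen, not a $350 baseline — the baseline price is labelled as a
surveillance-entry cost. False-positive work-ups cost
$(1-Sp)\cdot 740$ per screened subject (zero at the base-case specificity of
1). Incident cases incur staging ($740 if programme-detected with weight
$w$, $1155$ under usual care) plus stage-specific treatment
(17,000/27,200/38,000/15,500). Survivors accrue a $955 post-treatment
follow-up cost annually for at most 5 years after diagnosis; whether the
source intended this once or annually is unstated, and the annual reading
over the standard 5-year oncology follow-up horizon is this package's
choice. Costs and QALYs discount at 3%/year, cycle 0 undiscounted. No
half-cycle correction by default (`econ.half_cycle_correction` applies a 0.5
weight to the first cycle's utility when enabled).

## Synthetic epidemiology

No registry tables ship with the package; the generator provides a stated
stand-in world, and any CSV (`age,sex,value`) can replace it.

* **Background (other-cause) mortality**: Gompertz–Makeham,
  $q(a) = 1 - e^{-(A + B e^{C a})}$ with $A = 5\times10^{-4}$, $C = 0.095$
  and $B = 4.5\times10^{-5}$ (male) / $2.5\times10^{-5}$ (female), giving
  life expectancies near 82 and 86 years — a developed East-Asian
  population.
* **GC incidence**: $I(a) = I_{50}(1+g)^{a-50}$ per 100,000, capped at
  2,000, with $I_{50} = 28$ (male) and 14 (female) and $g = 0.07$ —
  male incidence twice female, and a sharp rise after age 50 consistent with
  Singapore Chinese registry magnitudes.
* **Starting population**: uniform weights over ages 50–69 × sex (the true
  enrolment age pyramid is unavailable).

These defaults were fixed once for realism and are deliberately not tuned to
reproduce published results. What a green test establishes is therefore
structural (conservation, nesting, closed-form limits, dominance logic,
distributional calibration) — not agreement with registry-based numbers,
which the generator cannot know. In this synthetic world the base-case
2-yearly surveillance ICER is ≈ $59,000/QALY, so at $\lambda = 46{,}200$ the
reference arm is optimal; the published evaluation, driven by unpublished
registry inputs, found surveillance cost-effective. Features of real data
the generator does not emulate include cohort effects, secular incidence
trends, non-exponential age structure and age-varying lesion prevalence.

## Sensitivity analysis

**One-way DSA.** Each parameter is varied over its analysis range (cost
parameters halved/doubled; clinical parameters over literature bounds) with
the full model re-run per grid point. A parameter is *influential* when some
arm's NHB swings by ≥ 0.2 QALY. Because several parameters move only a
subset of arms, the reported direction is the sign of the largest-magnitude
per-strategy swing. Threshold finding scans a coarse grid for changes in the
NHB-optimal arm and bisects each crossing of the two competing arms' NHB
difference to a configurable tolerance, verifying each sub-interval label at
its mid-point; more than 8 crossings raises an error rather than truncating.
On the synthetic world 7/8 published direction signs reproduce; the
prevalence sign flips because the discounted lifetime cost of annual
follow-up per additional high-risk subject (≈ $8k ≈ 0.17 QALY at
$\lambda$) slightly exceeds that subject's expected down-staging gain at
this incidence level — a genuinely input-dependent sign.

**PSA.** Nine quantities are drawn independently per iteration: stage
utilities (Gamma, method of moments, censored at 1 — modelled on the utility
scale as stated rather than as disutilities), odds ratio (log-normal,
mean 6.00, sd 2.46), prevalence (Beta, 0.135/0.0675), both stage
distributions (Dirichlet with concentration `proportions × ESS`; the source
states only the mean proportions, so the effective sample size defaults to
100 — a bounded, mean-preserving choice), and the starting (age, sex) cell
from the population weights. Independent utility draws can transiently
violate the base-case stage ordering; the engine never relies on that
ordering. Per-iteration seeds derive from a counter so earlier iterations
are unchanged when the iteration count grows. The CEAF reports, at each
$\lambda$ on a $0$–$100{,}000$ grid, the arm with maximal *expected* NMB and
the fraction of iterations in which it attains the per-iteration maximum
(ties share credit equally).

**Internal validation.** The engine's projected all-cause survival and
cumulative GC incidence are compared with curves built directly from the
input tables by an independent compact recursion (pooled incidence,
usual-care staging, constant stage hazards) using the Mantel–Cox log-rank
statistic with hypergeometric variance; the statistic is cross-checked
against `survival::survdiff` in the tests. The life table alone is *not* a
valid mortality reference because the model adds GC excess deaths on top of
background (other-cause) mortality; against the two-table reference the
no-intervention arm fits with statistic ≈ 0 by construction, while
intervention arms show their genuine down-staging survival gain.

## Numerical choices and degenerate inputs

* Frontier: strategies sorted by cost (ties: higher effect, then name);
  strictly dominated removed first, then extended dominance until ICERs
  strictly increase; exact (cost, effect) ties collapse to one point. The
  optimum at $\lambda$ — the most effective frontier arm with ICER
  ≤ $\lambda$ — equals the argmax of NMB; the tests verify this against an
  exact enumeration oracle over all pairwise crossing $\lambda$s.
* `split_incidence` guards $q=0$, $OR=1$ and $p \to 1$ limits explicitly.
* Termination: the trace ends when ≥ 99% of the cohort has died or at age
  110, whichever first; remaining survivors simply stop accruing.
* Zero-hazard life tables, zero incidence and degenerate PSA distributions
  are all legal inputs, used by the test suite as closed-form limits.

## Known limitations

* Rounded league tables: when the frontier module is fed (cost, QALY) pairs
  rounded to 0.01 QALY, the selected optimum can flip whenever a
  full-precision ICER lies near $\lambda$; two of the twelve published
  reference subgroups exhibit exactly this artifact (the affected ICERs,
  $46{,}291$ and $30{,}753$, sit on opposite sides of $\lambda = 46{,}200$
  from their rounded counterparts $33{,}750$ and $51{,}700$), so 10/12
  reported optima — and 12/12 extended-dominance flags — reproduce from the
  printed pairs.
* The rare-disease approximation $q/(1-p+p\,OR)$ for the low-risk incidence
  is only 1%-accurate while $q\,(OR-1)$ is small; at $q = 0.005$,
  $OR = 21.5$ its own error is 1.4–2.7%, so the exact solver is checked
  against it only for $OR \le 6$.
* No lead-time/length-bias modelling, no partial compliance, no lesion
  regression, no correlation structure in the PSA, single currency-year.
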