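---
title: "Optimal case-control matching in registry data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal case-control matching in registry data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casematch)
```

## The problem

In a case-control study nested in a primary-care registry, each incident
case (here the motivating example is a cancer diagnosis in a 2010–2015
ascertainment window) must be compared with controls that were at risk
at the same time and resemble the case on everything except the exposure
under study. Most matching routines sample controls greedily and with
replacement; when controls are plentiful and several confounders must be
balanced, matching *without* replacement increases statistical
efficiency, but a naive sequential implementation can strand a case by
giving its only suitable control to an earlier, less constrained case.

`casematch` implements a deterministic, round-based assignment that
avoids this: candidates are expanded within exactly matched subsets,
ordered so each case sees its closest control first, and contested
controls are arbitrated in favour of the case with the smallest
remaining pool.

## The distance and the matching variables

Matching variables come in two kinds:

* **exact** variables (default: sex, practice, and the yearly contact
  group JCG — the requirement that the control consulted the GP in the
  case's index year, which also operationalises "at risk and under
  observation at the index date"). Cases and controls must agree
  perfectly; they define disjoint subsets and never enter the distance.
* **varying** variables (age; registry follow-up when `trimmed`; the
  comorbidity index when `varying`), allowed to differ within a caliper
  and contributing to the Rosenbaum-style distance between case $i$ and
  control $j$:
  $$D_{ij} = \sum_{k=1}^{p} \lvert x^1_{ik} - x^0_{ik}\rvert \, W_k ,$$
  with positive weights $W_k$ (default 1). The total distance
  $T = \sum_i D_{ij}$ over matched pairs summarises the quality of the
  whole matched sample.

In practice the algorithm does not rank candidates by the scalar
$D_{ij}$ but lexicographically — follow-up difference before age
difference by default, then the control's availability frequency, then
the control id. This mirrors how registry analysts express "follow-up
matters more than age" without committing to numeric weights; passing
`ordering_priority = "distance"` ranks by $D_{ij}$ itself, and the
weight vector is exposed for users who want a numeric trade-off.

Follow-up is matched on the registry entry year: `exact` requires the
same entry year, `trimmed` lets the control enter earlier (so it has at
least the case's follow-up, guarding against differential opportunity
for exposure recording). The comorbidity index (CI) — the number of
distinct chronic diagnosis codes registered up to the index year — can
be required equal (`exact`) or within a threshold (`varying`, default
±1: a case with 3 chronic diseases accepts controls with 2–4).

## The assignment algorithm

Pre-processing:

1. split cases and controls by the exact-variable combinations that
   contain at least one case (controls that fit no case key are
   dropped);
2. replicate every eligible control into every case's pool within its
   subset ("artificial observations"), keeping pairs that pass the age
   caliper, follow-up rule and CI rule;
3. annotate each row with `total_controls_per_case` (pool size) and
   `frequency_of_controls` (how many cases want this control);
4. sort by case, the priority differences, frequency, control id.

Then one **round** per requested control (1:n matching = n rounds).
Within a round: take the first (best) row per unserved case; controls
picked by a single case are assigned immediately; a control picked by
several cases goes to the case with the smallest pool (ties to the
smaller case id), the losers re-enter the next inner iteration; without
replacement, assigned controls are deleted everywhere and both counters
are recomputed before the next inner iteration — recomputing *inside*
the round, not once per round, is what makes "least pool" track the
actually shrinking pools. The inner loop ends when every case with a
non-empty pool has a control for this round; cases with exhausted pools
simply keep fewer controls. With replacement, duplicate selections are
all granted (a control may serve many cases but never the same case
twice) and only satisfied cases are removed.

The procedure is deterministic — every tie is broken by an id sort and
there is no randomness anywhere in the matcher — so reruns are
byte-identical.

### What "optimal" does and does not mean

The least-pool-first rule guarantees that a case whose pool contains a
single control receives it (unless two single-pool cases want the same
control, which no assignment could satisfy), and on instances whose
per-case pools are disjoint it provably attains the global minimum of
$T$ (each case simply takes its nearest controls). On general instances
global optimality of the sequential rule is *not* a theorem. The
package therefore ships an exact assignment oracle
(`min_total_distance_assignment()`, a subset dynamic program plus an
independent maximum-weight bipartite matching backend) and the test
suite measures the gap: on random dense instances with up to 8 cases
and 12 controls the sequential total is never below the exact optimum
at the achieved cardinality (it cannot be), equals it on all
disjoint-pool instances, and exceeds it on a minority of dense
instances. Users for whom the last fraction of $T$ matters more than
speed can use the oracle directly on small problems; the production
path is the sequential rule, whose run time scales linearly in the
candidate rows.

## Conditional logistic regression

Matched sets are analysed with conditional logistic regression: set $s$
with case covariates $x_{\text{case}(s)}$ contributes
$$\log \frac{\exp(\beta^\top x_{\text{case}(s)})}
  {\sum_{j \in s}\exp(\beta^\top x_j)},$$
which conditions away everything constant within a set (all matching
variables). `clr_fit()` maximises this by Newton–Raphson with
step-halving, declares convergence when the score norm drops below
`tol` (default 1e-8), reports Wald 95% intervals
$\exp(\hat\beta \pm 1.96\,\widehat{se})$ from the inverse observed
information, and *withholds* estimates (with a warning,
`converged = FALSE`) under separation or when no set shows within-set
covariate variation. Because each set contains exactly one case, no
tie-handling (Breslow/Efron) question arises. For 1:1 sets with a
binary exposure the estimate reduces to the classical discordant-pair
ratio $\hat\beta = \log(n_{10}/n_{01})$, which the tests verify
exactly, alongside agreement with an independent likelihood search and
with `survival::clogit`.

The scenario engine fits exposure-only models: confounding control is
the matching's job. Extra within-set covariates can be added through
the formula interface.

## The scenario grid

`build_scenario_grid()` crosses age calipers × follow-up mode × CI mode
× replacement arm. The default levels — calipers 0–5 years, follow-up
{exact, trimmed}, CI {none, exact, varying ±1}, both replacement arms —
give the canonical 72 scenarios (36 per arm). The six-caliper and
three-CI-level choices are the package's defaults for a registry-scale
sensitivity analysis; both are configurable. `run_scenarios()` runs the
full pipeline per scenario, records the matched-set census (how many
cases obtained 1, …, n controls), the odds ratio with its interval, and
isolates per-scenario failures instead of aborting the batch.

## The synthetic registry generator

`generate_registry()` emulates the registry features the matcher relies
on: practices, registry entry years (2000–2012), yearly GP contacts
(default rate 0.7 per year — a typical adult consultation rate),
chronic diagnosis codes, incident case status in 2010–2015 with the
index year forced to be a contact year, and antibiotic prescriptions.
Exposure follows
$\operatorname{logit} P(\text{exposed}) = \alpha +
\log(\text{OR}_{\text{true}}) \cdot \text{case} + \gamma \cdot \text{CI}$,
so the within-CI-stratum exposure odds ratio is exactly `true_or`
(default 1.5); case status likewise depends on CI (default log-odds 0.4
per disease, i.e. a per-disease OR of about 1.5, with the exposure-side
$\gamma = 0.5$) — making CI a genuine confounder whose neglect biases
the crude matched OR upward and whose balancing removes that bias, the
qualitative pattern the scenario grid is designed to expose.

Two deliberate simplifications keep the generating odds ratio exactly
interpretable:

* chronic codes onset only during 2000–2009 (conditions predating
  registry entry are back-registered, as GP registries do), so a
  subject's CI is identical at every admissible index year and
  independent of its entry year;
* exposed subjects always hold a prescription in their entry year, so
  the event-derived exposure ("any prescription up to the index year")
  coincides with the model-assigned flag whichever index year a control
  inherits.

What the generator does **not** emulate: day-level dates (everything is
year-resolved, as in the motivating registry), hospital/specialist data
streams, code-system semantics (codes are opaque labels), registration
delay, and time-varying exposure intensity. Passing tests on this
generator therefore validate the algorithmic and inferential machinery,
not the clinical realism of any particular registry.

`toy_fixture()` is a hand-built 4-case/9-control miniature in a single
exact subset whose correct assignment is known by manual trace; it
exercises both the contested-control and the single-eligible-control
branches.

## Numerical and validation choices

* All years are integers; age at index = index year − birth year.
* Ties anywhere are broken by ascending id; no RNG outside the
  generator, which takes a single integer seed and restores the global
  RNG state on exit.
* The exhaustive oracle refuses instances beyond 16 controls / 24 case
  slots; the bipartite backend transforms minimisation to maximum
  weight via $C - D_{ij}$ with $C$ large enough that maximum weight
  implies maximum cardinality first.
* Newton–Raphson caps steps by halving against the likelihood and
  treats $|\hat\beta| > 15$ as separation.
* Validation problem sizes, chosen to make Monte-Carlo error small
  while keeping the suite quick: 500 random matcher instances (≤8
  cases, ≤12 controls) against the exact oracle; 100+ random CLR
  datasets against a likelihood search (agreement within $10^{-4}$);
  parameter recovery on 200 replicate registries of 1200 patients
  (3 practices, case rate 0.08) matched 1:4 without replacement — the
  mean log-OR must sit within 3 Monte-Carlo standard errors of
  $\log 1.5$ (and of 0 in the null configuration), and the CI-balanced
  analysis must land closer to the truth than the CI-ignoring one.
  `scripts/acceptance.R` reruns a 100-replicate version of the same
  pipeline from scratch.

## Known limitations

* The sequential rule can exceed the exact minimum total distance on
  dense instances (measured, not hidden; see above).
* Candidate expansion materialises one row per eligible pair; with
  millions of controls and wide calipers this is memory-hungry —
  subsetting by exact variables is what keeps it tractable, so
  configurations without exact variables scale worst.
* Controls are drawn from never-cases only; a design in which future
  cases serve as controls before their diagnosis (incidence-density
  sampling) is not implemented.
* Wald intervals only; profile-likelihood or exact conditional
  inference is out of scope.
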