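# casematch

Optimal 1:n case-control matching for primary-care registry data, with
and without replacement of controls.

## The problem

Case-control studies nested in morbidity registries must pair each
incident case with controls that were comparable and under observation
at the case's diagnosis year (the *index year*). Common routines sample
controls greedily and with replacement; when controls are plentiful,
matching **without replacement** is statistically more efficient — but a
naive sequential pass can give a case's only suitable control away to
an earlier case. `casematch` implements a deterministic round-based
algorithm that guarantees a case with a single eligible control
receives it, and that each case gets its closest available control.

Cases and controls are matched

* **exactly** on sex, practice and the yearly contact group (the
  control must have consulted the GP in the case's index year), which
  splits the data into small independent subsets;
* **within calipers** on varying variables — age, registry follow-up
  (entry year: `exact` or `trimmed`), and the comorbidity index CI
  (count of distinct chronic diagnoses up to the index year: `exact`
  or within ±1) — which enter the pair distance

  D(i,j) = Σₖ |x¹ᵢₖ − x⁰ⱼₖ| · Wₖ,

  whose matched-sample sum T the assignment seeks to minimise.

Candidate pairs are ranked per case (follow-up difference, then age
difference, then how many other cases want the same control), one
control is assigned per case per round, and a control contested by
several cases goes to the case with the smallest remaining pool. The
matched sets are analysed by conditional logistic regression
(Newton-Raphson on the set-conditional likelihood), and a factorial
scenario engine reruns the whole pipeline over 72 matching
configurations (6 age calipers × 2 follow-up modes × 3 CI modes × 2
replacement arms) to show how the odds ratio moves as balance tightens.

A synthetic registry generator with a known conditional odds ratio, an
exact assignment oracle and a hand-traceable 4-case/9-control fixture
make every component testable without access to any real registry.

## Worked example

```r
library(casematch)

reg <- generate_registry(n_patients = 2000, seed = 42)  # true OR 1.5
reg
#> Registry: 2000 subjects (104 cases), 14006 contacts, 3039 diagnoses, 690 prescriptions

spec <- matching_spec(age_caliper = 2, follow_up = "trimmed",
                      ci = "varying", n_controls = 4)
co <- cc_match(reg, spec)
summary(co)
#> Matched case-control cohort (1:4, without replacement)
#>   cases matched   : 90 of 104
#>   controls used   : 251 unique (251 slots)
#>   total distance T: 1297
#>   unmatched cases : 14
#>   controls per matched case:
#> controls_1 controls_2 controls_3 controls_4
#>         20         12         25         33

clr_fit(is_case ~ exposed, matched_sets_data(co, reg))
#> Conditional logistic regression (matched sets)
#>   sets: 90 (57 informative)   converged: TRUE
#>   exposedTRUE  beta =  0.2676  OR = 1.307  95% CI [0.756, 2.259]
```

90 of 104 cases found at least one control under these tight
constraints (20 of them only one); the exposure odds ratio 1.31
[0.76, 2.26] is a single noisy draw whose interval covers the
generating value 1.5 — averaged over replicates the estimator centres
on it (see the methods vignette). The full sensitivity surface comes
from `run_scenarios(reg, build_scenario_grid())`, one row per scenario
with matching census, OR and confidence limits.

A thin command-line front end over the same functions is installed at
`system.file("cli", "casematch.R", package = "casematch")` with
subcommands `simulate`, `match`, `scenarios`, `report`.

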