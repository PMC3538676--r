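# forensicBN

Bayesian-network and closed-form evaluation of the forensic **database
search problem**: how strong is the evidence against a suspect who was
found by trawling a database of `n` DNA profiles drawn from a closed
population of `N` potential sources of a crime stain?

The package is for forensic statisticians, caseworkers and teachers who
need the canonical desk-scale calculations — posterior source
probabilities and the database-search likelihood ratio — with an auditable
dual computation path: every quantity is produced both by exact inference
on a small discrete Bayesian network and by the corresponding closed
formula, and the two are checked against each other (and, on small
instances, against a brute-force individual-level enumeration).

## The model

Person 1 (the suspect) of `N` equally suspected persons matches the crime
stain (`M1`); the other `n − 1` database members are excluded
(`X2 & … & Xn`). With random match probability `γ` and priors `Π_i`
(default `1/N`):

- island problem (no database):
  `P(H1 | M1) = Π1 / (Π1 + γ(1 − Π1))`
- database search (match + exclusions):
  `P(H1 | E_n) = Π1 / (Π1 + γ Σ_{i=n+1..N} Π_i)`
- exclusions only: `P(H1 | X2..Xn) = 1 / (N − n + 1)` (uniform priors)
- database-search likelihood ratio for the exclusion evidence:
  `LR_DB = (1 − γ)^{n−1} / [(1 − γ)^{n−1} (N − n)/(N − 1)] = (N − 1)/(N − n)`,
  independent of `γ`; equal to 1 at `n = 1` and unbounded at `n = N`.

Excluding database members always *strengthens* the case against the
matching suspect: the excluded members' prior mass is redistributed over
the survivors.

## Worked example

```r
library(forensicBN)

sc <- scenario(N = 100, n = 2, gamma = 0.01)

# island value: the suspect's match alone
island_posterior(sc)$posterior_suspect
#> [1] 0.5025126

# add the exclusion of the other database member: the case strengthens
rep <- run_analysis(run_config("db", N = 100, n = 2, gamma = 0.01,
                               suspect_matches = TRUE, others_excluded = TRUE))
rep$formula      # closed form
#> [1] 0.5050505
rep$network      # same value from the Bayesian network
#> [1] 0.5050505
rep$difference
#> [1] 0

# likelihood ratio of the exclusion evidence, N = 1000, n = 100
lr <- db_likelihood_ratio(scenario(N = 1000, n = 100, gamma = 0.01))
round(c(lr$numerator, lr$denominator, lr$ratio), 4)
#> [1] 0.3697 0.3331 1.1100
```

`0.5025` is the posterior that the suspect is the source given only his
match; it rises to `0.5051` once the second database member is excluded.
The likelihood ratio `1.11 = 999/900` says the exclusion evidence favours
"the suspect is the source" by exactly the population-coverage factor
`(N − 1)/(N − n)`, whatever `γ`.

A command-line wrapper lives in `inst/scripts/forensicbn.R`:

```sh
Rscript inst/scripts/forensicbn.R --mode db --N 100 --n 2 --gamma 0.01 \
    --suspect-matches --others-excluded --format text --percent
```

## Acceptance script

`scripts/acceptance.R` rebuilds every headline scenario from scratch with
the installed package — the island posterior, the two-member database
posteriors and predictives, the three-person sequential example, the
exclusion-only update and the likelihood-ratio components — and writes the
resulting numbers as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/database-search.Rmd` for the model assumptions, parameter
semantics, numerical choices and limitations.
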