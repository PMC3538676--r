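---
title: "Evaluating database hits: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating database hits: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forensicBN)
```

## The inference problem

A crime stain has profile $G_c$. A closed population of $N$ persons could
have left it; a priori each person $i$ is the source with probability
$\Pi_i$ (by default $1/N$). The profile occurs in persons other than the
true source with the *random match probability* $\gamma$. Person 1, the
suspect, is found to match ($M_1$). In the *database search* variant,
persons $1,\dots,n$ have profiles in a searched database and the trawl also
shows that persons $2,\dots,n$ do **not** match ($X_2\&\dots\&X_n$). The
question is how strongly the combined evidence
$E_n = M_1 \& X_2 \& \dots \& X_n$ supports "the suspect is the source"
($H_1$).

Three assumptions are built into every model here and are *not* tunable:
profiling is error-free (a true source matches with certainty, so an
observed non-match excludes a person outright), individuals are unrelated
(each non-source matches independently with probability $\gamma$), and
knowledge of one person's profile does not change the match probability of
another. Relaxations — typing error, kinship, subpopulation-corrected match
probabilities — are out of scope.

## The models

**Island model** (no database): by Bayes' theorem,
$$\Pi_1' = \Pr(H_1 \mid M_1) = \frac{\Pi_1}{\Pi_1 + \gamma(1-\Pi_1)}.$$

**Database search**: the exclusions have likelihood 0 under "another
database member is the source", $(1-\gamma)^{n-1}$ otherwise; the common
factor cancels, leaving
$$\Pi_1' = \Pr(H_1 \mid E_n)
  = \frac{\Pi_1}{\Pi_1 + \gamma \sum_{i=n+1}^{N} \Pi_i}.$$
Because the sum runs only over the unexcluded persons *outside* the
database, this is never smaller than the island value: excluding database
members strengthens the case against the matching suspect.

**Exclusion only** (before looking at the suspect's own profile): the
excluded members' prior mass is redistributed proportionally over the
survivors, giving $1/(N-n+1)$ under uniform priors.

**Likelihood ratio** for the exclusion evidence, comparing $H_1$ against
"someone else is the source":
$$LR_{DB} = \frac{\Pr(X_2\&\dots\&X_n \mid H_1)}
                 {\Pr(X_2\&\dots\&X_n \mid \bar H_1)}
          = \frac{(1-\gamma)^{n-1}}{(1-\gamma)^{n-1}\,\frac{N-n}{N-1}}
          = \frac{N-1}{N-n},$$
independent of $\gamma$: only the database's coverage of the population
matters. At $n=1$ it is 1 (no exclusions, no evidence); at $n=N$ the
denominator vanishes and the ratio is unbounded — `db_likelihood_ratio()`
reports this as `finite = FALSE` with `ratio = Inf` rather than as an
error, because it is the meaningful limiting case (everyone else excluded,
the suspect must be the source).

Each formula is mirrored by a Bayesian network
(`build_island_network()`, `build_two_member_db_network()`,
`build_general_db_network()` + `attach_summary_node()`) whose conditional
probability tables encode exactly the likelihoods above; posteriors are
obtained by exact enumeration over the full joint. `run_analysis()` always
computes *both* routes and aborts if they disagree beyond $10^{-9}$ — the
dual path is the package's core trust mechanism.

```{r}
sc <- scenario(N = 100, n = 2, gamma = 0.01)
db_posterior(sc)$posterior_suspect
net <- build_two_member_db_network(sc)
infer_posterior(net, "H", c(M1 = "match", X2 = "no-match"))$probabilities
```

## Parameters and their meaning

* `N` — size of the closed population of potential sources. Larger `N`
  dilutes the prior and weakens the posterior; the models require the
  population to be well defined (the "island").
* `n` — database size *including* the suspect, $1 \le n \le N$. Persons are
  indexed so that 1 is the suspect, $2..n$ the other database members,
  $n{+}1..N$ the outsiders.
* `gamma` — random match probability in $[0,1]$; typical forensic
  illustrations use 0.1–0.001. It drives the island posterior and the LR
  *components*, but cancels from the LR itself.
* `priors` — optional length-`N` vector $\Pi_i$ (default uniform). The
  grouped networks aggregate it as $\Pi_1$, $\sum_{2..n}$,
  $\sum_{n+1..N}$; the closed forms use the same aggregation, so both
  routes accept non-uniform priors even though the canonical worked
  examples are uniform.

## Design choices in genuinely open territory

* **Inference algorithm.** Exact enumeration of the joint (sum over all
  completions of the evidence). The networks have at most six nodes with at
  most six states, so the joint never exceeds a few thousand terms; clarity
  and auditability beat speed at this scale. Any optimization (variable
  elimination) would have to be bit-compatible to $10^{-12}$ and is not
  worth the surface area.
* **Root nodes vs folded constants.** Expanded network views show $N$, $n$
  and $\gamma$ as discrete root nodes with exemplary numeric states. Every
  builder supports both representations (`explicit_roots = TRUE/FALSE`,
  default folded): explicit roots enumerate the exemplary states plus the
  scenario's own values with a point-mass prior, and the test suite asserts
  both give identical posteriors to $10^{-12}$. Rows of a CPT that are
  unreachable under the point mass (e.g. $n > N$ combinations) are filled
  with uniform vectors so that network validity never depends on priors.
* **State ordering.** States keep insertion order and all distributions are
  returned keyed by label, never by index. Exclusion-type nodes put
  "no-match" first because the evidence of interest is the *non*-match.
* **Zero-probability evidence** is always an `impossible_evidence` error,
  never a silent renormalization: conditioning the $n = N$ network on "all
  others excluded" together with "another database member is the source"
  must fail loudly.
* **Tolerances.** CPT columns must sum to 1 within $10^{-9}$; agreement
  between the closed-form, network and oracle routes is asserted at
  $10^{-12}$; the runner's formula/network audit trips at $10^{-9}$.
  Values are rounded (half-even, via `round()`) to the conventional 4–6
  decimals only at the reporting layer; internal math is full precision.
* **Degenerate scenarios.** $n = N$ retains the "outside the database"
  state with prior 0 so CPT shapes are scenario-independent; $n = 1$ makes
  the aggregate exclusion node vacuous (the empty product
  $(1-\gamma)^0 = 1$ under every source hypothesis).
* **Serialization.** Networks round-trip through JSON with CPTs keyed by
  "|"-joined parent state labels; root nodes use the sentinel key `"."`
  because an empty JSON object key is not portable. Probabilities are
  written with 17 significant digits so round-trips are lossless.

## What the fixture generator emulates — and what it does not

`generate_fixtures()` draws random scenarios with $N \in [2, 12]$,
$n \in [1, N]$, $\gamma \in \{0.5, 0.1, 0.01, 0.001\}$ and occasional
(≈30%) non-uniform priors. The small-$N$ cap exists because each fixture is
validated against the individual-level oracle (`enumerate_joint()`), whose
table has $N \cdot 2^n$ rows; 12 keeps an exhaustive check instantaneous
while still covering every structural regime (no database, partial
coverage, full coverage). The fixtures are *mathematical* scenarios, not
realistic casework: real populations are far larger, match probabilities
for full DNA profiles are far smaller, and real databases are not simple
random subsets. A green equivalence suite therefore establishes that the
three computational routes implement the same model exactly — it says
nothing about whether that model fits a given case (relatedness,
laboratory error and search-dependent priors are explicitly outside it).

## Known limitations

* No kinship/subpopulation correction of $\gamma$; no typing error.
* The grouped networks do not expose per-individual $X_i$ nodes; the
  disaggregated view lives in the oracle module only and is capped (by
  default) at $N \le 12$.
* Non-uniform priors are aggregated into the three proposition groups;
  person-level posteriors under non-uniform priors are available only
  through the oracle.
* Approximate inference, CPT learning and continuous nodes are non-goals.
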