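---
title: "Federated analysis under active disclosure control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated analysis under active disclosure control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsdc)
```

## The setting

`fedsdc` simulates a client–server federated-analysis platform in which
microdata never leave their holding site. Each site is a `ds_node`: an
immutable snapshot data frame plus an account table, user-specific data
views, a disclosure-settings vector, and an append-only audit log. The
analyst's client logs into every site, broadcasts *assign* requests (which
create derived objects server-side and return only a status message) and
*aggregate* requests (which return low-dimensional statistics after
disclosure checks). Network transport is deliberately out of scope: nodes
are in-process objects, which makes every protection layer directly
testable. The trust model is the usual one for such platforms: the analyst
is authenticated but potentially curious or adversarial; the custodian
controls all thresholds; protection reduces the *likelihood* of disclosure
rather than guaranteeing impossibility.

## The invocation flow

Every request passes through a single entry point, `dispatch()`, which runs
the stages in order: syntactic validation (function registry membership,
privacy-level whitelist, kind agreement, string-length and character-set
filters on every argument, all failures reported together), semantic checks
(symbols resolve, types match, variables inside the user's view),
pre-execution disclosure controls, execution, and a post-execution output
check. Failures at any stage return a typed error whose message is drawn
from a fixed catalogue with no interpolated values, so an error message can
never leak data — in particular, a refused subset reveals only that the
threshold was not met, never the attained size. Exactly one audit event is
appended per dispatch, whatever the outcome, so the custodian's log is a
complete command record.

The permitted character set for string arguments is a single documented
constant: letters, digits, space, and `. _ , ( ) = < > ! & | + - * / ~ ' "`.
This covers names, comparison predicates and model formulas while excluding
the characters that enable command injection (`;`, backtick, `$`, `@`, `#`,
backslash, braces, brackets, control characters). Name-like argument slots
use the short length limit; predicate/formula slots use the long one —
names are short by nature, formulas need room.

## Disclosure parameters

All thresholds live in one settings vector, set by the custodian and
readable (but not writable) by the analyst:

| field | config key | default | unit / domain |
|---|---|---|---|
| `tab_threshold` | `nfilter.tab` | 3 | min count in a non-empty cell; non-negative integer |
| `subset_threshold` | `nfilter.subset` | 3 | min subset rows; positive integer |
| `glm_ratio` | `nfilter.glm` | 0.33 | max parameters per observation; (0,1) |
| `string_max` / `string_short_max` | `nfilter.string(Short)` | 80 / 20 | characters |
| `levels_density` / `levels_max` | `nfilter.levels.*` | 0.33 / 40 | levels per observation; absolute levels |
| `knn_min` | `nfilter.kNN` | 3 | min neighbourhood size |
| `noise_min_fraction` | `nfilter.noise` | 0.25 | noise variance as fraction of data variance |
| `privacy_level` | `datashield.privacyControlLevel` | `banana` | blocked-function mode |

Interpretation choices where the rules admit more than one reading:

* **Empty cells never trigger the cell rule.** A zero count reveals only
  absence; a small positive count points at identifiable individuals. The
  exhaustive 2×2 oracle test pins this behaviour.
* **The two levels bounds are disjunctive** — either alone blocks. Blocking
  on the union is the stricter of the two readings and is what a custodian
  would expect of a guard rail.
* **Empty subsets are blocked** by a literal reading of "fewer than the
  threshold"; an empty subset arguably reveals only a zero count, but
  consistency with the subset rule costs little.
* **Fractional boundaries fail safe**: comparisons against `ratio × N` use
  a 1e-12 tolerance resolved toward blocking.
* **The model-dimension rule applies per site** against that site's own N; a
  federated model must pass everywhere. Whether the pooled N should also be
  checked is unspecified; per-site is the stricter and more local reading.
* **Profile overrides only tighten.** A user profile may carry its own
  parameter values and privacy level, but they are applied only where at
  least as strict as the site's (for the privacy level: only if its blocked
  set covers the site's). Site-versus-profile precedence is otherwise
  undefined, and a profile that could loosen site policy would invert the
  custodian's authority.

The four privacy levels carry fixed blocked-function lists (`permissive`
blocks nothing; `avocado` blocks the fourteen subsetting/difference-attack
functions; `banana` the eight inference-attack functions — seeded random
draws, sequence generation, seed control; `non-permissive` their union plus
`repDS`). The three non-empty lists are treated as authoritative verbatim
sets rather than deriving one from the others; the union relation is
asserted in tests rather than assumed. Every blockable name is present in
the function registry (as an executable function or a stub) so a block is
always resolvable.

## The federated GLM

For canonical-link gaussian, binomial and poisson models, site *s* returns
at the current β only its score vector `U_s = X_s'(y_s − μ_s)`, information
matrix `I_s = X_s' W_s X_s`, deviance contribution and complete-case count.
Score and information add across independent observations, so the client's
Newton step `β ← β + (Σ I_s)⁻¹ (Σ U_s)` reproduces pooled IRLS exactly;
this additivity is the entire mathematical content of the
federated-equals-pooled property, and the test suite verifies it against an
independent `stats::glm()` fit on the concatenated data (tolerance 1e-6 on
coefficients and standard errors, 20 seeds × 3 families at 3 sites × 200
observations; partition invariance across 1/2/5-site splits at 1e-8).

Numerical choices: start at β = 0; stop when the relative change in total
deviance is below `tol = 1e-8` or after `max_iter = 25` iterations
(conventional IRLS defaults); a singular summed information matrix raises a
typed error; non-convergence returns the result with `converged = FALSE`
rather than failing. Standard errors come from `(Σ I_s)⁻¹`, scaled for the
gaussian family by the moment dispersion estimate `deviance / (N − p)` so
they are comparable with a weighted-least-squares analysis; binomial and
poisson use dispersion 1. Missingness is handled complete-case per request
within each site, with only the aggregate missing count reported. The
result object contains coefficients, standard errors, the p×p covariance,
deviance, N, and the iteration trace (β and deviance per iteration — p+1
numbers per step, non-disclosive); it never contains fitted values,
residuals or linear predictors.

Contingency tables failing the cell rule are returned *suppressed* — flag
and dimension names, no counts — and a suppressed share blocks pooling
entirely: pooling the remaining sites would let the analyst recover the
suppressed counts by subtraction from a pooled table obtained elsewhere.
Univariate summaries travel as sufficient statistics `(N, Σx, Σx²,
n_missing)`; the per-site minimum N reuses the subset threshold, since no
dedicated filter exists for summaries and a tiny summary is as disclosive
as a tiny subset.

## Obfuscation

`knn_centroid_obfuscate()` replaces each point with the arithmetic centroid
of itself plus its k−1 nearest other points. Including the point itself
makes the neighbourhood well defined for k = 1 and yields the clean k = n
limit (every output equals the global centroid, tested exactly). Distances
are computed on per-dimension standardized coordinates (each dimension
divided by its standard deviation; zero-variance dimensions pass through
unscaled) so axis units cannot dominate, while centroids are reported on
the original scale; whether deployed systems standardize first is not
something the method's definition fixes, so it is recorded here as this
package's choice. Ties break by lowest input index, making the map fully
deterministic and permutation-equivariant on tie-free inputs.

`gaussian_noise_obfuscate()` returns `x + e` with `e ~ N(0,
f·var(x))`, drawn under an isolated RNG state from the request seed. A
constant vector is returned unchanged (the mandated variance is zero). The
analyst may choose the seed only when the active privacy level does not
block seed control; otherwise the node draws its own seed and records it in
custodian-side metadata only — an analyst-chosen seed would allow exact
noise subtraction.

## Audit and attack detection

The log is append-only with strictly increasing sequence numbers and an
injectable clock (tests use a fixed clock, so replayed workloads are
bit-identical). Export is custodian-only, as NDJSON (one event per line)
for external tooling. Two detectors are implemented, both post hoc:

* **Difference attack**: two executed subsets of the same parent by the
  same user whose custodian-recorded sizes differ by exactly one, each
  later queried with an aggregate. The size-difference-of-one signature is
  the only one claimed; predicate-refinement analysis would require
  interpreting predicate text, which the platform deliberately treats as
  opaque.
* **Seed abuse**: any seed-setting request — executed *or blocked* —
  preceding a noise-obfuscation request in the same session. Blocked
  attempts still matter: they reveal intent.

Detector calibration is validated on generated workloads
(`simulate_workload()`): one-row-difference constructions must always
alert; benign nested subsets with size gaps ≥ 2 must never alert (100
workloads each in the acceptance checks). One-step disclosure is
structurally undetectable from a command log — a single malicious request
is indistinguishable from valid analysis — and the suite documents this
negative property with a single-request scenario producing no alert.

## Synthetic data

`generate_multisite()` draws horizontally partitioned cohorts: independent
covariates (normal, Bernoulli, categorical), a linear predictor with known
coefficients and optional per-site intercept shifts, and a gaussian,
binomial or poisson outcome. Per-site RNG streams are derived from the
master seed, so adding a site never perturbs existing sites' data.
Intercept-shift-only heterogeneity keeps the pooled coefficient vector the
estimand, which is what the equivalence and recovery tests need. Optional
missing-completely-at-random item non-response (used at 3% in the demo
study) emulates the incomplete snapshots real cohorts hold.

What it does *not* emulate: covariate dependence, confounded site effects,
informative missingness, measurement error, or categorical covariates in
the outcome model. Passing tests therefore demonstrate the correctness of
the *mechanics* (filters, pooling algebra, detectors) under clean
conditions, not robustness of inference on messy real data.

`pseudonymize()` replaces identifiers with fixed-length keyed-MD5 hex
pseudonyms (key applied as a prefix before hashing) and returns the linkage
map as a separate object, mirroring the practice of storing linkage apart
from data; `coarsen_date()` truncates ISO dates to month or year.

## Problem sizes

The stock study designs are: 3 sites × 200 observations with three
covariates for the equivalence checks (20 seeds per family in the test
suite, 5 in the acceptance script); N = 5000 across three sites for
logistic parameter recovery (each coefficient within 3 reported standard
errors of truth); n = 10000 for the noise-variance band [0.23, 0.27]
(chi-square concentration at that n); 100 + 100 seeded workloads for
detector calibration; and a 300-participant three-site demo for the
end-to-end payload-hygiene scan.

## Known limitations

* Predicates are restricted to `variable op constant` combined with `&`
  and `|` (no parentheses, no variable–variable comparisons): small enough
  to verify, expressive enough to construct every attack scenario the
  detectors must recognize.
* The GLM handles numeric covariates and canonical links only; factor
  expansion, interactions and non-canonical links are out of scope.
* Detection is post hoc; nothing blocks a detected multi-step pattern in
  real time.
* In-process simulation cannot exercise transport-layer properties
  (encryption, firewalling, middleware authentication); those belong to the
  infrastructure this package abstracts away.
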