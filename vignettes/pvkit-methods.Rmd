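---
title: "Methods: signal detection, onset hazards and risk modelling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal detection, onset hazards and risk modelling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pvkit implements the standard post-marketing pharmacovigilance workflow on
spontaneous adverse-event reports in the FAERS quarterly ASCII dialect, plus a
synthetic-report generator with planted ground truth so that every stage of
the workflow can be validated without access to the real database. This
vignette records the models, the parameters that matter, the numerical
choices, and what a passing test does and does not establish.

## The data model and deduplication

A spontaneous report is one case (a `CASEID`) that may exist in several
versions (`PRIMARYID`s): follow-up reports, retransmissions from different
sources. Analyses must count patients, not transmissions, so ingest retains
exactly one version per case: the one with the latest receipt date
(`FDA_DT`), ties broken by highest case version, then highest primary id
(numeric comparison). Rows with unparseable receipt dates lose to any dated
row. This chain makes deduplication a pure function of the record set —
idempotent and invariant to input row order — which is what the tests assert.
No cross-case patient linkage is attempted: spontaneous-report databases
carry no patient key, so "one report per patient" is operationalized as one
report per case id.

Dates arrive as `YYYYMMDD`, `YYYYMM` or `YYYY`. The default `strict_day`
policy parses only full dates and turns partial ones into missing values,
because time-to-onset needs day resolution; a `pad_first` policy (pad to the
first of the month/year) is available for analyses that only need calendar
coverage. A malformed date never fails a row.

Case finding uses a Standardized MedDRA Query: a report is a target case iff
its reaction set intersects the scope's preferred-term (PT) list,
case-insensitively after trimming. The package ships an *illustrative*
pancreatitis PT list (`inst/extdata/smq_acute_pancreatitis.txt`); licensed
MedDRA SMQ content is not reproduced, and the list is an editable text input
precisely so that users with a MedDRA license can drop in the real scope.
Counting is report-level (a report with three pancreatitis PTs is one case);
the ingest log also records the PT-occurrence tally because published counts
are sometimes ambiguous between the two conventions.

## Disproportionality statistics

For a drug–event pair the deduplicated universe partitions into the familiar
2×2 table: `a` (drug and event), `b` (drug, other events), `c` (other drugs,
event), `d` (neither), with `N = a+b+c+d`. Drug exposure means the drug
appears with the primary-suspect (PS) role. Four statistics are computed:

* **ROR** `= ad/(bc)`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, with the Pearson
  statistic `χ² = (ad−bc)²N/[(a+b)(c+d)(a+c)(b+d)]`;
* **BCPNN information component**: the posterior-shrunken
  `E(IC) = log₂[(a+γ₁₁)(N+α)(N+β)/((N+γ)(a+b+α₁)(a+c+β₁))]` with
  `γ = γ₁₁(N+α)(N+β)/[(a+b+α₁)(a+c+β₁)]`, variance `V(IC)` as the standard
  three-term expression, and `IC025 = E(IC) − 2·√V(IC)`. The multiplier is
  exactly 2 standard deviations (the conventional published form), not a
  97.5% normal quantile. Priors default to `α₁=β₁=γ₁₁=1`, `α=β=2`.
* **EBGM**, implemented *as conventionally printed in this strand of the
  literature*: the relative reporting ratio `aN/[(a+c)(a+b)]` with one-sided
  lower bound `EBGM05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))`. This is not
  the full MGPS empirical-Bayes gamma-mixture shrinkage estimator; published
  tables produced by MGPS software will not reconcile exactly with this
  formula, and the divergence is deliberate and documented rather than
  hidden.

A pair is a **signal** iff all four per-algorithm criteria hold
simultaneously: `a ≥ 3` and ROR lower CI > 1; `PRR ≥ 2`, `χ² ≥ 4`, `a ≥ 3`;
`a ≥ 3` and `IC025 > 0`; `a > 0` and `EBGM05 > 2`. All cutoffs live in
`signal_thresholds()` so sensitivity analyses never touch code.

Numerical choices: when any cell is zero, a Haldane–Anscombe 0.5 continuity
correction is applied to all four cells for the ROR/PRR/EBGM point and
interval computations only (the BCPNN is already regularized by its priors;
the χ² keeps the raw cells), and the row is flagged `zero_corrected`. A table
with an empty margin has no χ² information and gets `χ² = 0`, `p = 1`. Raw
p-values come from the χ² statistic on 1 df (upper tail) — the literature
rarely states its p-value source, so this assumption is explicit here —
and multiplicity adjustment across all scanned pairs defaults to
Benjamini–Hochberg (Bonferroni available); "adjusted p" columns in published
tables typically leave the method unstated, so BH is a recorded default, not
a claim of equivalence. Cell arithmetic is done in doubles: the χ²
denominator overflows 32-bit integers at realistic database sizes.

Stratified scans re-run the same machinery within demographic bins — by
default sex (male/female), age at 65 years, weight at 80 kg, the
conventional cutpoints for this literature. Bins are half-open `(lo, hi]`
intervals and must be disjoint; reports missing the stratifying variable are
excluded from that stratification only.

## Time to onset and the Weibull shape test

Time-to-onset is event onset minus the start of PS-drug therapy, in days;
when several therapy episodes exist the earliest dated start anchors the
latency (a single conservative rule). Reports missing either date are
excluded and counted, as are non-positive differences (a 0-day onset cannot
be distinguished from a data error at day resolution). There is no censoring
model: only observed onsets are analyzed, so the fitted distribution
describes reported latencies, not a survival process.

The two-parameter Weibull is fit by maximum likelihood with the shape
profiled out: given shape `β`, the scale MLE is `α(β) = (mean xᵢ^β)^{1/β}`,
and the profiled score in `β` is strictly decreasing, so a bracketed
root-finder starting from the method-of-moments estimate is deterministic
and cannot converge to a non-optimum. Samples are pre-scaled by their
geometric mean to keep `x^β` in floating-point range (the fit is
scale-equivariant, and the tests check that property). 95% CIs are Wald
intervals on the log-parameters via the observed information at the MLE —
the CI method is rarely stated in published tables, so it is recorded here
as a choice. Below 30 onsets the fit is returned with a warning rather than
refused.

The hazard classification reads the shape interval: **wear-out** failure
(risk increasing with time on drug) iff `β > 1` with the whole CI above 1;
**early** failure iff `β < 1` with the whole CI below 1; **random** (roughly
constant hazard) otherwise. Boundary cases where the CI touches 1 classify
as random.

## Logistic risk model, nomogram, ROC

Among a drug's PS reports, the event flag is modelled by maximum-likelihood
logistic regression. Encodings follow the field's conventions: age ≤65 vs
>65 (reference), weight >80 kg vs ≤80 (reference), female vs male
(reference), plus 0/1 indicators per concomitant drug (any non-PS role row)
and per comorbidity PT. Rows missing a modelled covariate are dropped and
counted. Variable selection uses the common two-stage rule — univariable
screening at p < 0.05 feeds the multivariable model — recorded as an
assumption (published tables show both stages but rarely state the rule);
the cut is configurable, and "all covariates" is a valid setting. Degenerate
covariates and complete separation raise errors naming the covariate; the
pipeline orchestrator degrades per covariate (drops what cannot be fit and
logs it) so one sparse indicator does not abort a whole run.

The nomogram is a pure rescaling of the fitted coefficients: within each
covariate the smallest level scores 0 points, the covariate with the widest
coefficient span gets exactly 100 points, and the intercept plus the
per-covariate shifts become a base linear predictor. Total points therefore
map through the inverse logit *exactly* onto the model's fitted probability
(an identity the tests check to 10⁻⁹), and the point assignment is invariant
to jointly rescaling all coefficients. AUC is the rank-based concordance
probability with half credit for ties, computed on the model's own fitted
probabilities — an *apparent* (resubstitution) AUC, deliberately labelled as
such; no optimism correction is attempted.

## The network-toxicology tail

Upstream discovery steps (co-expression module detection, target prediction,
enrichment, docking) are external tools in this workflow; pvkit consumes
their *outputs* — plain gene lists and a STRING-style edge list — and
implements only the computable core: exact set intersection after
uppercase-trim normalization (no alias resolution, which would need an
external mapping resource), confidence-floor edge filtering (default 0.15,
the permissive STRING cutoff; 0–1000-scaled scores are auto-detected and
divided by 1000), self-loop removal, undirected duplicate collapse keeping
the higher score, and degree-centrality hub ranking. Ties in degree are
broken lexicographically — the upstream plugin ecosystem leaves tie order
unspecified, so a documented deterministic rule is preferable to silent
instability. Published hub identities and overlap counts depend on external
database versions and are explicitly not reproduction targets.

## The synthetic-report generator

`simulate_faers()` draws a full five-table dataset from a stated world:

* one PS drug per report, uniform over the vocabulary; a Poisson number
  (mean 1) of concomitant role-C drugs;
* event indicators per PT, with the planted rate ratio multiplying the
  **background reporting odds** (`p = plogis(qlogis(bg) + log(RR))`, default
  background 0.01). On the odds scale the planted ratio is exactly the
  estimand of the downstream reporting odds ratio, which is what makes
  "planted-RR recovery" a well-posed test; for rare events this is
  indistinguishable from multiplying the probability itself (the two differ
  by a factor `(1−p₀)/(1−p₁) ≈ 1+O(bg)`). Covariate effects
  (`risk_effects`) shift the same log-odds scale using the *true* covariate
  values, so the planted log-odds ratio is exactly what a correctly
  implemented logistic stage should recover;
* demographics from categorical mixes with explicit missingness: defaults
  emulate the large unknown fractions typical of spontaneous reports (10%
  missing sex, 40% age, 50% weight; observed ages concentrated in 18–65,
  observed weights in 50–100 kg). Missingness masks recording; the true
  value still drives any planted covariate effect;
* Weibull onset latencies (default scale 900 days, shape 1 — the
  random-failure regime reported for the antipsychotic/pancreatitis pairs
  this design emulates), rounded up to whole days so every planted latency
  is at least 1 and survives the date round-trip exactly; event date =
  therapy start + latency; reports without events get no event date;
* duplicates: with configurable probability a case is re-emitted verbatim
  under a new primary id, version 2 and a receipt date 30–400 days later,
  which makes the deduplication rule's correctness decidable against truth;
* a single seeded generator with a documented draw order; the same config
  yields byte-identical tables.

What the generator does **not** emulate: free-text drug-name noise and
ingredient mapping, MedDRA hierarchy beyond a flat PT vocabulary, reporting
dynamics over calendar time, correlated reactions within a report, and
event-dependent missingness. A green planted-recovery test therefore
establishes the *statistical machinery* end to end (ingest → dedup → 2×2 →
four algorithms → decision), not robustness to real-world name dirt.

Null calibration of the joint criteria is checked on multinomial
independence tables with a 5% drug share and 1% event share per 10⁴ reports
— shares chosen to mirror the planted-signal world — where the joint
four-algorithm false-positive rate must stay at or below 7%; in practice the
`a ≥ 3` gates and the conjunction push it far lower.

## Known limitations

* EBGM is the printed relative-reporting-ratio form, not MGPS shrinkage;
  IC credible intervals by Monte Carlo are out of scope.
* No censoring or mixture hazards in the onset model.
* Exact replication of published whole-database tables is not a target: the
  printed statistics in this literature are frequently not mutually
  consistent with their own printed marginals, and desk-scale synthetic
  worlds cannot reproduce database-scale counts. Validation is by oracle
  identity and planted-truth recovery instead.
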