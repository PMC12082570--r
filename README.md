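# pvkit — pharmacovigilance signal detection for spontaneous report data

Spontaneous adverse-event reporting systems (the FDA's FAERS being the
canonical example) collect millions of unverified drug–event reports. Whether
a drug is disproportionately co-reported with an event — say, an atypical
antipsychotic with acute pancreatitis — is asked with 2×2 disproportionality
statistics; when a report first appears matters for onset hazards; and
demographics and co-medications modulate risk. pvkit packages that whole
workflow for R users, together with a synthetic-report generator with planted
ground truth so every stage can be validated without downloading the real
database.

**Who it's for:** pharmacoepidemiologists and biostatisticians running
signal-detection studies on FAERS-dialect quarterly extracts, and method
developers who need a testable, deterministic reference implementation.

## What it computes

For each drug–event pair, with the deduplicated report universe partitioned
into the 2×2 table (a, b, c, d; N = a+b+c+d):

* **ROR** = ad/bc, 95% CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))
* **PRR** = [a/(a+b)]/[c/(c+d)] with Pearson
  χ² = (ad−bc)²N/[(a+b)(c+d)(a+c)(b+d)]
* **BCPNN**: E(IC) = log₂[(a+γ₁₁)(N+α)(N+β)/((N+γ)(a+b+α₁)(a+c+β₁))],
  IC025 = E(IC) − 2·√V(IC), priors α₁=β₁=γ₁₁=1, α=β=2
* **EBGM** = aN/[(a+c)(a+b)] (relative reporting ratio),
  EBGM05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))

A pair is a **signal** iff all four criteria hold: a≥3 & ROR lower CI > 1;
PRR≥2 & χ²≥4 & a≥3; a≥3 & IC025 > 0; a>0 & EBGM05 > 2. P-values (χ², 1 df)
are Benjamini–Hochberg adjusted across the scan.

Around that core: one-report-per-case deduplication (latest FDA_DT, then
highest version, then highest primary id), SMQ narrow/broad case finding,
demographic stratification (sex; age at 65 y; weight at 80 kg), Weibull
time-to-onset fitting with the shape-parameter hazard classification
(early / random / wear-out failure), univariable→multivariable logistic risk
modelling with an exact nomogram point scaling and rank-based AUC, and
gene-set intersection plus degree-centrality hub ranking on a STRING-style
edge list. `vignettes/pvkit-methods.Rmd` documents every model and numerical
choice.

## Worked example

Simulate a 20,000-case world where one drug carries a planted reporting odds
ratio of 10 against a pancreatitis preferred term (background reporting rate
1%, onset latencies Weibull with scale 900 days and shape 1), round-trip it
through the FAERS ASCII dialect, and scan:

```r
library(pvkit)
m <- matrix(1, 10, 10); m[1, 1] <- 10
cfg <- sim_config(n_cases = 20000,
                  drugs = c("OLANZAPINE", sprintf("DRUG_%02d", 1:9)),
                  events = c("Pancreatitis acute", sprintf("PT_%03d", 1:9)),
                  background_rate = 0.01, signal_matrix = m,
                  duplicate_rate = 0.1,
                  tto_params = list(scale_days = 900, shape = 1), seed = 1)
ds <- simulate_faers(cfg)
dir <- tempfile(); write_faers_tables(ds, dir)
fd <- deduplicate_reports(as_case_reports(read_faers_tables(dir)))

smq <- smq_definition("Acute pancreatitis", "Pancreatitis acute")
res <- scan_signals(fd, smq = smq)
res[1:3, .(drug, a, ror, ror_lo, ror_hi, chi2, ic025, ebgm05, signal, p_adjusted)]
#>          drug     a    ror ror_lo ror_hi   chi2 ic025 ebgm05 signal p_adjusted
#> 1: OLANZAPINE   207 11.330  9.230 13.908 825.37  2.13  4.492   TRUE  1.65e-180
#> 2:    DRUG_04    26  0.641  0.430  0.957   4.80 -1.14  0.479  FALSE   2.85e-02
#> 3:    DRUG_06    24  0.594  0.392  0.900   6.18 -1.26  0.440  FALSE   1.44e-02
```

The planted drug is the only joint signal: 207 of its reports carry the
event, the ROR interval (9.2–13.9) covers the planted 10, and all four
algorithm flags are true — the two runner-up pairs fail every criterion.
Onset analysis on the flagged reports recovers the planted latency
distribution and classifies the hazard as constant over time:

```r
flags <- flag_event_cases(fd, smq)
fit_weibull(compute_tto(fd, "OLANZAPINE", flags))
#> <weibull fit> n=207  alpha=914.95 (786.74-1064.06)  beta=0.951 (0.856-1.057)
#>   hazard over time: random failure type; median TTO 665 days (IQR 274-1317)
```

The shape CI spans 1 (random failure): events keep occurring at a roughly
constant rate over time on drug, so the scale (≈900 days, as planted) rather
than an early-onset window describes the latency.

`run_faers_pipeline(config, out_dir)` runs every stage on a directory of
dialect files and writes per-stage CSV/JSON outputs plus a reproducibility
manifest; `make_report(out_dir)` renders a summary document. A thin CLI
wrapper lives at `inst/cli/pvkit.R`.

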