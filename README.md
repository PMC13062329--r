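# neurovigil

Pharmacovigilance analysis of **neurological immune-related adverse
events (n-irAEs)** reported for **immune checkpoint inhibitors (ICIs)**
in spontaneous-report databases distributed in the FAERS ASCII dialect.

Spontaneous-report databases such as the FDA Adverse Event Reporting
System collect millions of suspected drug–event reports. Because there
is no denominator of treated patients, associations are screened by
*disproportionality*: for an exposure–event pair, the 2×2 table of
deduplicated reports

|                | event | no event |
|----------------|-------|----------|
| **exposed**    | a     | b        |
| **not exposed**| c     | d        |

yields the **reporting odds ratio**

```
ROR = (a/c) / (b/d) = ad / bc
SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)
95% CI     = exp( ln ROR ± 1.96 · SE )
```

A pair is flagged as a signal when **a ≥ 3 and the lower 95% confidence
bound (ROR₀₂₅) exceeds 1** (both strict). The package implements the
full pipeline around this statistic for the ten target ICIs
(anti-PD-1: pembrolizumab, nivolumab, cemiplimab, tislelizumab,
dostarlimab, toripalimab; anti-PD-L1: atezolizumab, avelumab,
durvalumab; anti-CTLA-4: ipilimumab):

- **`read_quarter()`** — quarterly `$`-delimited DEMO/DRUG/REAC/OUTC/
  INDI/THER tables plus deletion lists, with lenient typed coercion and
  orphan-row accounting;
- **`dedup_reports()` / `apply_deletions()`** — the FDA-recommended
  rule: per CASEID keep the largest FDA_DT, ties to the largest
  PRIMARYID; then drop cases named on any quarter's deletion list;
- **`normalize_drug_name()` / `exposure_profiles()`** — synonym-
  dictionary normalization of verbatim drug strings and suspect-role
  (PS/SS) exposure classification, including monotherapy and
  combination status;
- **`map_pt()` / `event_profiles()`** — PT → HLGT → SOC hierarchy
  mapping; nervous-system events are the PTs under the "Nervous system
  disorders" SOC;
- **`summarize_cohort()`** — the cohort description table (sex, age,
  year, reporter, country, seriousness, outcomes, indications, time to
  onset);
- **`signal_screen()`, `stratified_screen()`, `monotherapy_screen()`,
  `combination_screen()`, `rank_and_select()`** — ROR screening at PT
  and HLGT level, by sex/age stratum, under monotherapy restriction,
  and for ICI + partner-drug combinations;
- **`synth_config()` / `synth_generate()`** — a synthetic-data
  generator that emits FAERS-dialect quarterly packages with planted
  disproportionality signals, duplicate case versions, deletion lists,
  drug-name variants and partial dates, plus a ground-truth ledger;
- **`run_pipeline()`** — one deterministic, audited run producing
  `table1.csv`, five signal CSVs and a JSON manifest.

The shipped drug dictionary and terminology table are license-free
synthetic slices sufficient for every computation in the package; they
stand in for the licensed WHO Drug and MedDRA dictionaries.

## Worked example

```r
library(neurovigil)

# a single disproportionality test
fit <- ror_test(10, 90, 100, 9900)
fit
#> Reporting odds ratio test
#>   a=10 b=90 c=100 d=9900
#>   ROR 11.000, 95% CI [5.556, 21.779], signal: yes

# a synthetic study: two quarters, five planted signals
cfg <- synth_config(n_reports = 3000, seed = 7,
  planted_signals = default_planted_signals() |>
    dplyr::mutate(n_exposed = c(300, 280, 160, 120, 80)))
synth_generate(cfg, "faers_in")
manifest <- run_pipeline("faers_in", "faers_out")
str(manifest$counts)
#> List of 9
#>  $ reports_in                : int 3214
#>  $ removed_as_duplicate      : int 214
#>  $ removed_as_deleted        : int 30
#>  $ reports_kept              : int 2970
#>  $ ici_exposed_reports       : int 925
#>  $ nirae_reports_report_level: int 339
#>  $ nirae_records_record_level: int 386
#>  ...
```

`reports_in` counts every case version read; deduplication removed 214
versions and the deletion lists a further 30 cases, leaving 2,970
analyzable reports, of which 925 name a target ICI as suspect drug and
339 carry at least one nervous-system event (386 report×PT records).
The strongest recovered rows in `faers_out/signals_pt.csv`:

```
exposure      event                                   a   ror  ci_low
ATEZOLIZUMAB  PARANEOPLASTIC NEUROLOGICAL SYNDROME   49  24.3    15.7
PEMBROLIZUMAB IMMUNE-MEDIATED MYASTHENIA GRAVIS      81  13.4     9.3
NIVOLUMAB     IMMUNE-MEDIATED ENCEPHALOPATHY         59  12.8     8.7
IPILIMUMAB    IMMUNE-MEDIATED ENCEPHALITIS           24  14.6     8.6
```

each matching its planted association, with `ci_low` the ROR₀₂₅
ranking statistic.

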