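---
title: "Methods: disproportionality analysis of ICI neurotoxicity reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of ICI neurotoxicity reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(neurovigil)
```

## The problem and the estimator

Spontaneous-report pharmacovigilance data have no exposure denominator:
we observe only reports, each naming drugs and coded adverse events.
Disproportionality analysis asks whether an event is reported *more
often than expected* for an exposure, relative to the rest of the
database. For a deduplicated report universe, each exposure–event pair
defines a 2×2 table (a: exposed with event, b: exposed without, c:
unexposed with event, d: neither) and the reporting odds ratio

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc},\qquad
\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},$$

with the Wald interval $\exp(\ln \mathrm{ROR} \pm z_{0.975}\,\mathrm{SE})$.
A pair is a *signal* when $a \ge 3$ and the lower bound
($\mathrm{ROR}_{025}$) strictly exceeds 1. Signals are ranked by
$\mathrm{ROR}_{025}$ — the conservative strength statistic — not by the
point estimate, so sparse pairs with huge but unstable estimates do not
dominate the ranking.

Assumptions worth keeping in sight: the ROR measures *reporting*
disproportionality, not risk; the comparator ("all other reports") is
itself a mix of drugs and indications; and the Wald interval is a
large-sample approximation that degrades for very small cells — the
$a \ge 3$ floor removes the worst of these, and any table with a zero
cell is returned as *undefined* rather than continuity-corrected,
because an invented half-count would manufacture a ranking where the
data contain none.

## Unit of analysis and cohort accounting

The unit for every 2×2 cell and every cohort percentage is the
**deduplicated report** ("patient" row). A report with three
nervous-system PTs counts once per PT pair at screening but once — not
three times — in the cohort denominator. We additionally expose the
**record-level** count (report × nervous-PT pairs) in the manifest,
since both units circulate in the literature and they differ whenever
reports carry several events. Percentages are computed against the
report-level cohort size for every block; outcome percentages may
legitimately sum above 100 because one report can carry several outcome
codes.

## Pipeline stages and their rules

**Ingestion.** Quarterly packages are `$`-delimited with one header
row and no quoting. Field names are lower-cased so legacy and current
header spellings share one schema. Rows whose field count disagrees
with the header (free text containing a literal `$`) are dropped and
counted; a missing required column or a missing DEMO table is fatal.
Files are read as UTF-8 with a per-file Latin-1 fallback. Every
non-DEMO row must reference a DEMO `primaryid`; orphans are dropped
with counts, and each table satisfies
`rows_in == rows_kept + rows_dropped`.

**Deduplication.** Per `caseid`, keep the version with the largest
`fda_dt`; ties fall to the largest `primaryid` (numeric when fully
numeric, lexicographic fallback). Partial receipt dates are right-padded
(`YYYY` → `YYYY0101`) so the comparator is total; this ordering cannot
promote a partial date above a full date in the same month's favour —
it merely makes the comparison defined, after which the id rule breaks
ties exactly as specified. Deletion lists from *all* quarters are
unioned and applied to the post-dedup kept set: a case deleted in one
quarter must not resurface from an older package, and applying deletion
after deduplication matches the stated order of operations.

**Drug normalization.** Verbatim strings are upper-cased, whitespace-
collapsed, and stripped of *trailing* dose/form tokens from a fixed
list (numbers, `MG`, `TABLET`, …; unknown tokens are never stripped),
then looked up exactly in a synonym dictionary. No fuzzy matching: a
miss stays verbatim with a `RAW:` prefix so combination partners are
never silently lost. Exposure requires a *suspect* role (PS or SS,
configurable): a concomitant ICI does not qualify. This is the single
most consequential convention in the pipeline — all-role exposure
would inflate every exposed margin — and it follows standard
disproportionality practice.

**Terminology mapping.** PTs map through a slice table with one primary
HLGT and SOC per PT (no multi-axiality). Nervous-system events are the
PTs whose SOC is "Nervous system disorders". Unmapped PTs are excluded
from screening but counted in the manifest rather than guessed.

**Descriptives.** Ages convert to years (decades ×10, months /12,
weeks /52.143, days /365.25, hours /8766); values above 120 years are
treated as data errors and set missing. Time to onset is the day count
from the *earliest* target-ICI therapy start to the event date, both
required at day precision; partial dates yield missing rather than an
imputed within-month position, and negative spans (therapy recorded
after the event) are set missing. Quartiles use the Tukey
median-of-halves convention (median excluded from both halves at odd
n) — deterministic and aligned with integer-valued published quartiles,
but an approximation relative to interpolation-based definitions.
Presentation rounding is half-up to 2 decimals, applied only at output.

**Screening.** Per-drug screens compare the exposed reports against
*all* other reports, including reports of other ICIs; the pooled
`"any_ici"` screen removes the whole class from the comparator by
construction. Stratified screens (sex F/M; age bands young `<45`,
middle `45–64`, elderly `≥65`, configurable because published cutoffs
are rarely stated) re-run the screen inside each stratum's
sub-universe; reports missing the stratum value are excluded from that
dimension only, so strata partition the known-value universe. The
monotherapy sensitivity screen keeps as exposed only reports with
exactly one target ICI and no other suspect drug, while the comparator
keeps every non-exposed report. Combination screens require the ICI as
suspect plus the partner among co-suspect or concomitant ingredients
(and among co-suspect ICIs for dual-immunotherapy pairs, which would
otherwise be unreachable since a second ICI is never classified as a
plain co-suspect). Ranking ties (equal $\mathrm{ROR}_{025}$) break by
$a$ descending then event label ascending — invented, but
deterministic. No multiple-testing adjustment is applied, matching
field practice for hypothesis-generating screens; the manifest records
the number of tests performed so a reader can calibrate expectations.

## The synthetic-data generator

The generator emits quarterly packages in exactly the dialect the
reader consumes, with known ground truth. Its defaults encode the
study conditions of the analysed cohort: sex mix 53.5/37.8/8.7
(M/F/unknown), age ~ Normal(65.1, 12.76) truncated to [0, 100] years,
~91.2% serious reports with outcome-code probabilities from the cohort
table, and onset intervals lognormal with median 30 days (sdlog 1.46,
chosen so the implied mean ≈ 87 days matches the cohort's mean/median
spread). Where the cohort tables state no value (duplicate rate 5%,
deletion rate 1%, background event probability 2%, name-variant rate
30%, concomitant rate 40%), rates were chosen once at values a FAERS
analyst would recognise as realistic and are config-exposed, not
revisited.

Planting: each signal owns a disjoint block of `n_exposed` reports; the
block's event probability is raised from the baseline $p_0$ to
$p_1 = \mathrm{ROR}\,p_0 / (1 - p_0 + \mathrm{ROR}\,p_0)$, which makes
the exposed odds exactly ROR times the background odds, so the expected
2×2 realizes the target exactly (`expected_table()`, verified in tests
against an independent root-finder). Reports then sample their cells
independently — the multinomial draw over the universe — giving both an
exact expectation oracle and realistic sampling noise
(`sample_signal_cells()` draws the same cells without file I/O and is
the replicate engine for coverage studies). When one drug appears in
several planted blocks (e.g. alone and in a combination), the
analysis-level exposure is the union of its blocks, so the ground-truth
ledger records *realized* cells under that same exposure definition.

What the generator does **not** emulate: reporting-delay dynamics,
market-share trends over two decades, correlated event co-occurrence,
real FAERS country/indication margins, or free-text chaos beyond
synonym variants and a configurable junk-name rate. Green tests
therefore certify the *machinery* — parsing, dedup arithmetic,
normalization, mapping, cell construction, estimator calibration — not
the epidemiology of any real cohort; reproducing a published cohort's
actual counts requires the real database download, which is out of
scope by design.

## Numerical and degenerate-input choices

- Zero in any cell → `undefined = TRUE`, `NA` estimate, never a signal;
  no continuity correction.
- `percent()` errors on a zero denominator rather than returning `NaN`.
- Partial-date parsing is total: junk becomes missing, never an error.
- Dedup, screening and file emission are order-insensitive /
  deterministically sorted, so identical inputs give byte-identical
  outputs (the pipeline audit re-checks the conservation identities on
  every run and aborts on violation).
- All generator randomness flows from one integer seed.

## Problem sizes used by the test suite

The suite exercises the estimator against an independent closed-form
oracle on 10,000 random all-positive tables (1e-9 relative agreement),
the dedup rule against a brute-force group-sort oracle on 1,000
multi-version cases, and CI coverage of planted RORs {2, 5, 20} over
200 replicate universes of 50,000 reports each (binomial 3-SD band
around 95%), plus a null-configuration false-positive comparison
against a 2,000-draw Monte-Carlo oracle. End-to-end determinism and
generator-vs-pipeline ledger agreement run on 2,000–3,000-report
two-quarter packages — large enough to exercise every path, small
enough to keep the default test run fast.

## Known limitations

- The shipped dictionary and terminology tables are synthetic slices;
  real-data runs must supply licensed equivalents via
  `dict_path`/`slice_path`.
- Exact-match normalization will miss spellings outside the dictionary;
  misses are counted, not imputed.
- One primary HLGT per PT ignores MedDRA multi-axiality.
- The Wald interval's small-sample behaviour makes single-digit cells
  fragile; the $a \ge 3$ floor is a blunt guard, not a fix.
- ROR values are not comparable across drugs as risk estimates, and no
  causal reading is supported.
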