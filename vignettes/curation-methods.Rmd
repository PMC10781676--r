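---
title: "Curating aquatic effect concentrations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating aquatic effect concentrations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotoxcurate)
```

## The problem

Environmental risk assessment needs one robust, comparable effect
concentration per chemical and species group, but experimental ecotoxicity
records are scattered across decades of studies with heterogeneous species,
endpoints, exposure durations, and dosing units. `ecotoxcurate` implements a
curation pipeline that harvests acute effect records from ECOTOX-style
knowledgebase releases, filters them with explicit criteria, harmonizes all
concentrations to mg/L, and aggregates them per chemical for the three
biological quality elements (BQEs) of the EU Water Framework Directive:
algae, crustaceans, and fish. Around that core it adds a solubility-domain
quality flag, post-processing of acute QSAR predictions for chemicals
without measured data, and a data model with summary statistics for curated
use-group and mode-of-action (MoA) annotation catalogs.

## Selection criteria

Records are filtered after joining the release tables (`results` to `tests`
by `test_id`, then species, chemicals, and references by their keys; rows
with dangling keys are dropped and counted, never silently lost). A record
is retained only if all of the following hold, and every rejection is
attributed to the *first* failing criterion in this fixed order so the run
report is stable (the order is a reporting convention only — the retained
set is order-independent):

1. **chemical** — its CAS is on the study chemical list (CAS compared as
   digits-only canonical keys);
2. **dosing** — water-based dosing (`water_concentration`), derived from
   the concentration unit;
3. **species** — ecotoxgroup matches the BQE, habitat is `Water`, and for
   crustaceans and fish the species is on the standard-test-species
   whitelist (`species_selection = "standard_test_species"`); algae use all
   species;
4. **effect** — effect code in {MOR, GRO, POP, REP, MPH, DEV}, plus ITX
   for crustaceans only;
5. **endpoint** — an acute endpoint family code EC/ED/EL/IC/LC/LD/LL/LT
   with level 1–99, or LOEC/LETC verbatim (trailing `*` and `/` modifiers
   are stripped; NOEC-style chronic endpoints are out of scope);
6. **duration** — exposure duration inside the closed window 0–5 days
   (unit codes d/dph/dpf), 0–120 hours (h/ht/hph/hpf/hv), or 0–7200 minutes
   (mi); records with missing duration are rejected, not imputed;
7. **concentration** — a usable positive numeric value.

Leading `>`, `<`, and `~` qualifiers are split off into a censoring flag.
The default keeps such records (flagged), because discarding them loses
real observations; `drop_censored = TRUE` gives the strict reading. The
standard-species whitelist is configuration
(`extdata/standard_test_species.txt`, seeded with OECD standard acute test
species): no authoritative list is published, so any full-scale count that
depends on it is whitelist-sensitive.

## Unit standardization and aggregation

All retained concentrations are converted to mg/L. Mass units rescale by
fixed factors; ppm/ppb are equated to mg/L and µg/L under the dilute
aqueous assumption; molar units multiply by the average molecular mass from
a CAS-keyed lookup table. Unsupported unit spellings produce missing values
and are tallied in an unsupported-unit report rather than aborting a
release-wide run; the dialect table is configuration.

Per chemical × BQE the pipeline reports n, the 5th percentile
(`quantile = 0.05`), arithmetic mean, geometric mean, median, minimum, and
maximum, each rounded to four significant digits. Two numerical choices
matter:

* the percentile uses sorted-order linear interpolation with rank
  `h = (n − 1)p + 1` (the convention of `quantile(type = 7)`), implemented
  from the formula so the result is environment-independent and
  cross-checked in the tests against `stats::quantile` as an independent
  oracle;
* rounding is applied **after** all statistics are computed on unrounded
  values — rounding first would bias the percentile and the extremes.

All raw mg/L values, endpoints, effects, measurements, species, durations,
and reference IDs are collapsed into one `"; "`-delimited string per
category on each summary row, so every aggregated number can be audited
back to its inputs. The `"; "` delimiter differs from the CSV delimiter and
the writer quotes fields, so collapsed values survive file round trips.

## Solubility domain

Nominal effect concentrations above a chemical's water solubility are
suspect (older studies dosed nominally). Each aggregated statistic is
graded against the predicted solubility `S_w` (converted from log10 mol/L
via `10^logSw · mw · 1000`):

| class | condition |
|-------|-----------------------------------|
| 3 | `EC ≤ S_w` |
| 2 | `S_w < EC ≤ S_w·10^0.5` |
| 1 | `S_w·10^0.5 < EC ≤ S_w·10^1` |
| 0 | `EC > S_w·10^1` |

The half-log and full-log boundaries are exposed as configuration
(`steps = c(0.5, 1.0)`). Published descriptions of this scheme print the
intermediate bounds in a typographically garbled form; the half-log-step
reading implemented here is the only one consistent with the accompanying
prose, and it makes the classifier a total, scale-invariant, monotone step
function partitioning (0, ∞) — properties the test suite asserts. Note the
scheme is usually described as having "three classes" (of exceedance);
four labels {3, 2, 1, 0} exist because class 3 is the non-exceedance case.

## QSAR post-processing

Measured data cover only a minority of chemicals; acute EC50 QSAR
predictions fill gaps. The deployed acute models report −log10(mmol/L)
plus an a-dimensional (box-cox-scale) value; a molecular-weight defect in
the deployed model version makes the logged value unreliable for the algae
and fish models, so EC50s are recovered from the a-dimensional value:

* algae: `EC50 [mmol/L] = (a·0.07 + 1)^(1/0.07)`
* fish: `EC50 [mmol/L] = (a·0.11 + 1)^(1/0.07)` by default.

The fish exponent is printed as 1.0/0.07 in the source describing the
correction, although box-cox symmetry would suggest 1.0/0.11; we keep the
printed value as the default for fidelity and expose
`correct_fish(a, exponent = 1/0.11)` for the symmetric reading — the
ambiguity cannot be resolved from the published material. The Daphnia model
has no printed correction; its −log values are back-transformed directly
(`10^(−pred)`). Predictions with `a·λ + 1 ≤ 0` are outside the transform's
domain and become missing values with a warning, never clipped.
Applicability-domain text passes through verbatim. mg/L values are
`mmol/L · mw`.

## Annotation catalog model

The catalog data model stores, per compound, parent/transformation-product
(TP) status, use groups, broad and specific MoA lists, molecular targets,
and non-target alerts. The separator grammar uses `","` between broad
domains, `"+"` between sectors, and `"/"` within a sector. Summary
statistics follow the catalog's analysis conventions: biocides are counted
with pesticides and drugs of abuse with pharmaceuticals; compounds whose
merged categories still span several groups count once under "Multiple
use"; `parent + TP` compounds tally as parents; and the per-category MoA
table counts only single-MoA compounds, with multi-MoA and unknown
compounds tallied separately so the three buckets partition the catalog.
Category matching is case- and whitespace-insensitive; unknown tokens are
reported, never coerced or dropped — in a hand-curated catalog, deviations
are signal. The eight use-group categories ship as an editable list; the
32-entry broad-MoA vocabulary shipped here is an illustrative system-level
default, since the authoritative vocabulary travels with a given catalog.

## Synthetic studies and what they show

`fixture_spec()` + the three generators produce a miniature, fully seeded
study: a release archive whose records include exactly one violation of
each selection criterion, planted concentration sets, solubility profiles
that deterministically cover all four domain classes, an annotation table,
and QSAR outputs. Every expectation in the manifests is computed with
plain base R (`stats::quantile(type = 7)`, `exp(mean(log(x)))`, base
`signif`, direct inequality checks), never with the pipeline's own code, so
end-to-end tests compare two independent routes. Default sizes (10 data
points for the data-rich algae chemical, 6 crustacean and 8 fish records,
12 annotations, 5 QSAR compounds) keep the suite fast while exercising
every code path; one test scales the data-rich chemical to 75 points to
exercise deep provenance fields.

The fixtures target code paths, not realism: they do not mimic the
empirical distribution of a real knowledgebase release (study sizes, unit
frequencies, species imbalance, free-text noise). Passing fixture tests
therefore demonstrates correctness of the mechanics, not that any
particular real-world count will be reproduced — full-scale results
additionally depend on the standard-species whitelist configuration noted
above.

## Degenerate inputs and tie-breaks

Single-value sets return that value for every statistic. Empty value sets
are errors at aggregation (a chemical without usable records simply has no
row). Boundary durations and solubility ratios compare with `≤` (closed
intervals, inclusive upper bounds). `signif` rounds ties half-to-even.
Duplicate keys in lookup tables abort (ambiguous join) rather than pick a
row.

## Limitations

* The standard-species whitelist and unit dialect are deliberately
  configuration; shipped defaults are sensible but not authoritative.
* Only water-based acute dosing is handled; body-burden (mg/kg) records
  are rejected upstream by design.
* The fish-model exponent ambiguity is exposed, not resolved.
* MoA vocabularies are validated, not inferred; no structure-based MoA
  prediction is attempted.
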