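---
title: "Methods: emissions accounting for IV antimicrobial single-use waste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emissions accounting for IV antimicrobial single-use waste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxcarbon)
```

## The accounting model

`abxcarbon` estimates the CO2-equivalent greenhouse-gas emissions embodied
in the *disposal* of single-use materials consumed when IV antimicrobials
are packaged, prepared, and administered. The model is a bill-of-materials
aggregation, not a life-cycle model:

1. every weighable item (vial, bag, box, syringe, tubing, ...) carries a
   measured mass in grams and a single WARM material class — for
   multi-component items, the most substantial component's class, assigned
   at data entry;
2. an item's emission is `mass / 907184.74 g × f(material, method)`, where
   `f` is a WARM-style factor in metric tons CO2e per short ton of waste
   and the method (landfilled / recycled / combusted) comes from the active
   disposal scenario;
3. a product's per-dose emission sums `count_per_dose × item emission` over
   its packaging and preparation bill of materials;
4. its per-DOT emission is the per-dose value times the product's standard
   doses/day (normal renal function, most common indication) plus the daily
   administration-materials total — administration is charged **per day of
   therapy, not per dose**, because infusion setups (tubing, secondary
   lines) are maintained across a day's doses. Institutions whose practice
   charges administration per dose can fold those items into the product
   BOMs instead; no separate switch is provided;
5. per-agent factors are unweighted arithmetic means over the agent's
   products (per-(agent, dose-strength) means for the dose calculator).
   Utilization-weighted averaging is deliberately not offered.

All internal arithmetic is in metric tons CO2e at full double precision;
short tons appear only as a report column (both are emitted, since waste
factors are short-ton-based while equivalency factors are metric). The
two-decimal values users see (0.08 boxes/dose for a box of 12; 0.33
vials/dose for a three-dose vial) are display rounding only.

## Averaging layers

Two distinct averages interact when several sites measure the same program:

- **item masses** are averaged across the sites that weighed the item
  (items weighed at only one site use that site's value; the site coverage
  is carried in `items$n_sites_measured`);
- **product totals** are computed per site from that site's own counts —
  using the cross-site mean masses — and then averaged across sites.

Whether per-site totals should instead use per-site masses is a genuinely
open choice; we compute per-site totals from mean masses so that count
differences (workflow differences) and mass differences (manufacturer
differences) are separated, and the layering is isolated in one internal
function (`product_totals()`) so it can be swapped without touching
anything else. Between-site weight concordance is summarized with
`relative_difference()`, defined symmetrically as `|a − b| / mean(a, b)`.

## Reference data and scenarios

The packaged `emission_factors.csv` transcribes the EPA GHG Emission
Factors Hub waste table (the transcription vintage is recorded in the
file's `source` column and propagates into every report header as the
provenance string); institutions should substitute their preferred vintage
via `load_emission_factors()`. Factors may be negative (recycling credits);
a report whose total goes net-negative triggers a warning rather than an
error. A `"mixed"` fallback class (mixed-MSW factors) exists for items that
cannot be assigned a specific material — assigning it is an inventory
classification decision; `get_factor()` itself never falls back silently.

A disposal scenario is a default method plus per-material overrides
(`disposal_scenario("landfilled", c(glass = "recycled"))`). The default is
landfilled everywhere, the disposal route for nonhazardous hospital waste
at the institutions whose practice the defaults mirror. `"incinerated"` is
accepted on input as a spelling of `"combusted"`. Waste-mass columns are
scenario-independent by construction; only emissions move.

The equivalency set (miles driven by an average passenger vehicle, gallons
of gasoline consumed, smartphones charged, tree seedlings grown for 10
years) follows the EPA equivalencies calculator, with values reported as
emissions ÷ per-unit factor. The published calculator names four
equivalency columns without defining them, so this default set is a
documented choice and is fully replaceable via `equivalencies.csv` — file
order defines report column order.

## Name matching

Usage exports spell agents inconsistently ("Vancomycin HCl",
"piperacillin/tazobactam"). `normalize_agent_name()` trims, case-folds,
hyphenates slash combinations, strips salt suffixes, and applies a packaged
alias table (brands and salts). Names that still match nothing are
*flagged*, never guessed, and the calculators fail on them with
nearest-candidate suggestions rather than dropping rows.

## The synthetic generator

`generate_fixture()` emulates the *structure* of a two-site measurement
campaign so every pipeline stage is testable without any external data:

- study-scale cardinalities via `fixture_spec_study()`: 47 agents, 110
  drug products (premix fraction 26/110, split frozen/nonfrozen; the
  remainder locally compounded with a minority Mini-Bag-Plus share), 102
  inactive preparation/administration materials, 2 sites;
- every product BOM contains exactly one drug container and a box
  allocation drawn from {1/6, 1/10, 1/12, 1/24}; some compounded vials are
  shared across 2–3 doses; sites occasionally differ by one preparation
  item, mirroring workflow differences;
- per-site masses are jittered uniformly ±10% around a base mass and
  rounded to centigrams (most observed between-site weight differences in
  practice are under 15%); base masses are log-uniform on 0.5–120 g for
  inactive items;
- doses/day are drawn from {0.5, 1, 2, 3, 4, 6} (0.5 encodes q48h).

One explicit seed drives every draw, so a spec + seed pair is byte
reproducible. What the generator does **not** emulate: real measured
masses and counts, correlations between an agent and its materials,
formulary composition, renal dose adjustment, or usage volumes tied to
real case mix. Passing tests therefore demonstrate the *arithmetic and its
invariants* on realistic structure, not agreement with any institution's
measured waste.

## Numerical choices

- Report rows are sorted by key (radix order, locale-independent) before
  summation, making totals bit-stable across platforms; the canonical
  writers format numbers at 15 significant digits, so write→read
  round-trips are exact to ~1e-15 relative and golden-file comparison is
  byte-for-byte meaningful (the report timestamp is injectable and omitted
  by default for exactly this reason).
- Degenerate inputs are defined, not special-cased: zero masses and zero
  counts yield zero emissions; zero-quantity usage rows are reported, not
  dropped; an empty usage table yields a header plus zero totals; a single
  site is a valid campaign (all cross-site operations are defined for any
  site count ≥ 1).
- Missing data fail loudly: a site with a product BOM but no
  administration BOM is an error rather than a silent zero, as are dangling
  BOM references and materials absent from the factor table.

The test suite cross-checks the vectorized engine against an independent
plain-loop reference implementation to 1e-12 relative on 200 randomly
generated small inventories (≤ 3 agents, ≤ 2 products/agent, ≤ 10 items,
≤ 3 sites), alongside additivity, homogeneity, scenario-isolation,
unit-round-trip, and totals-equal-column-sums properties; the acceptance
script exercises the full study-scale configuration. These sizes were
chosen to keep the oracle comparison exhaustive per fixture while covering
many random structures.

## Reference-data import

`import_supplementary()` rebuilds a full inventory from an
institution-supplied delimited export (the published reference workbook's
tabs, or an institution's own tables) laid out as the four inventory files
plus an optional `reported_emissions.csv`; when the latter is present,
every product's per-dose emission is recomputed and discrepancies are
listed, so transcription errors surface immediately. The published
workbook itself is not redistributable and is never bundled; the importer
is isolated so that nothing else in the package depends on it.

## Known limitations

Estimates cover only materials the hospital discards: drug manufacturing,
shipping, personal protective equipment, refrigeration, and emissions from
antimicrobial-associated complications are out of scope, so totals are
underestimates of the full footprint. The DOT calculator assumes standard
dosing with normal renal function and will overestimate for renally
dose-reduced patients (partly offsetting the underestimates above).
Administration-material counts are per-day averages; practices such as
secondary-line use vary within and between institutions, and the admin BOM
is keyed by site only, not by agent. Formulary and formulation differences
between institutions mean packaged per-agent factors should be
re-derived from a local inventory where accuracy matters.
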