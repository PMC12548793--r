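# abxcarbon

Greenhouse-gas (GHG) emissions accounting for the single-use disposable
waste generated by packaging, preparing, and administering intravenous (IV)
antimicrobials in hospitals.

Antimicrobial stewardship programs routinely track IV antimicrobial use as
days of therapy (DOT), and many run IV-to-oral conversion initiatives. Every
avoided IV dose also avoids a stream of single-use waste — powder vials,
premix bags, paperboard and corrugated boxes, syringes, tubing, flushes —
whose disposal releases CO2 and methane. `abxcarbon` turns stewardship
utilization data into estimated avoided (or incurred) CO2-equivalent
emissions, so environmental impact can sit alongside cost and resistance as
a stewardship outcome measure.

## The model

Each single-use item *i* is weighed (grams, centigram precision), classified
to an EPA Waste Reduction Model (WARM) material type, and mapped to an
emission factor *f*(mat<sub>i</sub>, method) in metric tons CO2e per short
ton of waste, where the disposal method (landfilled by default; recycled or
combusted per material via a disposal scenario) is the institution's own.
Masses measured at several sites are arithmetically averaged. Then, per
drug product *p* at site *s* with per-dose bill-of-materials counts
*c<sub>i,s</sub>*:

- **per dose** (packaging + preparation):
  E<sub>dose</sub>(p, s) = Σ<sub>i</sub> c<sub>i,s</sub> · (m̄<sub>i</sub> / τ) · f(mat<sub>i</sub>),
  with τ = 907 184.74 g per short ton;
- **per DOT**:
  E<sub>DOT</sub>(p, s) = E<sub>dose</sub>(p, s) · d<sub>p</sub> + A<sub>s</sub>,
  where d<sub>p</sub> is the product's standard doses/day and A<sub>s</sub>
  the site's daily administration-materials total;
- per-site totals are averaged across sites, and per-agent factors are
  unweighted means over the agent's products (per-(agent, dose) means for
  the dose calculator).

Items shared across doses enter fractionally: a box of 12 premixes counts
1/12 ≈ 0.08 boxes per dose; a vial yielding 3 doses counts 1/3 ≈ 0.33 vials
per dose.

The **DOT / Dose / Drug-Product calculators** multiply usage counts
(per-agent IV DOT as in an NHSN line listing, per-dose counts, or per-product
counts) by these factors and report CO2e in short and metric tons, waste
mass, and interpretable equivalencies (miles driven, gallons of gasoline,
smartphone charges, tree seedlings grown 10 years), with column totals.

## Worked example

The package ships a small synthetic two-site inventory
(`inst/extdata/example/`, regenerable with `fixture_spec(seed = 20240901)`):

```r
library(abxcarbon)
ex <- system.file("extdata", "example", package = "abxcarbon")
factors <- abx_emission_factors()
bundle <- load_inventory(file.path(ex, "items.csv"), file.path(ex, "products.csv"),
                         file.path(ex, "bom.csv"), file.path(ex, "admin_daily.csv"),
                         factors = factors)
agent_factors(bundle, factors)
#> # A tibble: 4 × 4
#>   agent       mtco2e_per_dot waste_g_per_dot n_products_averaged
#>   <chr>                <dbl>           <dbl>               <int>
#> 1 cefazolin        0.0000271            272.                   2
#> 2 cefepime         0.0000264            191.                   2
#> 3 ceftriaxone      0.0000273            197.                   2
#> 4 vancomycin       0.0000204            300.                   2

usage <- readr::read_csv(file.path(ex, "usage_dot.csv"), show_col_types = FALSE)
compute_dot_report(usage, agent_factors(bundle, factors),
                   provenance = factor_provenance(factors))
#> <abx_report> mode=dot, 4 row(s)
#>   total: 0.143233 mtCO2e (0.157887 short tons), 1.32692e+06 g waste
#>   = 364.5 miles driven by average passenger vehicle
#>   = 16.12 gallons of gasoline consumed
#>   = 1.742e+04 smartphones charged
#>   = 2.387 tree seedlings grown for 10 years
```

Reading: ~5,400 IV DOT across four agents correspond to ~0.14 metric tons
CO2e and ~1.3 tonnes of landfilled waste — the emissions of driving ~364
miles. Per-DOT factors of 2–3 × 10⁻⁵ mtCO2e (20–30 g CO2e/DOT) are typical
for landfilled plastic-dominated waste; paper and corrugated packaging
dominate the emissions because their landfill factors are ~50× those of
plastics.

A command-line wrapper is installed under `exec/`:

```sh
abx-carbon fixture generate --seed 5 --out demo
abx-carbon compute --mode dot --usage demo/usage_dot.csv --inventory demo --out report.csv
abx-carbon factors list
```

## Package data

- `inst/extdata/emission_factors.csv` — WARM material × disposal-method
  factors (mtCO2e per short ton), transcribed from the EPA GHG Emission
  Factors Hub waste table; replaceable via `load_emission_factors()`.
- `inst/extdata/equivalencies.csv` — EPA equivalencies-calculator factors.
- `inst/extdata/agent_synonyms.csv` — agent-name aliases (brands, salts)
  used by `normalize_agent_name()`.
- `inst/extdata/example/`, `inst/extdata/golden/` — synthetic worked example
  and its golden DOT report used by the regression tests.

See the vignette (`vignettes/emissions-accounting.Rmd`) for the full
methods discussion: averaging layers, disposal scenarios, what the synthetic
generator does and does not emulate, and known limitations.
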