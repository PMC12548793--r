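# Hand-built single-site inventory with round numbers, used wherever a test
# needs values checkable by hand.
make_toy_bundle <- function() {
  items <- tibble::tibble(
    item_id = c("vial", "box", "bag", "flush", "tubing", "syringe"),
    name = c("drug powder vial (empty)", "vial paperboard box",
             "carrier bag (empty and dry)", "saline flush syringe",
             "primary tubing set", "60 mL syringe"),
    role = c("drug_container", "drug_packaging", "drug_container",
             "administration", "administration", "preparation"),
    material = c("glass", "corrugated containers", "mixed plastics",
                 "polypropylene", "hdpe", "polypropylene"),
    site = "A",
    mass_g = c(20, 30, 40, 10, 50, 5)
  )
  products <- tibble::tibble(
    product_id = "p1", agent = "vancomycin", dose_label = "1 g/50 mL",
    formulation = "local_compound", doses_per_day = 2
  )
  bom <- tibble::tibble(
    product_id = "p1", item_id = c("vial", "box", "bag"), site = "A",
    count_per_dose = c(1, 0.08, 1)
  )
  admin <- tibble::tibble(site = "A", item_id = c("flush", "tubing"),
                          count_per_day = c(2, 1))
  inventory_bundle(items, products, bom, admin)
}

# Random small fixture spec for property loops.
random_small_spec <- function(seed) {
  fixture_spec(
    seed = seed,
    n_agents = 1L + (seed %% 3L),
    n_products_per_agent = 1L + (seed %% 2L),
    n_items = 6L + (seed %% 5L),
    n_sites = 1L + (seed %% 3L)
  )
}

# Synthetic stand-in for an institution's reference-data export, in the
# layout import_supplementary() documents. The reported per-dose emissions
# are computed with the naive oracle, independently of the engine.
write_synthetic_supplementary <- function(dir, seed = 42L) {
  fx <- generate_fixture(fixture_spec(seed = seed, n_agents = 3L,
                                      n_products_per_agent = 2L,
                                      n_items = 10L, n_sites = 2L))
  write_inventory(fx$bundle, dir)
  orc <- oracle_totals(fx$bundle, abx_emission_factors())
  writeLines(c("product_id,mtco2e_per_dose",
               sprintf("%s,%.17g", orc$products$product_id,
                       orc$products$mtco2e_per_dose)),
             file.path(dir, "reported_emissions.csv"))
  fx
}
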