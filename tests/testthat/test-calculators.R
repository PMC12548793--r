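pkg_factors <- abx_emission_factors()
eq <- abx_equivalencies()

test_that("agent names normalize by case, whitespace, separators, and salts", {
  expect_equal(as.character(normalize_agent_name("Vancomycin ")), "vancomycin")
  expect_equal(as.character(normalize_agent_name("vancomycin HCl")), "vancomycin")
  expect_equal(as.character(normalize_agent_name("piperacillin/tazobactam")),
               as.character(normalize_agent_name("piperacillin-tazobactam")))
  expect_equal(as.character(normalize_agent_name("Zosyn")), "piperacillin-tazobactam")
  fl <- normalize_agent_name("florbetapir")
  expect_false(attr(fl, "matched"))
  expect_true(attr(normalize_agent_name("meropenem"), "matched"))
  expect_error(normalize_agent_name(""), class = "abx_validation_error")
})

test_that("equivalency values divide emissions by the per-unit factor", {
  miles_f <- eq$mtco2e_per_unit[eq$name == "miles driven by average passenger vehicle"]
  v <- equivalency_values(miles_f, eq)
  expect_equal(unname(v["miles driven by average passenger vehicle"]), 1)
  expect_equal(unname(equivalency_values(0, eq)), rep(0, nrow(eq)))
  v2 <- equivalency_values(0.0224, eq)
  expect_equal(unname(v2[1]), 0.0224 / miles_f)
  expect_equal(round(unname(v2[1])), 57)
})

toy_af <- function() {
  tibble::tibble(agent = c("vancomycin", "cefepime"),
                 mtco2e_per_dot = c(2e-5, 5e-5),
                 waste_g_per_dot = c(500, 900),
                 n_products_averaged = c(2L, 1L))
}

test_that("DOT report rows scale usage by per-DOT factors and keep zero rows", {
  af <- toy_af()
  zero <- compute_dot_report(tibble::tibble(agent = af$agent, iv_dot = 0), af, eq)
  expect_equal(nrow(zero$rows), 2L)
  expect_true(all(as.matrix(zero$rows[-1]) == 0))

  usage <- tibble::tibble(agent = c("Vancomycin", "cefepime"), iv_dot = c(100, 40))
  r1 <- compute_dot_report(usage, af, eq)
  expect_equal(r1$rows$co2e_metric_tons[r1$rows$key == "vancomycin"], 100 * 2e-5)
  expect_equal(r1$rows$waste_mass_g[r1$rows$key == "cefepime"], 40 * 900)
  # short tons column is the converted metric column
  expect_equal(r1$rows$co2e_short_tons,
               convert_mass(r1$rows$co2e_metric_tons, "metric_ton", "short_ton"))
  # doubling quantities doubles every numeric cell except nothing else changes
  r2 <- compute_dot_report(transform(usage, iv_dot = iv_dot * 2), af, eq)
  num <- vapply(r1$rows, is.numeric, logical(1))
  expect_equal(as.matrix(r2$rows[num]), 2 * as.matrix(r1$rows[num]))

  expect_error(compute_dot_report(tibble::tibble(agent = "vancomycin", iv_dot = -1), af, eq),
               class = "abx_validation_error")
  err <- tryCatch(compute_dot_report(tibble::tibble(agent = "vancomicin", iv_dot = 1), af, eq),
                  condition = identity)
  expect_s3_class(err, "abx_unmatched_key_error")
  expect_match(conditionMessage(err), "vancomycin") # near-miss suggestion
})

test_that("report totals equal column sums and ignore usage-row order", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(2:6, 1)
      af <- tibble::tibble(agent = paste0("agent", seq_len(n)),
                           mtco2e_per_dot = runif(n, 1e-6, 1e-4),
                           waste_g_per_dot = runif(n, 10, 1000),
                           n_products_averaged = 1L)
      usage <- tibble::tibble(agent = af$agent, iv_dot = sample(0:2000, n))
      r <- compute_dot_report(usage, af, eq, known = af$agent)
      for (cn in names(r$totals)[-1]) {
        expect_lt(rel_err(r$totals[[cn]], sum(r$rows[[cn]])), 1e-9)
      }
      shuf <- usage[sample(n), ]
      r2 <- compute_dot_report(shuf, af, eq, known = af$agent)
      expect_identical(r$rows, r2$rows)
      expect_identical(r$totals, r2$totals)
    }
  })
})

test_that("dose report is consistent with the DOT report under uniform dosing", {
  # one agent, one dose strength, fixed doses/day: DOT total must equal
  # dose-per-day-scaled dose total plus the daily administration materials
  toy <- make_toy_bundle()
  af <- agent_factors(toy, pkg_factors)
  adf <- agent_dose_factors(toy, pkg_factors)
  dpd <- toy$products$doses_per_day[1]
  n_dot <- 30
  rd <- compute_dot_report(tibble::tibble(agent = "vancomycin", iv_dot = n_dot), af, eq)
  rq <- compute_dose_report(tibble::tibble(agent = "vancomycin", dose_label = "1 g/50 mL",
                                           n_doses = n_dot * dpd), adf, eq)
  admin <- abxcarbon:::admin_totals_by_site(toy, pkg_factors, disposal_scenario())
  expect_equal(rd$totals$co2e_metric_tons,
               rq$totals$co2e_metric_tons + n_dot * mean(admin$mtco2e))
  expect_equal(rd$totals$waste_mass_g,
               rq$totals$waste_mass_g + n_dot * mean(admin$waste_mass_g))
  # quantity 1 returns the factor itself
  r1 <- compute_dose_report(tibble::tibble(agent = "vancomycin", dose_label = "1 g/50 mL",
                                           n_doses = 1), adf, eq)
  expect_equal(r1$rows$co2e_metric_tons, adf$mtco2e_per_dose)
  expect_error(compute_dose_report(tibble::tibble(agent = "vancomycin",
                                                  dose_label = "9 g/999 mL", n_doses = 1),
                                   adf, eq),
               class = "abx_unmatched_key_error")
})

test_that("product report uses un-averaged per-product factors", {
  fx <- generate_fixture(fixture_spec(seed = 61))
  pf <- product_factors(fx$bundle, pkg_factors)
  orc <- oracle_totals(fx$bundle, pkg_factors)
  usage <- fx$usage_product
  r <- compute_product_report(usage, pf, eq)
  expect_equal(nrow(r$rows), nrow(usage))
  ord <- order(usage$product_id, method = "radix")
  expected <- usage$n_doses[ord] *
    orc$products$mtco2e_per_dose[match(usage$product_id[ord], orc$products$product_id)]
  expect_lt(max(rel_err(r$rows$co2e_metric_tons, expected)), 1e-12)
  zero <- compute_product_report(transform(usage, n_doses = 0), pf, eq)
  expect_true(all(zero$rows$co2e_metric_tons == 0))
  r2 <- compute_product_report(transform(usage, n_doses = n_doses * 2), pf, eq)
  expect_equal(r2$totals$waste_mass_g, 2 * r$totals$waste_mass_g)
  expect_error(compute_product_report(tibble::tibble(product_id = "nope", n_doses = 1), pf, eq),
               class = "abx_unmatched_key_error")
})

test_that("waste-mass columns are scenario-independent while emissions move", {
  fx <- generate_fixture(fixture_spec(seed = 71))
  alt <- disposal_scenario("landfilled", c("corrugated containers" = "recycled"))
  af0 <- agent_factors(fx$bundle, pkg_factors)
  af1 <- agent_factors(fx$bundle, pkg_factors, alt)
  usage <- fx$usage_dot[fx$usage_dot$agent %in% af0$agent, ]
  r0 <- compute_dot_report(usage, af0, eq, known = af0$agent)
  r1 <- compute_dot_report(usage, af1, eq, known = af1$agent)
  expect_equal(r1$rows$waste_mass_g, r0$rows$waste_mass_g)
  expect_false(isTRUE(all.equal(r1$totals$co2e_metric_tons, r0$totals$co2e_metric_tons)))
})
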