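pkg_factors <- abx_emission_factors()

test_that("item emissions are mass times factor in short tons", {
  expect_equal(item_emissions("glass", 0, pkg_factors), 0)
  f <- get_factor(pkg_factors, "polypropylene")
  expect_equal(item_emissions("polypropylene", 907184.74, pkg_factors), f)
  expect_equal(item_emissions("glass", 50, pkg_factors),
               50 / 907184.74 * get_factor(pkg_factors, "glass"))
  expect_error(item_emissions("glass", -1, pkg_factors), class = "abx_validation_error")
  expect_error(item_emissions("unobtainium", 1, pkg_factors),
               class = "abx_missing_factor_error")
})

test_that("dose emissions equal the hand-summed bill of materials", {
  toy <- make_toy_bundle()
  d <- dose_emissions(toy, "p1", "A", pkg_factors)
  # 1 vial (20 g glass) + 0.08 box (30 g corrugated) + 1 bag (40 g mixed plastics)
  expect_equal(d$waste_mass_g, 20 + 0.08 * 30 + 40) # 62.4 g
  expect_equal(d$mtco2e,
               (20 * 0.02 + 0.08 * 30 * 1.13 + 40 * 0.02) / 907184.74)
  # zero counts give zero
  zero <- toy
  zero$bom$count_per_dose <- 0
  z <- dose_emissions(zero, "p1", "A", pkg_factors)
  expect_equal(z$mtco2e, 0)
  expect_equal(z$waste_mass_g, 0)
  # doubling every count doubles both outputs
  dbl <- toy
  dbl$bom$count_per_dose <- dbl$bom$count_per_dose * 2
  d2 <- dose_emissions(dbl, "p1", "A", pkg_factors)
  expect_equal(d2$mtco2e, 2 * d$mtco2e)
  expect_equal(d2$waste_mass_g, 2 * d$waste_mass_g)
  expect_error(dose_emissions(toy, "p1", "no-such-site", pkg_factors),
               class = "abx_validation_error")
})

test_that("site averaging is arithmetic and keeps per-site values", {
  one <- average_sites(tibble::tibble(site = "A", mtco2e = 0.5, waste_mass_g = 10))
  expect_equal(one$mtco2e, 0.5)
  two <- average_sites(tibble::tibble(site = c("A", "B"), mtco2e = c(1, 3),
                                      waste_mass_g = c(10, 20)))
  expect_equal(two$waste_mass_g, 15)
  expect_equal(nrow(two$site_values), 2L)
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(2:4, 1)
      mt <- runif(n); g <- runif(n, 0, 100)
      r <- average_sites(tibble::tibble(site = letters[1:n], mtco2e = mt, waste_mass_g = g))
      expect_equal(r$mtco2e, sum(mt) / n)
      expect_equal(r$waste_mass_g, sum(g) / n)
    }
  })
  expect_error(average_sites(list()), class = "abx_validation_error")
})

test_that("DOT totals are dose x doses/day plus daily administration", {
  # masses chosen so prep = 0.001 mtCO2e/dose and admin = 0.002 mtCO2e/day
  items <- tibble::tibble(
    item_id = c("vial", "tub"), name = c("vial", "tubing"),
    role = c("drug_container", "administration"),
    material = "glass", site = "A",
    mass_g = c(0.001 * 907184.74 / 0.02, 0.002 * 907184.74 / 0.02)
  )
  products <- tibble::tibble(product_id = "p1", agent = "x", dose_label = "1 g",
                             formulation = "local_compound", doses_per_day = 4)
  bom <- tibble::tibble(product_id = "p1", item_id = "vial", site = "A",
                        count_per_dose = 1)
  admin <- tibble::tibble(site = "A", item_id = "tub", count_per_day = 1)
  b <- inventory_bundle(items, products, bom, admin)
  r <- dot_emissions(b, "p1", pkg_factors)
  expect_equal(r$mtco2e, 0.001 * 4 + 0.002) # 0.006 mtCO2e/DOT

  # halving doses/day halves the preparation term but not the admin term
  b$products$doses_per_day <- 0.5
  r2 <- dot_emissions(b, "p1", pkg_factors)
  expect_equal(r2$mtco2e, 0.001 * 0.5 + 0.002)

  # admin-only product equals the daily administration total
  b$bom$count_per_dose <- 0
  r3 <- dot_emissions(b, "p1", pkg_factors)
  expect_equal(r3$mtco2e, 0.002)

  # a site with a product BOM but no admin BOM is an error, never silent zero
  b$admin_daily <- b$admin_daily[0, ]
  expect_error(dot_emissions(b, "p1", pkg_factors), class = "abx_validation_error")
})

test_that("agent factors are unweighted means over the agent's products", {
  fx <- generate_fixture(fixture_spec(seed = 31, n_agents = 3L,
                                      n_products_per_agent = 3L, n_items = 9L))
  af <- agent_factors(fx$bundle, pkg_factors)
  orc <- oracle_totals(fx$bundle, pkg_factors)
  expect_equal(af$agent, orc$agents$agent)
  expect_lt(max(rel_err(af$mtco2e_per_dot, orc$agents$mtco2e_per_dot)), 1e-12)
  expect_equal(af$n_products_averaged, orc$agents$n_products_averaged)
  # single-product agent passes its values through
  fx1 <- generate_fixture(fixture_spec(seed = 32, n_agents = 1L,
                                       n_products_per_agent = 1L, n_items = 6L))
  af1 <- agent_factors(fx1$bundle, pkg_factors)
  d1 <- dot_emissions(fx1$bundle, fx1$bundle$products$product_id[1], pkg_factors)
  expect_equal(af1$mtco2e_per_dot, d1$mtco2e)
})

test_that("agent-dose grouping partitions the product set", {
  fx <- generate_fixture(fixture_spec(seed = 33, n_agents = 3L,
                                      n_products_per_agent = 2L, n_items = 8L))
  adf <- agent_dose_factors(fx$bundle, pkg_factors)
  expect_equal(sum(adf$n_products_averaged), nrow(fx$bundle$products))
  # premix + compounded variants sharing a strength average to their mean
  toy <- make_toy_bundle()
  extra_prod <- tibble::tibble(product_id = "p2", agent = "vancomycin",
                               dose_label = "1 g/50 mL", formulation = "frozen_premix",
                               doses_per_day = 2)
  extra_bom <- tibble::tibble(product_id = "p2", item_id = "bag", site = "A",
                              count_per_dose = 1)
  b2 <- inventory_bundle(toy$item_sites, rbind(toy$products, extra_prod),
                         rbind(toy$bom, extra_bom), toy$admin_daily)
  adf2 <- agent_dose_factors(b2, pkg_factors)
  expect_equal(nrow(adf2), 1L)
  d1 <- dose_emissions(b2, "p1", "A", pkg_factors)
  d2 <- dose_emissions(b2, "p2", "A", pkg_factors)
  expect_equal(adf2$mtco2e_per_dose, (d1$mtco2e + d2$mtco2e) / 2)
})

test_that("engine agrees with the naive reference on random small inventories", {
  for (seed in 101:125) {
    fx <- generate_fixture(random_small_spec(seed))
    pf <- product_factors(fx$bundle, pkg_factors)
    orc <- oracle_totals(fx$bundle, pkg_factors)
    expect_equal(pf$product_id, orc$products$product_id)
    for (col in c("mtco2e_per_dose", "waste_g_per_dose", "mtco2e_per_dot",
                  "waste_g_per_dot")) {
      expect_lt(max(rel_err(pf[[col]], orc$products[[col]])), 1e-12)
    }
  }
})

test_that("emissions are additive over BOM partitions and homogeneous in mass", {
  toy <- make_toy_bundle()
  full <- dose_emissions(toy, "p1", "A", pkg_factors)
  withr::with_seed(7, {
    for (i in 1:10) {
      keep <- runif(nrow(toy$bom)) < 0.5
      a <- toy; a$bom$count_per_dose[!keep] <- 0
      b <- toy; b$bom$count_per_dose[keep] <- 0
      ra <- dose_emissions(a, "p1", "A", pkg_factors)
      rb <- dose_emissions(b, "p1", "A", pkg_factors)
      expect_equal(ra$mtco2e + rb$mtco2e, full$mtco2e)
      expect_equal(ra$waste_mass_g + rb$waste_mass_g, full$waste_mass_g)
    }
  })
  k <- 3.7
  scaled <- toy
  scaled$item_sites$mass_g <- scaled$item_sites$mass_g * k
  scaled <- inventory_bundle(scaled$item_sites, scaled$products, scaled$bom,
                             scaled$admin_daily)
  rs <- dot_emissions(scaled, "p1", pkg_factors)
  r0 <- dot_emissions(toy, "p1", pkg_factors)
  expect_lt(rel_err(rs$mtco2e, k * r0$mtco2e), 1e-12)
  expect_lt(rel_err(rs$waste_mass_g, k * r0$waste_mass_g), 1e-12)
})

test_that("changing one material's disposal method touches only that material", {
  fx <- generate_fixture(fixture_spec(seed = 55))
  base <- disposal_scenario()
  m <- "corrugated containers"
  alt <- disposal_scenario("landfilled", setNames("combusted", m))
  pf0 <- product_factors(fx$bundle, pkg_factors, base)
  pf1 <- product_factors(fx$bundle, pkg_factors, alt)
  # waste mass is scenario-independent
  expect_equal(pf1$waste_g_per_dot, pf0$waste_g_per_dot)
  expect_equal(pf1$waste_g_per_dose, pf0$waste_g_per_dose)
  # the emission delta is exactly the factor delta applied to material-m items
  df <- get_factor(pkg_factors, m, alt) - get_factor(pkg_factors, m, base)
  items <- fx$bundle$items
  bom <- fx$bundle$bom
  for (p in seq_len(nrow(pf0))) {
    rows <- bom[bom$product_id == pf0$product_id[p], ]
    idx <- match(rows$item_id, items$item_id)
    is_m <- items$material[idx] == m
    per_site <- tapply(rows$count_per_dose * items$mean_mass_g[idx] * is_m,
                       rows$site, sum)
    expected_delta <- mean(per_site) / 907184.74 * df
    expect_lt(abs((pf1$mtco2e_per_dose[p] - pf0$mtco2e_per_dose[p]) - expected_delta),
              1e-15 + 1e-9 * abs(expected_delta))
  }
})
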