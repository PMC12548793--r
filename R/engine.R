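#' @name engine
#' @title Emissions arithmetic
#'
#' @description
#' The core accounting: an item's waste emission is its mass (converted to
#' short tons) times the WARM factor for its material under the active
#' disposal scenario, in metric tons CO2e. A dose total sums count-per-dose
#' times item emission over the product's bill of materials (packaging +
#' preparation). A day-of-therapy (DOT) total multiplies the dose total by
#' the product's standard doses/day and adds the per-day administration
#' materials. Per-site totals are computed from each site's counts (with
#' cross-site mean item masses) and then arithmetically averaged; per-agent
#' factors are unweighted means over the agent's drug products.
NULL

#' Emissions from a single item mass
#'
#' @param material WARM material class (character, vectorized).
#' @param mass_g mass in grams (vectorized).
#' @param factors an `abx_factor_table`.
#' @param scenario an `abx_scenario`.
#' @return metric tons CO2e.
#' @export
item_emissions <- function(material, mass_g, factors, scenario = disposal_scenario()) {
  if (any(!is.finite(mass_g)) || any(mass_g < 0)) {
    abx_validation_error("mass_g must be finite and >= 0")
  }
  f <- get_factor(factors, material, scenario)
  (mass_g / GRAMS_PER_SHORT_TON) * f
}

new_emission_result <- function(mtco2e, waste_mass_g, site_values = NULL) {
  structure(list(mtco2e = mtco2e, waste_mass_g = waste_mass_g, site_values = site_values),
            class = "abx_emission_result")
}

#' @export
print.abx_emission_result <- function(x, ...) {
  cat(sprintf("<emissions> %.6g mtCO2e, %.6g g waste", x$mtco2e, x$waste_mass_g))
  if (!is.null(x$site_values)) cat(sprintf(" (mean of %d site(s))", nrow(x$site_values)))
  cat("\n")
  invisible(x)
}

# Per-(product, site) packaging+preparation totals for all products at once.
# Mean item masses (cross-site averages) feed each site's own counts.
dose_totals_by_site <- function(bundle, factors, scenario) {
  b <- dplyr::left_join(bundle$bom, bundle$items[c("item_id", "material", "mean_mass_g")],
                        by = "item_id")
  b$item_mt <- item_emissions(b$material, b$mean_mass_g, factors, scenario)
  dplyr::summarise(
    dplyr::group_by(b, .data$product_id, .data$site),
    mtco2e = sum(.data$count_per_dose * .data$item_mt),
    waste_mass_g = sum(.data$count_per_dose * .data$mean_mass_g),
    .groups = "drop"
  )
}

# Per-site daily administration totals.
admin_totals_by_site <- function(bundle, factors, scenario) {
  a <- dplyr::left_join(bundle$admin_daily,
                        bundle$items[c("item_id", "material", "mean_mass_g")],
                        by = "item_id")
  a$item_mt <- item_emissions(a$material, a$mean_mass_g, factors, scenario)
  dplyr::summarise(
    dplyr::group_by(a, .data$site),
    mtco2e = sum(.data$count_per_day * .data$item_mt),
    waste_mass_g = sum(.data$count_per_day * .data$mean_mass_g),
    .groups = "drop"
  )
}

#' Packaging + preparation emissions for one dose of a product at one site
#'
#' @param bundle an `abx_inventory`.
#' @param product_id product identifier.
#' @param site site identifier.
#' @param factors an `abx_factor_table`.
#' @param scenario an `abx_scenario`.
#' @return an `abx_emission_result` (no site averaging; one site).
#' @export
dose_emissions <- function(bundle, product_id, site, factors,
                           scenario = disposal_scenario()) {
  rows <- bundle$bom[bundle$bom$product_id == product_id & bundle$bom$site == site, ]
  if (nrow(rows) == 0L) {
    abx_validation_error(sprintf("product '%s' has no bill of materials at site '%s'",
                                 product_id, site))
  }
  idx <- match(rows$item_id, bundle$items$item_id)
  mt <- item_emissions(bundle$items$material[idx], bundle$items$mean_mass_g[idx],
                       factors, scenario)
  new_emission_result(sum(rows$count_per_dose * mt),
                      sum(rows$count_per_dose * bundle$items$mean_mass_g[idx]))
}

#' Average per-site emission results
#'
#' @param results named list of `abx_emission_result` (names = site ids), or a
#'   tibble with columns `site`, `mtco2e`, `waste_mass_g`.
#' @return an `abx_emission_result` whose headline values are the arithmetic
#'   means and whose `site_values` retains the per-site numbers.
#' @export
average_sites <- function(results) {
  if (is.data.frame(results)) {
    tbl <- tibble::as_tibble(results)
  } else {
    if (length(results) == 0L) abx_validation_error("average_sites: no site results")
    tbl <- tibble::tibble(
      site = names(results) %||% as.character(seq_along(results)),
      mtco2e = vapply(results, function(r) r$mtco2e, numeric(1)),
      waste_mass_g = vapply(results, function(r) r$waste_mass_g, numeric(1))
    )
  }
  if (nrow(tbl) == 0L) abx_validation_error("average_sites: no site results")
  new_emission_result(mean(tbl$mtco2e), mean(tbl$waste_mass_g), site_values = tbl)
}

#' Per-day-of-therapy emissions for one product
#'
#' For every site with a BOM for the product: dose total x doses/day plus the
#' site's daily administration total; the per-site DOT totals are then
#' averaged. A site that has a product BOM but no administration BOM is an
#' error — administration materials are never silently zero.
#'
#' @inheritParams dose_emissions
#' @return an `abx_emission_result` with `site_values`.
#' @export
dot_emissions <- function(bundle, product_id, factors, scenario = disposal_scenario()) {
  prod <- bundle$products[bundle$products$product_id == product_id, ]
  if (nrow(prod) == 0L) {
    abx_unmatched_key_error(sprintf("unknown product_id '%s'", product_id))
  }
  sites <- unique(bundle$bom$site[bundle$bom$product_id == product_id])
  if (length(sites) == 0L) {
    abx_validation_error(sprintf("product '%s' has no bill of materials", product_id))
  }
  admin <- admin_totals_by_site(bundle, factors, scenario)
  missing_admin <- setdiff(sites, admin$site)
  if (length(missing_admin) > 0L) {
    abx_validation_error(sprintf(
      "site(s) %s have a product BOM but no administration BOM",
      paste(missing_admin, collapse = ", ")
    ))
  }
  per_site <- lapply(sites, function(s) {
    d <- dose_emissions(bundle, product_id, s, factors, scenario)
    a <- admin[admin$site == s, ]
    new_emission_result(d$mtco2e * prod$doses_per_day + a$mtco2e,
                        d$waste_mass_g * prod$doses_per_day + a$waste_mass_g)
  })
  average_sites(setNames(per_site, sites))
}

# Cross-site averaged per-dose and per-DOT totals for every product.
product_totals <- function(bundle, factors, scenario) {
  dose_site <- dose_totals_by_site(bundle, factors, scenario)
  admin <- admin_totals_by_site(bundle, factors, scenario)
  missing_admin <- setdiff(unique(dose_site$site), admin$site)
  if (length(missing_admin) > 0L) {
    abx_validation_error(sprintf(
      "site(s) %s have product BOMs but no administration BOM",
      paste(missing_admin, collapse = ", ")
    ))
  }
  x <- dplyr::left_join(dose_site, bundle$products, by = "product_id")
  x <- dplyr::left_join(x, admin, by = "site", suffix = c("_dose", "_admin"))
  x$dot_mtco2e <- x$mtco2e_dose * x$doses_per_day + x$mtco2e_admin
  x$dot_waste_g <- x$waste_mass_g_dose * x$doses_per_day + x$waste_mass_g_admin
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$product_id, .data$agent, .data$dose_label,
                    .data$formulation, .data$doses_per_day),
    mtco2e_per_dose = mean(.data$mtco2e_dose),
    waste_g_per_dose = mean(.data$waste_mass_g_dose),
    mtco2e_per_dot = mean(.data$dot_mtco2e),
    waste_g_per_dot = mean(.data$dot_waste_g),
    n_sites = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$product_id)
}

#' Per-product emission factors
#'
#' Cross-site averaged per-dose (packaging + preparation) and per-DOT totals
#' for every product in the bundle; the basis of the drug-product calculator.
#' @param bundle an `abx_inventory`.
#' @param factors an `abx_factor_table`.
#' @param scenario an `abx_scenario`.
#' @return tibble, one row per product.
#' @export
product_factors <- function(bundle, factors, scenario = disposal_scenario()) {
  product_totals(bundle, factors, scenario)
}

#' Per-agent emission factors (DOT calculator basis)
#'
#' Unweighted mean of the per-DOT results over each agent's drug products.
#' @inheritParams product_factors
#' @return tibble: `agent`, `mtco2e_per_dot`, `waste_g_per_dot`,
#'   `n_products_averaged`.
#' @export
agent_factors <- function(bundle, factors, scenario = disposal_scenario()) {
  pt <- product_totals(bundle, factors, scenario)
  out <- dplyr::summarise(
    dplyr::group_by(pt, .data$agent),
    mtco2e_per_dot = mean(.data$mtco2e_per_dot),
    waste_g_per_dot = mean(.data$waste_g_per_dot),
    n_products_averaged = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$agent)
}

#' Per-agent-and-dose emission factors (dose calculator basis)
#'
#' Mean per-dose (packaging + preparation) results over products sharing an
#' (agent, dose strength) key — e.g. a frozen premix and a locally compounded
#' variant of the same strength are averaged.
#' @inheritParams product_factors
#' @return tibble: `agent`, `dose_label`, `mtco2e_per_dose`,
#'   `waste_g_per_dose`, `n_products_averaged`.
#' @export
agent_dose_factors <- function(bundle, factors, scenario = disposal_scenario()) {
  pt <- product_totals(bundle, factors, scenario)
  out <- dplyr::summarise(
    dplyr::group_by(pt, .data$agent, .data$dose_label),
    mtco2e_per_dose = mean(.data$mtco2e_per_dose),
    waste_g_per_dose = mean(.data$waste_g_per_dose),
    n_products_averaged = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$agent, .data$dose_label)
}
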