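#' @name inventory
#' @title Item, drug-product, and bill-of-materials inventory
#'
#' @description
#' The inventory holds everything the emissions engine needs about one
#' institution (or several measurement sites): weighable single-use items
#' with their WARM material class and per-site masses, drug products (agent,
#' dose strength, formulation, standard doses/day), a per-dose bill of
#' materials (BOM) per product and site, and a per-day administration BOM per
#' site. Item masses measured at several sites are arithmetically averaged;
#' items measured at only some sites are averaged over the sites that weighed
#' them, and the site coverage is carried alongside the mean.
NULL

ITEM_ROLES <- c("drug_packaging", "drug_container", "preparation", "administration")
FORMULATIONS <- c("local_compound", "minibag_plus", "frozen_premix", "nonfrozen_premix")

#' Average an item's per-site masses
#'
#' Weight measurements collected at different institutions are combined by
#' arithmetic mean.
#' @param site_masses named numeric vector (or list), site id -> grams.
#' @return mean mass in grams.
#' @examples
#' average_site_mass(c(A = 10, B = 12)) # 11
#' @export
average_site_mass <- function(site_masses) {
  m <- unlist(site_masses)
  if (length(m) == 0L) abx_validation_error("site_masses must have at least one entry")
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    abx_validation_error("all site masses must be finite and > 0")
  }
  mean(m)
}

#' Relative difference between two measurements
#'
#' `|a - b| / mean(a, b)` — the symmetric percent-difference convention used
#' to describe between-site weight concordance.
#' @param a,b positive masses in grams.
#' @return fraction (0 = identical).
#' @export
relative_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(c(a, b))) || any(c(a, b) <= 0)) {
    abx_validation_error("relative_difference requires positive finite inputs")
  }
  abs(a - b) / ((a + b) / 2)
}

#' Fractional per-dose count for boxed items
#'
#' Packaging shared by a whole box (premix boxes, vial paperboard boxes) is
#' allocated to each dose as 1 / items-per-box, e.g. a box of 12 premixes
#' contributes 0.0833... (displayed 0.08) boxes per dose. Full precision is
#' kept internally; rounding to two decimals is report formatting only.
#' @param items_per_box positive integer.
#' @return count per dose.
#' @export
per_dose_count_from_box <- function(items_per_box) {
  if (!is.numeric(items_per_box) || length(items_per_box) != 1L ||
      !is.finite(items_per_box) || items_per_box < 1 ||
      items_per_box != floor(items_per_box)) {
    abx_validation_error("items_per_box must be a positive integer")
  }
  1 / items_per_box
}

#' Fractional per-dose count for shared preparation materials
#'
#' When one preparation yields several doses (e.g. three 3 g/100 mL doses
#' drawn from one 10 g vial), each preparation item is allocated as
#' 1 / doses-per-preparation, e.g. 1/3 = 0.33 vials per dose.
#' @param doses_per_preparation positive integer.
#' @return count per dose.
#' @export
per_dose_count_from_shared_prep <- function(doses_per_preparation) {
  if (!is.numeric(doses_per_preparation) || length(doses_per_preparation) != 1L ||
      !is.finite(doses_per_preparation) || doses_per_preparation < 1 ||
      doses_per_preparation != floor(doses_per_preparation)) {
    abx_validation_error("doses_per_preparation must be a positive integer")
  }
  1 / doses_per_preparation
}

#' Assemble and validate an inventory bundle
#'
#' @param items long tibble, one row per item x site:
#'   `item_id,name,role,material,site,mass_g`.
#' @param products tibble `product_id,agent,dose_label,formulation,doses_per_day`.
#' @param bom tibble `product_id,item_id,site,count_per_dose`.
#' @param admin_daily tibble `site,item_id,count_per_day`.
#' @param factors optional `abx_factor_table`; when given, every item material
#'   must exist in it (unclassifiable items should be entered as `"mixed"`).
#' @return an `abx_inventory`: list with `items` (per-item summary with
#'   `mean_mass_g` and `n_sites_measured`), `item_sites`, `products`, `bom`,
#'   `admin_daily`.
#' @export
inventory_bundle <- function(items, products, bom, admin_daily, factors = NULL) {
  items <- tibble::as_tibble(items)
  products <- tibble::as_tibble(products)
  bom <- tibble::as_tibble(bom)
  admin_daily <- tibble::as_tibble(admin_daily)

  check_columns(items, c("item_id", "name", "role", "material", "site", "mass_g"), "items")
  check_columns(products, c("product_id", "agent", "dose_label", "formulation", "doses_per_day"),
                "products")
  check_columns(bom, c("product_id", "item_id", "site", "count_per_dose"), "bom")
  check_columns(admin_daily, c("site", "item_id", "count_per_day"), "admin_daily")

  items$mass_g <- as.numeric(items$mass_g)
  if (any(!is.finite(items$mass_g)) || any(items$mass_g <= 0)) {
    abx_validation_error("items: all masses must be finite and > 0 grams")
  }
  bad_role <- setdiff(unique(items$role), ITEM_ROLES)
  if (length(bad_role) > 0L) {
    abx_validation_error(sprintf(
      "items: invalid role(s) %s (accepted: %s)",
      paste(sQuote(bad_role), collapse = ", "), paste(ITEM_ROLES, collapse = ", ")
    ))
  }
  items$material <- norm_material(items$material)
  dup <- duplicated(items[c("item_id", "site")])
  if (any(dup)) {
    abx_validation_error(sprintf(
      "items: duplicate (item_id, site) row(s): %s",
      paste(unique(items$item_id[dup]), collapse = ", ")
    ))
  }
  attr_chk <- dplyr::summarise(dplyr::group_by(items, .data$item_id),
                               n_attr = dplyr::n_distinct(.data$name, .data$role, .data$material),
                               .groups = "drop")
  if (any(attr_chk$n_attr > 1L)) {
    abx_validation_error(sprintf(
      "items: conflicting name/role/material across sites for: %s",
      paste(attr_chk$item_id[attr_chk$n_attr > 1L], collapse = ", ")
    ))
  }

  item_summary <- dplyr::summarise(
    dplyr::group_by(items, .data$item_id, .data$name, .data$role, .data$material),
    mean_mass_g = mean(.data$mass_g),
    n_sites_measured = dplyr::n(),
    .groups = "drop"
  )
  item_summary <- dplyr::arrange(item_summary, .data$item_id)

  if (!is.null(factors)) {
    known <- unique(factors$material)
    unknown <- setdiff(unique(item_summary$material), known)
    if (length(unknown) > 0L) {
      offenders <- item_summary$item_id[item_summary$material %in% unknown]
      abx_validation_error(sprintf(
        paste0("items %s use material(s) %s absent from the emission-factor table; ",
               "classify to the closest WARM material or to 'mixed'"),
        paste(offenders, collapse = ", "), paste(sQuote(unknown), collapse = ", ")
      ))
    }
  }

  products$doses_per_day <- as.numeric(products$doses_per_day)
  if (any(!is.finite(products$doses_per_day)) || any(products$doses_per_day <= 0)) {
    abx_validation_error("products: doses_per_day must be finite and > 0")
  }
  bad_form <- setdiff(unique(products$formulation), FORMULATIONS)
  if (length(bad_form) > 0L) {
    abx_validation_error(sprintf(
      "products: invalid formulation(s) %s (accepted: %s)",
      paste(sQuote(bad_form), collapse = ", "), paste(FORMULATIONS, collapse = ", ")
    ))
  }
  if (anyDuplicated(products$product_id)) {
    abx_validation_error("products: product_id values must be unique")
  }
  if (anyDuplicated(products[c("agent", "dose_label", "formulation")])) {
    abx_validation_error("products: (agent, dose_label, formulation) must be unique")
  }

  bom$count_per_dose <- as.numeric(bom$count_per_dose)
  if (any(!is.finite(bom$count_per_dose)) || any(bom$count_per_dose < 0)) {
    abx_validation_error("bom: count_per_dose must be finite and >= 0")
  }
  dangling_p <- setdiff(unique(bom$product_id), products$product_id)
  dangling_i <- setdiff(unique(bom$item_id), item_summary$item_id)
  if (length(dangling_p) + length(dangling_i) > 0L) {
    abx_validation_error(sprintf(
      "bom: dangling reference(s)%s%s",
      if (length(dangling_p)) paste0(" to product_id ", paste(dangling_p, collapse = ", ")) else "",
      if (length(dangling_i)) paste0(" to item_id ", paste(dangling_i, collapse = ", ")) else ""
    ))
  }

  admin_daily$count_per_day <- as.numeric(admin_daily$count_per_day)
  if (any(!is.finite(admin_daily$count_per_day)) || any(admin_daily$count_per_day < 0)) {
    abx_validation_error("admin_daily: count_per_day must be finite and >= 0")
  }
  dangling_a <- setdiff(unique(admin_daily$item_id), item_summary$item_id)
  if (length(dangling_a) > 0L) {
    abx_validation_error(sprintf("admin_daily: dangling reference(s) to item_id %s",
                                 paste(dangling_a, collapse = ", ")))
  }
  admin_roles <- item_summary$role[match(admin_daily$item_id, item_summary$item_id)]
  if (any(admin_roles != "administration")) {
    abx_validation_error(sprintf(
      "admin_daily: item(s) %s do not have role 'administration'",
      paste(unique(admin_daily$item_id[admin_roles != "administration"]), collapse = ", ")
    ))
  }

  structure(
    list(
      items = item_summary,
      item_sites = dplyr::arrange(items, .data$item_id, .data$site),
      products = dplyr::arrange(products, .data$product_id),
      bom = dplyr::arrange(bom, .data$product_id, .data$site, .data$item_id),
      admin_daily = dplyr::arrange(admin_daily, .data$site, .data$item_id)
    ),
    class = "abx_inventory"
  )
}

#' Load an inventory bundle from its four CSV files
#'
#' @param items_path,products_path,bom_path,admin_bom_path CSV paths with the
#'   schemas documented in [inventory_bundle()].
#' @param factors optional `abx_factor_table` used to validate WARM classes.
#' @return an `abx_inventory`.
#' @export
load_inventory <- function(items_path, products_path, bom_path, admin_bom_path,
                           factors = NULL) {
  read1 <- function(path) {
    if (!file.exists(path)) abx_schema_error(sprintf("inventory file not found: %s", path))
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  inventory_bundle(read1(items_path), read1(products_path), read1(bom_path),
                   read1(admin_bom_path), factors = factors)
}

#' Canonical inventory writer
#'
#' Writes `items.csv`, `products.csv`, `bom.csv`, `admin_daily.csv` into `dir`
#' in canonical row order with byte-stable numbers, so that load -> write ->
#' load round-trips exactly.
#' @param bundle an `abx_inventory`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inventory <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_ <- bundle$item_sites
  writeLines(c("item_id,name,role,material,site,mass_g",
               sprintf("%s,%s,%s,%s,%s,%s", is_$item_id, csv_field(is_$name), is_$role,
                       is_$material, is_$site, format_number(is_$mass_g))),
             file.path(dir, "items.csv"))
  p <- bundle$products
  writeLines(c("product_id,agent,dose_label,formulation,doses_per_day",
               sprintf("%s,%s,%s,%s,%s", p$product_id, p$agent, p$dose_label,
                       p$formulation, format_number(p$doses_per_day))),
             file.path(dir, "products.csv"))
  b <- bundle$bom
  writeLines(c("product_id,item_id,site,count_per_dose",
               sprintf("%s,%s,%s,%s", b$product_id, b$item_id, b$site,
                       format_number(b$count_per_dose))),
             file.path(dir, "bom.csv"))
  a <- bundle$admin_daily
  writeLines(c("site,item_id,count_per_day",
               sprintf("%s,%s,%s", a$site, a$item_id, format_number(a$count_per_day))),
             file.path(dir, "admin_daily.csv"))
  invisible(dir)
}

#' @export
print.abx_inventory <- function(x, ...) {
  cat(sprintf(
    "<abx_inventory> %d items (%d item-site measurements), %d products, %d agents, %d sites\n",
    nrow(x$items), nrow(x$item_sites), nrow(x$products),
    length(unique(x$products$agent)),
    length(unique(c(x$item_sites$site, x$bom$site, x$admin_daily$site)))
  ))
  invisible(x)
}
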