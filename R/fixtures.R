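#' @name fixtures
#' @title Seeded synthetic inventories and usage data
#'
#' @description
#' The generator emulates the structure of a two-site hospital measurement
#' campaign: a formulary of IV antimicrobial agents, each with one or more
#' drug products (locally compounded, Mini-Bag Plus, frozen or nonfrozen
#' premix), a pool of inactive preparation/administration materials with
#' per-site masses jittered around a base weight, per-dose bills of
#' materials including exactly one drug container and a fractional box
#' allocation, per-site daily administration counts, and NHSN-style usage
#' tables. Everything is driven by one explicit seed, so identical specs
#' produce byte-identical fixture directories.
NULL

AGENT_POOL <- c(
  "vancomycin", "cefazolin", "ceftriaxone", "cefepime", "ceftazidime",
  "cefoxitin", "cefuroxime", "ceftaroline", "ceftolozane-tazobactam",
  "ceftazidime-avibactam", "piperacillin-tazobactam", "ampicillin",
  "ampicillin-sulbactam", "nafcillin", "oxacillin", "penicillin g",
  "meropenem", "ertapenem", "imipenem-cilastatin", "aztreonam",
  "levofloxacin", "ciprofloxacin", "moxifloxacin", "azithromycin",
  "erythromycin", "clindamycin", "metronidazole", "linezolid", "daptomycin",
  "tigecycline", "gentamicin", "tobramycin", "amikacin", "doxycycline",
  "minocycline", "trimethoprim-sulfamethoxazole", "rifampin", "acyclovir",
  "ganciclovir", "foscarnet", "fluconazole", "voriconazole", "micafungin",
  "caspofungin", "amphotericin b", "posaconazole", "isavuconazole"
)

PREP_ITEM_NAMES <- c(
  "60 mL syringe", "10 mL syringe", "blunt fill needle", "dispensing pin",
  "alcohol prep pad", "sterile water vial", "saline diluent bag",
  "compounding bag overwrap", "vial adapter", "filter needle"
)

ADMIN_ITEM_NAMES <- c(
  "primary tubing set", "secondary tubing set", "saline flush syringe",
  "IV end cap", "alcohol swab", "extension set", "tubing label"
)

#' Packaged agent pool
#'
#' The formulary agent names the synthetic generator draws from; also the
#' default known-agent list for [normalize_agent_name()].
#' @return character vector of agent names.
#' @export
abx_agent_pool <- function() AGENT_POOL

#' Specification for a synthetic fixture
#'
#' Defaults are desk-scale; [fixture_spec_study()] gives the full
#' study-scale configuration.
#'
#' @param seed integer seed; identical spec + seed gives identical output.
#' @param n_agents number of agents (drawn from the packaged pool, then
#'   synthesized names if more are requested).
#' @param n_products_per_agent products per agent when `n_products_total` is
#'   `NULL`.
#' @param n_products_total optional exact total product count, distributed
#'   round-robin across agents (each agent gets at least one product).
#' @param n_items number of inactive (preparation/administration) materials.
#' @param n_sites number of measurement sites.
#' @param mass_range_g low/high bounds for base item masses, grams.
#' @param material_pool WARM classes for inactive items.
#' @param doses_per_day_pool standard dosing frequencies to draw from
#'   (0.5 = every 48 h).
#' @param premix_fraction fraction of products that are premixes.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_agents = 4L, n_products_per_agent = 2L,
                         n_products_total = NULL, n_items = 12L, n_sites = 2L,
                         mass_range_g = c(0.5, 120),
                         material_pool = c("mixed plastics", "polypropylene",
                                           "hdpe", "pet", "ldpe", "glass",
                                           "mixed paper (general)",
                                           "corrugated containers", "mixed"),
                         doses_per_day_pool = c(0.5, 1, 2, 3, 4, 6),
                         premix_fraction = 26 / 110) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_agents < 1L || n_items < 2L || n_sites < 1L) {
    abx_validation_error("fixture_spec: n_agents >= 1, n_items >= 2, n_sites >= 1 required")
  }
  if (length(mass_range_g) != 2L || any(mass_range_g <= 0) ||
      mass_range_g[1] >= mass_range_g[2]) {
    abx_validation_error("fixture_spec: mass_range_g must be positive and increasing")
  }
  if (premix_fraction < 0 || premix_fraction > 1) {
    abx_validation_error("fixture_spec: premix_fraction must be in [0, 1]")
  }
  if (length(material_pool) == 0L || length(doses_per_day_pool) == 0L) {
    abx_validation_error("fixture_spec: pools must be non-empty")
  }
  n_products <- if (is.null(n_products_total)) {
    as.integer(n_agents) * as.integer(n_products_per_agent)
  } else {
    as.integer(n_products_total)
  }
  if (n_products < n_agents) {
    abx_validation_error("fixture_spec: need at least one product per agent")
  }
  structure(list(
    seed = as.integer(seed), n_agents = as.integer(n_agents),
    n_products = n_products, n_items = as.integer(n_items),
    n_sites = as.integer(n_sites), mass_range_g = as.numeric(mass_range_g),
    material_pool = material_pool,
    doses_per_day_pool = as.numeric(doses_per_day_pool),
    premix_fraction = premix_fraction
  ), class = "fixture_spec")
}

#' Study-scale fixture specification
#'
#' The cardinalities of the measurement campaign the package models: 47
#' agents, 110 drug products (26 of them premixes), 102 inactive materials,
#' 2 sites.
#' @param seed integer seed.
#' @return a `fixture_spec`.
#' @export
fixture_spec_study <- function(seed = 1L) {
  fixture_spec(seed = seed, n_agents = 47L, n_products_total = 110L,
               n_items = 102L, n_sites = 2L, premix_fraction = 26 / 110)
}

rint <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))
pick <- function(x, n = 1L, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

#' Generate a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, the inventory CSVs
#'   (`items.csv`, `products.csv`, `bom.csv`, `admin_daily.csv`), the three
#'   usage tables, and a default `scenario.json` are written there with the
#'   canonical writers.
#' @return (invisibly) a list with `bundle` (an `abx_inventory`),
#'   `usage_dot`, `usage_dose`, `usage_product`, and `spec`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- withr::with_seed(spec$seed, generate_fixture_impl(spec))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_inventory(out$bundle, dir)
    u <- out$usage_dot
    writeLines(c("agent,iv_dot", sprintf("%s,%s", u$agent, format_number(u$iv_dot))),
               file.path(dir, "usage_dot.csv"))
    u <- out$usage_dose
    writeLines(c("agent,dose_label,n_doses",
                 sprintf("%s,%s,%s", u$agent, u$dose_label, format_number(u$n_doses))),
               file.path(dir, "usage_dose.csv"))
    u <- out$usage_product
    writeLines(c("product_id,n_doses",
                 sprintf("%s,%s", u$product_id, format_number(u$n_doses))),
               file.path(dir, "usage_product.csv"))
    writeLines('{"default_method":"landfilled","overrides":{}}',
               file.path(dir, "scenario.json"))
  }
  invisible(out)
}

generate_fixture_impl <- function(spec) {
  sites <- sprintf("site%02d", seq_len(spec$n_sites))
  agents <- if (spec$n_agents <= length(AGENT_POOL)) {
    AGENT_POOL[seq_len(spec$n_agents)]
  } else {
    c(AGENT_POOL, sprintf("agent%03d", seq_len(spec$n_agents - length(AGENT_POOL))))
  }

  # --- inactive materials: ~60/40 preparation/administration split --------
  n_prep <- max(1L, round(spec$n_items * 0.6))
  n_admin <- spec$n_items - n_prep
  if (n_admin < 1L) { n_admin <- 1L; n_prep <- spec$n_items - 1L }
  roles <- c(rep("preparation", n_prep), rep("administration", n_admin))
  inactive <- tibble::tibble(
    item_id = sprintf("mat%03d", seq_len(spec$n_items)),
    name = c(pick(PREP_ITEM_NAMES, n_prep, replace = TRUE),
             pick(ADMIN_ITEM_NAMES, n_admin, replace = TRUE)),
    role = roles,
    material = pick(spec$material_pool, spec$n_items, replace = TRUE),
    base_mass = exp(runif(spec$n_items, log(spec$mass_range_g[1]), log(spec$mass_range_g[2])))
  )

  # --- products: round-robin allocation so totals are exact ---------------
  agent_of_product <- agents[((seq_len(spec$n_products) - 1L) %% spec$n_agents) + 1L]
  n_premix <- round(spec$premix_fraction * spec$n_products)
  premix_idx <- sample.int(spec$n_products, n_premix)
  formulation <- ifelse(seq_len(spec$n_products) %in% premix_idx,
                        pick(c("frozen_premix", "nonfrozen_premix"),
                             spec$n_products, replace = TRUE),
                        ifelse(runif(spec$n_products) < 0.2, "minibag_plus",
                               "local_compound"))
  strengths <- c("250 mg", "500 mg", "750 mg", "1 g", "1.5 g", "2 g", "3 g",
                 "4.5 g", "600 mg")
  volumes <- c("50 mL", "100 mL", "250 mL")
  combos <- as.vector(outer(strengths, volumes, paste, sep = "/"))
  dose_label <- character(spec$n_products)
  for (a in unique(agent_of_product)) {
    idx <- which(agent_of_product == a)
    dose_label[idx] <- pick(combos, length(idx))
  }
  products <- tibble::tibble(
    product_id = sprintf("prod%03d", seq_len(spec$n_products)),
    agent = agent_of_product,
    dose_label = dose_label,
    formulation = formulation,
    doses_per_day = pick(spec$doses_per_day_pool, spec$n_products, replace = TRUE)
  )

  # --- drug-specific container + packaging items per product --------------
  is_premix <- products$formulation %in% c("frozen_premix", "nonfrozen_premix")
  drug_items <- tibble::tibble(
    item_id = c(sprintf("%s-container", products$product_id),
                sprintf("%s-box", products$product_id)),
    name = c(ifelse(is_premix, "premix bag (empty and dry)", "drug powder vial (empty)"),
             ifelse(is_premix, "premix corrugated box", "vial paperboard box")),
    role = rep(c("drug_container", "drug_packaging"), each = spec$n_products),
    material = c(ifelse(is_premix, "mixed plastics", "glass"),
                 ifelse(is_premix, "corrugated containers", "mixed paper (general)")),
    base_mass = c(exp(runif(spec$n_products, log(8), log(60))),
                  exp(runif(spec$n_products, log(5), log(90))))
  )

  all_items <- dplyr::bind_rows(inactive, drug_items)
  # per-site masses: uniform +/-10% jitter around base, centigram precision
  item_sites <- do.call(dplyr::bind_rows, lapply(sites, function(s) {
    tibble::tibble(
      item_id = all_items$item_id, name = all_items$name, role = all_items$role,
      material = all_items$material, site = s,
      mass_g = pmax(0.01, round(all_items$base_mass *
                                  runif(nrow(all_items), 0.9, 1.1), 2))
    )
  }))

  # --- bills of materials -------------------------------------------------
  box_fracs <- c(1 / 6, 1 / 10, 1 / 12, 1 / 24)
  prep_ids <- inactive$item_id[inactive$role == "preparation"]
  bom <- do.call(dplyr::bind_rows, lapply(seq_len(spec$n_products), function(i) {
    pid <- products$product_id[i]
    container_count <- if (!is_premix[i] && runif(1) < 0.25) {
      per_dose_count_from_shared_prep(pick(c(2L, 3L)))
    } else 1
    core_prep <- pick(prep_ids, min(length(prep_ids), rint(1L, 2L, 4L)))
    core <- tibble::tibble(
      item_id = c(sprintf("%s-container", pid), sprintf("%s-box", pid), core_prep),
      count_per_dose = c(container_count, pick(box_fracs),
                         rint(length(core_prep), 1L, 2L))
    )
    do.call(dplyr::bind_rows, lapply(sites, function(s) {
      rows <- core
      # occasional site-specific extra preparation item, as seen between
      # institutions with different compounding workflows
      extra <- setdiff(prep_ids, core$item_id)
      if (length(extra) > 0L && runif(1) < 0.3) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(item_id = pick(extra),
                                                      count_per_dose = 1))
      }
      tibble::tibble(product_id = pid, item_id = rows$item_id, site = s,
                     count_per_dose = rows$count_per_dose)
    }))
  }))

  # --- daily administration BOM per site ----------------------------------
  admin_ids <- inactive$item_id[inactive$role == "administration"]
  admin_daily <- do.call(dplyr::bind_rows, lapply(sites, function(s) {
    chosen <- pick(admin_ids, min(length(admin_ids), rint(1L, 3L, 6L)))
    tibble::tibble(site = s, item_id = chosen,
                   count_per_day = rint(length(chosen), 1L, 3L))
  }))

  bundle <- inventory_bundle(item_sites, products, bom, admin_daily)

  usage_dot <- tibble::tibble(agent = agents, iv_dot = rint(length(agents), 0L, 3000L))
  dose_keys <- unique(products[c("agent", "dose_label")])
  usage_dose <- tibble::tibble(agent = dose_keys$agent, dose_label = dose_keys$dose_label,
                               n_doses = rint(nrow(dose_keys), 0L, 5000L))
  usage_product <- tibble::tibble(product_id = products$product_id,
                                  n_doses = rint(nrow(products), 0L, 5000L))

  list(bundle = bundle, usage_dot = usage_dot, usage_dose = usage_dose,
       usage_product = usage_product, spec = spec)
}
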