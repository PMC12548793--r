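#' @name reference-data
#' @title Emission-factor and equivalency reference tables
#'
#' @description
#' Waste emission factors follow the EPA GHG Emission Factors Hub convention:
#' metric tons of CO2 equivalent emitted per short ton of a material managed
#' by a given disposal pathway (landfilled, recycled, or combusted). The
#' packaged table transcribes the Hub's waste factors for the material types
#' that occur in IV-drug packaging, preparation, and administration waste,
#' plus a `"mixed"` fallback class for items that cannot be assigned a single
#' WARM material. Equivalency factors (mtCO2e per mile driven, per gallon of
#' gasoline, ...) turn report totals into interpretable quantities.
NULL

norm_material <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

DISPOSAL_METHODS <- c("landfilled", "recycled", "combusted")

norm_method <- function(x, context = "disposal_method") {
  out <- tolower(trimws(x))
  out[out == "incinerated"] <- "combusted"
  bad <- setdiff(unique(out), DISPOSAL_METHODS)
  if (length(bad) > 0L) {
    abx_validation_error(sprintf(
      "%s: invalid value(s) %s (accepted: %s, plus 'incinerated' as an alias for 'combusted')",
      context, paste(sQuote(bad), collapse = ", "),
      paste(DISPOSAL_METHODS, collapse = ", ")
    ))
  }
  out
}

#' Load a WARM emission-factor table
#'
#' Reads a delimited table with columns `material`, `disposal_method`,
#' `mtco2e_per_short_ton`, `source`. Material names are matched
#' case-insensitively after whitespace normalization; `"incinerated"` is
#' accepted as a spelling of `"combusted"`. Negative factors are permitted
#' (recycling pathways can carry net credits in some factor sets).
#'
#' @param path path to a CSV file.
#' @param provenance version/source tag carried into report headers; defaults
#'   to the distinct values of the file's `source` column.
#' @return a tibble of class `abx_factor_table` with attribute `provenance`.
#' @seealso [get_factor()], [abx_emission_factors()]
#' @export
load_emission_factors <- function(path, provenance = NULL) {
  if (!file.exists(path)) abx_schema_error(sprintf("emission-factor file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  expected <- c("material", "disposal_method", "mtco2e_per_short_ton", "source")
  check_columns(raw, expected, path)
  extra <- setdiff(names(raw), expected)
  if (length(extra) > 0L) {
    abx_schema_error(sprintf("%s: unexpected column(s): %s", path, paste(extra, collapse = ", ")))
  }
  factor_num <- suppressWarnings(as.numeric(raw$mtco2e_per_short_ton))
  bad_rows <- which(is.na(factor_num) | !is.finite(factor_num))
  if (length(bad_rows) > 0L) {
    abx_schema_error(sprintf(
      "%s: non-numeric or non-finite mtco2e_per_short_ton in data row(s) %s",
      path, paste(bad_rows, collapse = ", ")
    ))
  }
  tbl <- tibble::tibble(
    material = norm_material(raw$material),
    disposal_method = norm_method(raw$disposal_method, context = path),
    mtco2e_per_short_ton = factor_num,
    source = raw$source
  )
  if (any(!nzchar(tbl$material))) {
    abx_validation_error(sprintf("%s: empty material name", path))
  }
  dup <- tbl[duplicated(tbl[c("material", "disposal_method")]), c("material", "disposal_method")]
  if (nrow(dup) > 0L) {
    abx_validation_error(sprintf(
      "%s: duplicate (material, disposal_method) key(s): %s", path,
      paste(sprintf("(%s, %s)", dup$material, dup$disposal_method), collapse = "; ")
    ))
  }
  no_landfill <- setdiff(unique(tbl$material), tbl$material[tbl$disposal_method == "landfilled"])
  if (nrow(tbl) > 0L && length(no_landfill) > 0L) {
    abx_validation_error(sprintf(
      "%s: material(s) without a landfilled factor: %s", path,
      paste(no_landfill, collapse = ", ")
    ))
  }
  provenance <- provenance %||% paste(unique(tbl$source), collapse = "; ")
  structure(tbl, class = c("abx_factor_table", class(tbl)), provenance = provenance)
}

#' Packaged emission-factor table
#'
#' The reference table shipped with the package (EPA Hub waste factors,
#' transcribed; see the file's `source` column for provenance).
#' @return an `abx_factor_table`.
#' @export
abx_emission_factors <- function() {
  load_emission_factors(system.file("extdata", "emission_factors.csv", package = "abxcarbon"))
}

#' Factor-table provenance string
#' @param table an `abx_factor_table`.
#' @return character scalar.
#' @export
factor_provenance <- function(table) {
  attr(table, "provenance") %||% "unspecified"
}

#' Canonical emission-factor writer
#'
#' Writes the table sorted by material, then by disposal method in the fixed
#' order landfilled, recycled, combusted, with byte-stable number formatting,
#' so that load -> write -> load is an identity.
#' @param table an `abx_factor_table`.
#' @param path output CSV path.
#' @export
write_emission_factors <- function(table, path) {
  ord <- order(table$material, match(table$disposal_method, DISPOSAL_METHODS))
  tbl <- table[ord, , drop = FALSE]
  lines <- c(
    "material,disposal_method,mtco2e_per_short_ton,source",
    sprintf("%s,%s,%s,%s", tbl$material, tbl$disposal_method,
            format_number(tbl$mtco2e_per_short_ton), tbl$source)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Disposal scenario
#'
#' A scenario is the institution's waste-treatment configuration: a default
#' disposal method (the study sites landfilled all nonhazardous waste, so the
#' default is `"landfilled"`) plus per-material overrides for institutions
#' that recycle or incinerate specific materials.
#'
#' @param default_method one of landfilled, recycled, combusted.
#' @param overrides named list or character vector, material -> method.
#' @return an object of class `abx_scenario`.
#' @examples
#' disposal_scenario()
#' disposal_scenario("landfilled", c("corrugated containers" = "recycled"))
#' @export
disposal_scenario <- function(default_method = "landfilled", overrides = list()) {
  default_method <- norm_method(default_method, context = "default_method")
  overrides <- unlist(overrides)
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abx_validation_error("scenario overrides must be named by material")
    }
    overrides <- setNames(norm_method(overrides, context = "scenario override"),
                          norm_material(names(overrides)))
  } else {
    overrides <- setNames(character(0), character(0))
  }
  structure(list(default_method = default_method, overrides = overrides),
            class = "abx_scenario")
}

#' @export
print.abx_scenario <- function(x, ...) {
  cat("<disposal scenario> default:", x$default_method, "\n")
  if (length(x$overrides) > 0L) {
    cat(sprintf("  %s -> %s\n", names(x$overrides), x$overrides), sep = "")
  }
  invisible(x)
}

#' Read a disposal scenario from JSON
#'
#' Expected shape:
#' `{"default_method": "landfilled", "overrides": {"corrugated containers": "recycled"}}`.
#' @param path JSON file path.
#' @return an `abx_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abx_schema_error(sprintf("scenario file not found: %s", path))
  js <- jsonlite::read_json(path)
  disposal_scenario(js$default_method %||% "landfilled", js$overrides %||% list())
}

#' Check a scenario against a factor table
#'
#' Every override (and the default method for every material in the table)
#' must resolve to a factor present in `table`.
#' @param scenario an `abx_scenario`.
#' @param table an `abx_factor_table`.
#' @return the scenario, invisibly; errors if any pair is unresolvable.
#' @export
validate_scenario <- function(scenario, table) {
  for (m in names(scenario$overrides)) {
    meth <- scenario$overrides[[m]]
    hit <- table$material == m & table$disposal_method == meth
    if (!any(hit)) {
      abx_missing_factor_error(sprintf(
        "scenario override (%s, %s) has no factor in the active table", m, meth
      ))
    }
  }
  invisible(scenario)
}

#' Resolve an emission factor for a material under a scenario
#'
#' The disposal method is the scenario's override for the material if one
#' exists, otherwise the scenario default. A missing (material, method) pair
#' is an error: falling back to `"mixed"` is a classification decision made
#' at inventory entry, never silently at lookup time.
#'
#' @param table an `abx_factor_table`.
#' @param material character vector of WARM material names.
#' @param scenario an `abx_scenario` (default: everything landfilled).
#' @return numeric vector of factors, mtCO2e per short ton.
#' @export
get_factor <- function(table, material, scenario = disposal_scenario()) {
  if (length(material) == 0L) return(numeric(0))
  if (any(is.na(material) | !nzchar(trimws(material)))) {
    abx_validation_error("material name must be non-empty")
  }
  mat <- norm_material(material)
  method <- unname(scenario$overrides[mat])
  method[is.na(method)] <- scenario$default_method
  idx <- match(paste(mat, method, sep = "\r"),
               paste(table$material, table$disposal_method, sep = "\r"))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    abx_missing_factor_error(sprintf(
      "no emission factor for material '%s' under disposal method '%s'",
      mat[miss], method[miss]
    ))
  }
  table$mtco2e_per_short_ton[idx]
}

#' Load GHG equivalency factors
#'
#' Reads `name,unit_label,mtco2e_per_unit` rows; file order is preserved and
#' defines the order of equivalency columns in reports.
#' @param path CSV path.
#' @return tibble with one row per equivalency.
#' @export
load_equivalency_factors <- function(path) {
  if (!file.exists(path)) abx_schema_error(sprintf("equivalency file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("name", "unit_label", "mtco2e_per_unit"), path)
  val <- suppressWarnings(as.numeric(raw$mtco2e_per_unit))
  bad <- which(is.na(val) | !is.finite(val) | val <= 0)
  if (length(bad) > 0L) {
    abx_validation_error(sprintf(
      "%s: mtco2e_per_unit must be a positive number (bad row(s): %s)",
      path, paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(raw$name)) {
    abx_validation_error(sprintf("%s: duplicate equivalency name(s)", path))
  }
  tibble::tibble(name = raw$name, unit_label = raw$unit_label, mtco2e_per_unit = val)
}

#' Packaged equivalency factors
#'
#' Miles driven by an average passenger vehicle, gallons of gasoline consumed,
#' smartphones charged, and tree seedlings grown for 10 years — the EPA
#' equivalencies-calculator set the reports default to. Fully replaceable via
#' [load_equivalency_factors()].
#' @return tibble of equivalency factors.
#' @export
abx_equivalencies <- function() {
  load_equivalency_factors(system.file("extdata", "equivalencies.csv", package = "abxcarbon"))
}

# Byte-stable numeric formatting used by every canonical writer: integers as
# integers, everything else at 15 significant digits.
format_number <- function(x) {
  integral <- is.finite(x) & x == floor(x) & abs(x) < 1e15
  ifelse(integral, sprintf("%.0f", x), sprintf("%.15g", x))
}
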