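#' Import an institution-supplied reference-data export
#'
#' Institutions that have the published reference workbook (or their own
#' measurement campaign) can export its tabs to delimited text and rebuild
#' the full inventory from it. The expected layout is a directory holding
#' the four inventory files (`items.csv`, `products.csv`, `bom.csv`,
#' `admin_daily.csv`, schemas as in [inventory_bundle()]) and, optionally,
#' `reported_emissions.csv` (`product_id,mtco2e_per_dose`) carrying the
#' export's own per-product emission values. When the reported column is
#' present the importer recomputes every product's per-dose emissions and
#' lists discrepancies, so transcription errors surface immediately.
#'
#' The importer is best-effort and isolated: nothing else in the package
#' depends on it, and no copy of the published workbook is bundled.
#'
#' @param dir directory containing the exported delimited files.
#' @param factors an `abx_factor_table` (default: packaged table).
#' @param scenario an `abx_scenario` used for the recomputation check.
#' @param tolerance relative tolerance above which a recomputed-vs-reported
#'   difference is listed as a discrepancy.
#' @return a list of class `abx_supplementary_import`: `bundle`,
#'   `n_products`, `n_inactive_materials`, `comparison` (tibble or `NULL`),
#'   `discrepancies` (subset of `comparison`).
#' @export
import_supplementary <- function(dir, factors = abx_emission_factors(),
                                 scenario = disposal_scenario(),
                                 tolerance = 1e-6) {
  if (!dir.exists(dir)) {
    abx_schema_error(sprintf("supplementary export directory not found: %s", dir))
  }
  needed <- c("items.csv", "products.csv", "bom.csv", "admin_daily.csv")
  present <- list.files(dir)
  missing <- setdiff(needed, present)
  if (length(missing) > 0L) {
    headers <- vapply(file.path(dir, intersect(needed, present)),
                      function(p) paste(names(readr::read_csv(p, n_max = 0,
                                                              show_col_types = FALSE)),
                                        collapse = ","), character(1))
    abx_schema_error(sprintf(
      "unrecognized supplementary layout in %s: missing %s; detected files: %s%s",
      dir, paste(missing, collapse = ", "),
      paste(present, collapse = ", "),
      if (length(headers)) paste0("; detected headers: ",
                                  paste(headers, collapse = " | ")) else ""
    ))
  }
  bundle <- load_inventory(file.path(dir, "items.csv"), file.path(dir, "products.csv"),
                           file.path(dir, "bom.csv"), file.path(dir, "admin_daily.csv"),
                           factors = factors)
  n_inactive <- sum(bundle$items$role %in% c("preparation", "administration"))

  comparison <- NULL
  discrepancies <- NULL
  rep_path <- file.path(dir, "reported_emissions.csv")
  if (file.exists(rep_path)) {
    reported <- readr::read_csv(rep_path, col_types = readr::cols(
      product_id = readr::col_character(), mtco2e_per_dose = readr::col_double()
    ), progress = FALSE)
    check_columns(reported, c("product_id", "mtco2e_per_dose"), rep_path)
    recomputed <- product_factors(bundle, factors, scenario)
    comparison <- dplyr::left_join(
      reported,
      recomputed[c("product_id", "mtco2e_per_dose")],
      by = "product_id", suffix = c("_reported", "_recomputed")
    )
    denom <- pmax(abs(comparison$mtco2e_per_dose_reported), .Machine$double.eps)
    comparison$rel_diff <- abs(comparison$mtco2e_per_dose_recomputed -
                                 comparison$mtco2e_per_dose_reported) / denom
    discrepancies <- comparison[is.na(comparison$rel_diff) |
                                  comparison$rel_diff > tolerance, , drop = FALSE]
  }

  structure(list(bundle = bundle, n_products = nrow(bundle$products),
                 n_inactive_materials = n_inactive, comparison = comparison,
                 discrepancies = discrepancies),
            class = "abx_supplementary_import")
}

#' @export
print.abx_supplementary_import <- function(x, ...) {
  cat(sprintf("<supplementary import> %d drug products, %d inactive materials\n",
              x$n_products, x$n_inactive_materials))
  if (!is.null(x$comparison)) {
    cat(sprintf("  emission recomputation check: %d/%d products within tolerance\n",
                nrow(x$comparison) - nrow(x$discrepancies), nrow(x$comparison)))
    if (nrow(x$discrepancies) > 0L) {
      cat("  discrepancies:", paste(x$discrepancies$product_id, collapse = ", "), "\n")
    }
  }
  invisible(x)
}
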