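#' @name calculators
#' @title DOT, dose, and drug-product emissions calculators
#'
#' @description
#' The calculators turn antimicrobial-use counts into emissions reports. The
#' DOT calculator takes per-agent IV days-of-therapy counts (the shape of an
#' NHSN line-listing export) and multiplies them by per-agent per-DOT
#' factors; the dose calculator works per (agent, dose strength) and the
#' drug-product calculator per product, for programs with more granular
#' data. Every report row carries the CO2-equivalent in short tons and
#' metric tons, the waste mass, and one column per configured equivalency;
#' the totals row is the column-wise sum. Summation is performed in a
#' canonical key-sorted order so totals are bit-stable.
NULL

SALT_TOKENS <- c("hcl", "hydrochloride", "sodium", "sulfate", "sulphate",
                 "phosphate", "succinate", "mesylate", "tartrate", "besylate",
                 "tosylate", "lactobionate")

#' Packaged agent-name synonym table
#' @return tibble with columns `alias`, `canonical`.
#' @export
abx_synonyms <- function() {
  path <- system.file("extdata", "agent_synonyms.csv", package = "abxcarbon")
  raw <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  check_columns(raw, c("alias", "canonical"), path)
  raw
}

basic_normalize <- function(x) {
  out <- tolower(gsub("[[:space:]]+", " ", trimws(x)))
  out <- gsub("\\s*/\\s*", "-", out)   # piperacillin/tazobactam -> piperacillin-tazobactam
  out <- gsub("\\s*-\\s*", "-", out)
  out
}

#' Normalize an antimicrobial agent name
#'
#' Trims and case-folds, converts slash-separated combination names to the
#' hyphenated form, strips trailing salt suffixes (HCl, sodium, sulfate,
#' ...), and applies the packaged synonym table. Names that still do not
#' match a known agent are returned as-is and flagged via the `matched`
#' attribute — never guessed.
#'
#' @param raw character vector of agent names.
#' @param synonyms synonym table (`alias`, `canonical`), default packaged.
#' @param known character vector of known agent names used for flagging;
#'   defaults to the packaged agent pool. `NULL` disables flagging.
#' @return character vector of normalized names with a logical attribute
#'   `matched`.
#' @examples
#' normalize_agent_name("Vancomycin ")             # "vancomycin"
#' normalize_agent_name("piperacillin/tazobactam") # "piperacillin-tazobactam"
#' @export
normalize_agent_name <- function(raw, synonyms = abx_synonyms(), known = abx_agent_pool()) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    abx_validation_error("agent name must be non-empty")
  }
  out <- basic_normalize(raw)
  # synonym table first (explicit aliases win), then generic salt-suffix strip
  hit <- match(out, basic_normalize(synonyms$alias))
  out[!is.na(hit)] <- synonyms$canonical[hit[!is.na(hit)]]
  strip_salt <- function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1L && toks[length(toks)] %in% SALT_TOKENS) {
      toks <- toks[-length(toks)]
    }
    paste(toks, collapse = " ")
  }
  out <- vapply(out, strip_salt, character(1), USE.NAMES = FALSE)
  hit2 <- match(out, basic_normalize(synonyms$alias))
  out[!is.na(hit2)] <- synonyms$canonical[hit2[!is.na(hit2)]]
  matched <- if (is.null(known)) rep(TRUE, length(out)) else out %in% basic_normalize(known)
  attr(out, "matched") <- matched
  out
}

#' Equivalency values for an emissions total
#'
#' Each equivalency value is emissions divided by the per-unit factor: a
#' total of 0.0224 mtCO2e and a miles factor of 3.93e-4 mtCO2e/mile gives
#' ~57 miles driven.
#' @param mtco2e numeric scalar or vector, metric tons CO2e.
#' @param equivalencies tibble from [load_equivalency_factors()].
#' @return for scalar input, a named numeric vector in file order; for vector
#'   input, a tibble with one column per equivalency.
#' @export
equivalency_values <- function(mtco2e, equivalencies = abx_equivalencies()) {
  vals <- lapply(equivalencies$mtco2e_per_unit, function(f) mtco2e / f)
  if (length(mtco2e) == 1L) {
    return(setNames(vapply(vals, identity, numeric(1)), equivalencies$name))
  }
  tibble::as_tibble(setNames(vals, equivalencies$name))
}

suggest_candidates <- function(x, candidates) {
  if (length(candidates) == 0L) return(character(0))
  d <- utils::adist(x, candidates, partial = FALSE)[1, ]
  head(candidates[order(d)], 3L)
}

scenario_string <- function(scenario) {
  if (is.null(scenario)) return("default=landfilled")
  s <- paste0("default=", scenario$default_method)
  if (length(scenario$overrides) > 0L) {
    s <- paste0(s, "; ", paste(names(scenario$overrides), scenario$overrides,
                               sep = "=", collapse = "; "))
  }
  s
}

# Shared assembly: rows come in as (key, quantity, mtco2e, waste_g); sort by
# key (radix order, locale-independent), derive unit columns and
# equivalencies, and sum each column for the totals block.
build_report <- function(rows, equivalencies, metadata) {
  ord <- order(rows$key, method = "radix")
  rows <- rows[ord, , drop = FALSE]
  out <- tibble::tibble(
    key = rows$key,
    quantity = rows$quantity,
    co2e_short_tons = convert_mass(rows$mtco2e, "metric_ton", "short_ton"),
    co2e_metric_tons = rows$mtco2e,
    waste_mass_short_tons = rows$waste_g / GRAMS_PER_SHORT_TON,
    waste_mass_g = rows$waste_g
  )
  for (i in seq_len(nrow(equivalencies))) {
    out[[equivalencies$name[i]]] <- rows$mtco2e / equivalencies$mtco2e_per_unit[i]
  }
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  totals <- tibble::as_tibble(c(
    list(key = "TOTAL"),
    lapply(setNames(num_cols, num_cols), function(cn) sum(out[[cn]]))
  ))
  if (totals$co2e_metric_tons < 0) {
    rlang::warn("report total is net-negative (recycling credits exceed emissions)")
  }
  structure(list(rows = out, totals = totals,
                 equivalency_names = equivalencies$name, metadata = metadata),
            class = "abx_report")
}

check_usage_quantity <- function(q, label) {
  q <- as.numeric(q)
  if (any(is.na(q) | !is.finite(q))) abx_validation_error(sprintf("%s must be numeric", label))
  if (any(q < 0)) abx_validation_error(sprintf("%s must be >= 0", label))
  q
}

#' DOT-calculator report
#'
#' @param usage tibble/data.frame with columns `agent`, `iv_dot` (per-agent IV
#'   days of therapy, e.g. from an NHSN line listing).
#' @param factors_by_agent tibble from [agent_factors()].
#' @param equivalencies tibble from [load_equivalency_factors()].
#' @param scenario the `abx_scenario` the factors were computed under (for the
#'   report header only).
#' @param provenance emission-factor provenance string for the header.
#' @param created optional timestamp string for the header; omit for
#'   byte-reproducible reports.
#' @param synonyms,known passed to [normalize_agent_name()].
#' @return an `abx_report`.
#' @export
compute_dot_report <- function(usage, factors_by_agent,
                               equivalencies = abx_equivalencies(),
                               scenario = NULL, provenance = "unspecified",
                               created = NULL, synonyms = abx_synonyms(),
                               known = NULL) {
  usage <- tibble::as_tibble(usage)
  check_columns(usage, c("agent", "iv_dot"), "usage")
  q <- check_usage_quantity(usage$iv_dot, "iv_dot")
  fk <- normalize_agent_name(factors_by_agent$agent, synonyms, known = NULL)
  uk <- normalize_agent_name(usage$agent, synonyms, known = NULL)
  idx <- match(uk, fk)
  if (anyNA(idx)) {
    missing <- uk[is.na(idx)][1]
    near <- suggest_candidates(missing, factors_by_agent$agent)
    abx_unmatched_key_error(sprintf(
      "no per-DOT factor for agent '%s'%s", missing,
      if (length(near)) paste0(" (closest matches: ", paste(near, collapse = ", "), ")") else ""
    ))
  }
  rows <- tibble::tibble(
    key = fk[idx],
    quantity = q,
    mtco2e = q * factors_by_agent$mtco2e_per_dot[idx],
    waste_g = q * factors_by_agent$waste_g_per_dot[idx]
  )
  build_report(rows, equivalencies, list(
    mode = "dot", scenario = scenario_string(scenario),
    provenance = provenance, created = created
  ))
}

#' Dose-calculator report
#'
#' @param usage tibble with columns `agent`, `dose_label`, `n_doses`.
#' @param factors_by_dose tibble from [agent_dose_factors()].
#' @inheritParams compute_dot_report
#' @return an `abx_report` keyed by `"agent | dose_label"`.
#' @export
compute_dose_report <- function(usage, factors_by_dose,
                                equivalencies = abx_equivalencies(),
                                scenario = NULL, provenance = "unspecified",
                                created = NULL, synonyms = abx_synonyms()) {
  usage <- tibble::as_tibble(usage)
  check_columns(usage, c("agent", "dose_label", "n_doses"), "usage")
  q <- check_usage_quantity(usage$n_doses, "n_doses")
  fk <- paste(normalize_agent_name(factors_by_dose$agent, synonyms, known = NULL),
              trimws(factors_by_dose$dose_label), sep = " | ")
  uk <- paste(normalize_agent_name(usage$agent, synonyms, known = NULL),
              trimws(usage$dose_label), sep = " | ")
  idx <- match(uk, fk)
  if (anyNA(idx)) {
    missing <- uk[is.na(idx)][1]
    near <- suggest_candidates(missing, fk)
    abx_unmatched_key_error(sprintf(
      "no per-dose factor for '%s'%s", missing,
      if (length(near)) paste0(" (closest matches: ", paste(near, collapse = ", "), ")") else ""
    ))
  }
  rows <- tibble::tibble(
    key = fk[idx],
    quantity = q,
    mtco2e = q * factors_by_dose$mtco2e_per_dose[idx],
    waste_g = q * factors_by_dose$waste_g_per_dose[idx]
  )
  build_report(rows, equivalencies, list(
    mode = "dose", scenario = scenario_string(scenario),
    provenance = provenance, created = created
  ))
}

#' Drug-product-calculator report
#'
#' Uses un-averaged per-product results (each product keeps its own factor;
#' no agent-level averaging).
#' @param usage tibble with columns `product_id`, `n_doses`.
#' @param factors_by_product tibble from [product_factors()].
#' @inheritParams compute_dot_report
#' @return an `abx_report` keyed by `product_id`.
#' @export
compute_product_report <- function(usage, factors_by_product,
                                   equivalencies = abx_equivalencies(),
                                   scenario = NULL, provenance = "unspecified",
                                   created = NULL) {
  usage <- tibble::as_tibble(usage)
  check_columns(usage, c("product_id", "n_doses"), "usage")
  q <- check_usage_quantity(usage$n_doses, "n_doses")
  idx <- match(usage$product_id, factors_by_product$product_id)
  if (anyNA(idx)) {
    missing <- usage$product_id[is.na(idx)][1]
    near <- suggest_candidates(missing, factors_by_product$product_id)
    abx_unmatched_key_error(sprintf(
      "unknown product_id '%s'%s", missing,
      if (length(near)) paste0(" (closest matches: ", paste(near, collapse = ", "), ")") else ""
    ))
  }
  rows <- tibble::tibble(
    key = usage$product_id,
    quantity = q,
    mtco2e = q * factors_by_product$mtco2e_per_dose[idx],
    waste_g = q * factors_by_product$waste_g_per_dose[idx]
  )
  build_report(rows, equivalencies, list(
    mode = "product", scenario = scenario_string(scenario),
    provenance = provenance, created = created
  ))
}

#' @export
print.abx_report <- function(x, ...) {
  cat(sprintf("<abx_report> mode=%s, %d row(s)\n", x$metadata$mode, nrow(x$rows)))
  cat(sprintf("  total: %.6g mtCO2e (%.6g short tons), %.6g g waste\n",
              x$totals$co2e_metric_tons, x$totals$co2e_short_tons, x$totals$waste_mass_g))
  for (nm in x$equivalency_names) {
    cat(sprintf("  = %.4g %s\n", x$totals[[nm]], nm))
  }
  invisible(x)
}
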