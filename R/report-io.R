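#' @name report-io
#' @title Deterministic report serialization
#'
#' @description
#' Reports are written with a fixed column order (key, quantity, CO2e, waste
#' mass, then the equivalencies in factor-file order), metadata header lines,
#' full-precision numbers plus 2-decimal display companions, and a trailing
#' totals row. The writer is byte-deterministic so golden-file regression
#' comparison is meaningful.
NULL

csv_field <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

report_numeric_cols <- function(report) {
  setdiff(names(report$rows)[vapply(report$rows, is.numeric, logical(1))], "quantity")
}

#' Write an emissions report
#'
#' @param report an `abx_report`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    meta <- Filter(Negate(is.null), report$metadata)
    jsonlite::write_json(
      list(metadata = meta, equivalency_names = report$equivalency_names,
           rows = report$rows, totals = report$totals),
      path, auto_unbox = TRUE, digits = NA
    )
    return(invisible(path))
  }
  disp_cols <- report_numeric_cols(report)
  header_meta <- c(
    "# abxcarbon report",
    sprintf("# mode: %s", report$metadata$mode),
    sprintf("# scenario: %s", report$metadata$scenario),
    sprintf("# provenance: %s", report$metadata$provenance),
    if (!is.null(report$metadata$created)) sprintf("# created: %s", report$metadata$created)
  )
  all_rows <- dplyr::bind_rows(report$rows, report$totals)
  cols <- names(report$rows)
  header <- paste(c(csv_field(cols), csv_field(paste0(disp_cols, " (2dp)"))), collapse = ",")
  body <- vapply(seq_len(nrow(all_rows)), function(i) {
    full <- vapply(cols, function(cn) {
      v <- all_rows[[cn]][i]
      if (is.numeric(v)) format_number(v) else csv_field(v)
    }, character(1))
    disp <- vapply(disp_cols, function(cn) sprintf("%.2f", all_rows[[cn]][i]), character(1))
    paste(c(full, disp), collapse = ",")
  }, character(1))
  writeLines(c(header_meta, header, body), path)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return an `abx_report` (display companion columns are not retained).
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    js <- jsonlite::fromJSON(path)
    rows <- tibble::as_tibble(js$rows)
    totals <- tibble::as_tibble(js$totals)
    return(structure(list(rows = rows, totals = totals,
                          equivalency_names = js$equivalency_names,
                          metadata = as.list(js$metadata)),
                     class = "abx_report"))
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines[-1]) {
    kv <- sub("^# ", "", ml)
    k <- sub(":.*$", "", kv)
    metadata[[k]] <- sub("^[^:]*: ", "", kv)
  }
  tbl <- readr::read_csv(I(paste(lines[!grepl("^#", lines)], collapse = "\n")),
                         col_types = readr::cols(key = readr::col_character(),
                                                 .default = readr::col_double()),
                         progress = FALSE)
  tbl <- tbl[, !grepl(" \\(2dp\\)$", names(tbl)), drop = FALSE]
  is_total <- tbl$key == "TOTAL"
  fixed <- c("key", "quantity", "co2e_short_tons", "co2e_metric_tons",
             "waste_mass_short_tons", "waste_mass_g")
  structure(list(rows = tbl[!is_total, , drop = FALSE],
                 totals = tbl[is_total, , drop = FALSE],
                 equivalency_names = setdiff(names(tbl), fixed),
                 metadata = metadata),
            class = "abx_report")
}
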