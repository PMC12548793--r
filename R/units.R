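#' Mass unit conversion
#'
#' Converts a mass between grams, kilograms, metric tons, and short tons.
#' Item weights are recorded in grams, EPA WARM emission factors are stated
#' per short ton of waste, and all internal emissions arithmetic is kept in
#' metric tons CO2e, so explicit conversions appear throughout the package.
#'
#' Definitions used: 1 short ton = 907184.74 g (2000 lb), 1 metric ton =
#' 1e6 g, both exact.
#'
#' @param value numeric vector of masses.
#' @param from,to one of `"gram"`, `"kilogram"`, `"metric_ton"`, `"short_ton"`.
#' @return numeric vector, `value` expressed in unit `to`.
#' @examples
#' convert_mass(907184.74, "gram", "short_ton") # 1
#' convert_mass(1, "metric_ton", "short_ton")   # 1.102311...
#' @export
convert_mass <- function(value, from, to) {
  grams <- c(
    gram = 1,
    kilogram = 1000,
    metric_ton = 1e6,
    short_ton = 907184.74
  )
  if (!is.character(from) || length(from) != 1L || is.na(grams[from])) {
    abx_validation_error(sprintf("unknown mass unit '%s'", as.character(from)[1]))
  }
  if (!is.character(to) || length(to) != 1L || is.na(grams[to])) {
    abx_validation_error(sprintf("unknown mass unit '%s'", as.character(to)[1]))
  }
  if (!is.numeric(value)) abx_validation_error("mass value must be numeric")
  if (from == to) return(value)
  value * (grams[[from]] / grams[[to]])
}

GRAMS_PER_SHORT_TON <- 907184.74
GRAMS_PER_METRIC_TON <- 1e6
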