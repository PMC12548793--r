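# Independent reference implementation: plain base-R loops over the raw
# tables, no shared code with the vectorized engine. Used to cross-check
# every engine quantity on small inventories.

GST <- 907184.74

oracle_factor <- function(factors, material, scenario) {
  method <- unname(scenario$overrides[material])
  if (length(method) == 0L || is.na(method)) method <- scenario$default_method
  hit <- which(factors$material == material & factors$disposal_method == method)
  stopifnot(length(hit) == 1L)
  factors$mtco2e_per_short_ton[hit]
}

# bundle: an abx_inventory; factors: abx_factor_table; scenario: abx_scenario.
# Returns per-product and per-agent tables computed by brute force.
oracle_totals <- function(bundle, factors, scenario = disposal_scenario()) {
  items <- as.data.frame(bundle$item_sites)
  prods <- as.data.frame(bundle$products)
  bom <- as.data.frame(bundle$bom)
  admin <- as.data.frame(bundle$admin_daily)

  mean_mass <- function(id) mean(items$mass_g[items$item_id == id])
  item_material <- function(id) items$material[items$item_id == id][1]

  admin_site <- function(s) {
    mt <- 0; g <- 0
    rows <- admin[admin$site == s, ]
    for (i in seq_len(nrow(rows))) {
      m <- mean_mass(rows$item_id[i])
      f <- oracle_factor(factors, item_material(rows$item_id[i]), scenario)
      mt <- mt + rows$count_per_day[i] * (m / GST) * f
      g <- g + rows$count_per_day[i] * m
    }
    c(mt = mt, g = g)
  }

  out <- NULL
  for (p in seq_len(nrow(prods))) {
    pid <- prods$product_id[p]
    sites <- unique(bom$site[bom$product_id == pid])
    dose_mt <- c(); dose_g <- c(); dot_mt <- c(); dot_g <- c()
    for (s in sites) {
      rows <- bom[bom$product_id == pid & bom$site == s, ]
      mt <- 0; g <- 0
      for (i in seq_len(nrow(rows))) {
        m <- mean_mass(rows$item_id[i])
        f <- oracle_factor(factors, item_material(rows$item_id[i]), scenario)
        mt <- mt + rows$count_per_dose[i] * (m / GST) * f
        g <- g + rows$count_per_dose[i] * m
      }
      a <- admin_site(s)
      dose_mt <- c(dose_mt, mt); dose_g <- c(dose_g, g)
      dot_mt <- c(dot_mt, mt * prods$doses_per_day[p] + a["mt"])
      dot_g <- c(dot_g, g * prods$doses_per_day[p] + a["g"])
    }
    out <- rbind(out, data.frame(
      product_id = pid, agent = prods$agent[p], dose_label = prods$dose_label[p],
      mtco2e_per_dose = mean(dose_mt), waste_g_per_dose = mean(dose_g),
      mtco2e_per_dot = mean(dot_mt), waste_g_per_dot = mean(dot_g)
    ))
  }
  agents <- unique(out$agent)
  ag <- NULL
  for (a in agents) {
    sub <- out[out$agent == a, ]
    ag <- rbind(ag, data.frame(agent = a,
                               mtco2e_per_dot = mean(sub$mtco2e_per_dot),
                               waste_g_per_dot = mean(sub$waste_g_per_dot),
                               n_products_averaged = nrow(sub)))
  }
  list(products = out[order(out$product_id), ], agents = ag[order(ag$agent), ])
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
}
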