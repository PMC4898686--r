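#' Allocate each stratum to its higher-value land use
#'
#' For every landscape stratum, computes the annualised REDD+ NPV from its
#' carbon class and the reference level of its suitability class, compares
#' it with the oil-palm opportunity cost for that suitability, and awards
#' the stratum to REDD+ when its NPV is equal or higher (ties favour
#' REDD+). Comparisons use unrounded NPVs.
#'
#' @param strata data frame with columns `extent_ha`, `carbon_class`,
#'   `suitability` (and optionally `stratum_id`, `tenure`).
#' @param scenario a [scenario()].
#' @param references reference levels by suitability, as returned by
#'   [reference_levels()].
#' @param oilpalm_npvs named vector of annualised oil-palm NPVs by
#'   suitability (USD/ha/yr), default the published benchmarks
#'   [oilpalm_npv_benchmarks()].
#' @return The input strata with added columns `redd_npv`, `oilpalm_npv`
#'   (USD/ha/yr, unrounded) and `winner` (`"redd"` or `"oilpalm"`).
#' @export
#' @examples
#' land <- data.frame(extent_ha = c(100, 100),
#'                    carbon_class = c(6, 1),
#'                    suitability = c("under25", "full_stand"))
#' allocate_landscape(land, scenario(3, "upfront"))
allocate_landscape <- function(strata, scenario,
                               references = reference_levels(),
                               oilpalm_npvs = oilpalm_npv_benchmarks()) {
  stopifnot(inherits(scenario, "redd_scenario"))
  if (!"suitability" %in% names(strata))
    stopf("strata must carry a suitability column")
  validate_strata(strata)
  if (!all(strata$suitability %in% references$suitability) ||
      !all(strata$suitability %in% names(oilpalm_npvs)))
    stopf("unknown suitability class")
  ref <- references$mgc_per_ha[match(strata$suitability,
                                     references$suitability)]
  net <- net_co2e_per_ha(strata$carbon_class, ref, scenario$co2e_factor)
  strata$redd_npv <- vapply(net, redd_annual_npv, numeric(1),
                            scenario = scenario)
  strata$oilpalm_npv <- unname(oilpalm_npvs[strata$suitability])
  strata$winner <- ifelse(strata$redd_npv >= strata$oilpalm_npv,
                          "redd", "oilpalm")
  strata
}

#' Carbon finance required to secure a carbon stock
#'
#' Converts a carbon stock to CO2-equivalent and to the offset funds needed
#' at a given carbon price. Funds are computed from the *unrounded* CO2e
#' and each reported figure is rounded once, half away from zero — the
#' single rounding rule under which all published fund cells reproduce
#' (including half-dollar cases).
#'
#' @param mgc carbon stock, MgC.
#' @param carbon_price USD per MgCO2e.
#' @param co2e_factor MgCO2e per MgC, default 3.67.
#' @return Data frame with `mgc`, `mgco2e` (rounded) and `funds_usd`
#'   (rounded). Vectorised over `mgc` and `carbon_price`.
#' @export
#' @examples
#' carbon_finance(2495980, 3)  # 9,160,247 MgCO2e, $27,480,740
carbon_finance <- function(mgc, carbon_price, co2e_factor = 3.67) {
  if (any(mgc < 0)) stopf("mgc must be >= 0")
  if (any(carbon_price <= 0)) stopf("carbon_price must be positive")
  co2e <- mgc * co2e_factor
  data.frame(mgc = mgc,
             mgco2e = round_half_up(co2e),
             funds_usd = round_half_up(co2e * carbon_price))
}

#' Landscape roll-up of a REDD+ allocation
#'
#' Sums extent and mid-point carbon over the REDD+-winning strata and
#' derives the carbon finance required: CO2e is carbon times the molecular
#' factor, and funds are price times the *unrounded* CO2e, each rounded
#' once (half away from zero) for reporting. The landscape share is the
#' winning extent as an integer percentage of the total extent.
#'
#' @param allocated output of [allocate_landscape()].
#' @param scenario the [scenario()] used for the allocation.
#' @return One-row data frame: `price`, `stance`, `extent_ha`,
#'   `pct_of_landscape`, `total_mgc`, `total_mgco2e`, `funds_usd`.
#' @export
allocation_rollup <- function(allocated, scenario) {
  stopifnot(inherits(scenario, "redd_scenario"))
  if (!"winner" %in% names(allocated))
    stopf("allocated must come from allocate_landscape()")
  win <- allocated[allocated$winner == "redd", , drop = FALSE]
  total_extent <- sum(allocated$extent_ha)
  extent <- sum(win$extent_ha)
  mgc <- if (nrow(win)) sum(stratum_carbon(win$extent_ha, win$carbon_class)) else 0
  fin <- carbon_finance(mgc, scenario$carbon_price, scenario$co2e_factor)
  data.frame(
    price = scenario$carbon_price,
    stance = scenario$stance,
    extent_ha = extent,
    pct_of_landscape = if (total_extent > 0)
      round_half_up(100 * extent / total_extent) else 0,
    total_mgc = mgc,
    total_mgco2e = fin$mgco2e,
    funds_usd = fin$funds_usd
  )
}

#' Allocation summary over a scenario grid
#'
#' Runs [allocate_landscape()] and [allocation_rollup()] for every
#' combination of carbon price and payment stance at one discount rate.
#'
#' @inheritParams allocate_landscape
#' @param prices carbon prices, USD/MgCO2e.
#' @param stances payment stances.
#' @param rate annual discount rate.
#' @return Data frame with one roll-up row per stance x price.
#' @export
allocation_table <- function(strata,
                             prices = c(3, 7.8, 15, 30),
                             stances = c("upfront", "staggered"),
                             rate = 0.11,
                             references = reference_levels(),
                             oilpalm_npvs = oilpalm_npv_benchmarks()) {
  grid <- expand.grid(price = prices, stance = stances,
                      stringsAsFactors = FALSE)[, 2:1]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sc <- scenario(grid$price[i], grid$stance[i], discount_rate = rate)
    allocation_rollup(
      allocate_landscape(strata, sc, references, oilpalm_npvs), sc)
  }))
  rownames(out) <- NULL
  out
}
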