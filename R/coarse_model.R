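#' Coarse-scale REDD+ versus oil-palm comparison
#'
#' The deliberately coarse single-average model: one landscape-average
#' forest carbon density (156 MgC/ha) against one mature oil-palm carbon
#' value (52 MgC/ha) and one full-stand opportunity cost (594 USD/ha/yr).
#' Delegates to the same discounted cash-flow engine as the fine-scale
#' models — net CO2e is `(forest - reference) * co2e_factor` and each
#' price/stance cell is an ordinary [redd_annual_npv()] evaluation — so
#' there is no second arithmetic path.
#'
#' At the default 11% rate the eight cells annualise (rounded) to
#' 37/103/202/409 USD/ha/yr upfront and 24/68/135/274 staggered, all below
#' the 594 oil-palm benchmark: at coarse scale REDD+ never wins.
#'
#' @param prices carbon prices, USD/MgCO2e.
#' @param stances payment stances to evaluate.
#' @param rate annual discount rate.
#' @param forest_mgc_per_ha landscape-average forest carbon, MgC/ha.
#' @param oilpalm_reference_mgc_per_ha mature oil-palm carbon, MgC/ha.
#' @param oilpalm_annual_npv_usd oil-palm opportunity cost, USD/ha/yr.
#' @param co2e_factor MgCO2e per MgC.
#' @return Data frame with one row per stance x price: `stance`, `price`,
#'   `redd_annual_npv` (rounded USD/ha/yr), `oilpalm_annual_npv`, `winner`.
#' @export
#' @examples
#' coarse_comparison()
coarse_comparison <- function(prices = c(3, 7.8, 15, 30),
                              stances = c("upfront", "staggered"),
                              rate = 0.11,
                              forest_mgc_per_ha = 156,
                              oilpalm_reference_mgc_per_ha = 52,
                              oilpalm_annual_npv_usd = 594,
                              co2e_factor = 3.67) {
  if (forest_mgc_per_ha < 0 || oilpalm_reference_mgc_per_ha < 0)
    stopf("carbon densities must be >= 0")
  net <- (forest_mgc_per_ha - oilpalm_reference_mgc_per_ha) * co2e_factor
  grid <- expand.grid(price = prices, stance = stances,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$redd_annual_npv <- mapply(function(st, p) {
    round_half_up(redd_annual_npv(
      net, scenario(p, st, discount_rate = rate, co2e_factor = co2e_factor)))
  }, grid$stance, grid$price)
  grid$oilpalm_annual_npv <- oilpalm_annual_npv_usd
  # tie goes to REDD+ ("equal or higher"), as in the fine-scale allocation
  grid$winner <- ifelse(grid$redd_annual_npv >= grid$oilpalm_annual_npv,
                        "redd", "oilpalm")
  rownames(grid) <- NULL
  grid
}
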