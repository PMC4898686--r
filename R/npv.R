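#' REDD+ payment scenario
#'
#' Bundles the economic constants of one REDD+ evaluation: carbon price,
#' payment stance, discount rate, horizon, implementation costs and the
#' carbon-to-CO2e conversion factor.
#'
#' Default study values: carbon prices of 3, 7.8, 15 and 30 USD/MgCO2e
#' (voluntary low/mid/high and compliance); discount rates 5%, 8%, 11%
#' (industry rate, the headline) and 14%; establishment cost 25 USD/ha in
#' year 1; running cost 10 USD/ha in years 2..25; molecular conversion
#' factor 3.67 MgCO2e per MgC.
#'
#' @param carbon_price USD per MgCO2e, `> 0`.
#' @param stance payment stance: `"upfront"` (all carbon revenue in year 1)
#'   or `"staggered"` (50% in year 1, remainder in equal annual payments
#'   over years 2..horizon).
#' @param discount_rate annual discount rate as a fraction in (0, 1).
#' @param horizon_yr project horizon in years, default 25.
#' @param establish_cost one-off year-1 cost, USD/ha.
#' @param run_cost annual cost in years 2..horizon, USD/ha.
#' @param co2e_factor MgCO2e per MgC, default 3.67.
#' @return An object of class `redd_scenario` (a validated list).
#' @export
#' @examples
#' scenario(3, "upfront")
scenario <- function(carbon_price,
                     stance = c("upfront", "staggered"),
                     discount_rate = 0.11,
                     horizon_yr = 25,
                     establish_cost = 25,
                     run_cost = 10,
                     co2e_factor = 3.67) {
  stance <- match.arg(stance)
  if (!is.numeric(carbon_price) || length(carbon_price) != 1L ||
      carbon_price <= 0)
    stopf("carbon_price must be a single positive number")
  if (discount_rate <= 0 || discount_rate >= 1)
    stopf("discount_rate must lie in (0, 1)")
  if (horizon_yr < 1 || horizon_yr != round(horizon_yr))
    stopf("horizon_yr must be a positive integer")
  if (establish_cost < 0 || run_cost < 0) stopf("costs must be >= 0")
  if (co2e_factor <= 0) stopf("co2e_factor must be positive")
  structure(list(carbon_price = carbon_price, stance = stance,
                 discount_rate = discount_rate, horizon_yr = horizon_yr,
                 establish_cost = establish_cost, run_cost = run_cost,
                 co2e_factor = co2e_factor),
            class = "redd_scenario")
}

#' @export
print.redd_scenario <- function(x, ...) {
  cat(sprintf(
    "REDD+ scenario: $%g/MgCO2e, %s payment, %g%% discount, %d yr\n",
    x$carbon_price, x$stance, 100 * x$discount_rate, x$horizon_yr))
  invisible(x)
}

#' Net present value of a cash-flow series
#'
#' End-of-year convention: the year-`t` flow is discounted by `(1+rate)^-t`,
#' so the first flow is discounted one full period.
#'
#' @param cashflows numeric vector of annual flows (USD/ha), year 1 first.
#' @param rate annual discount rate, `> -1`.
#' @return Present value (USD/ha).
#' @export
#' @examples
#' npv(rep(1, 25), 0.11)  # 25-year annuity factor at 11%
npv <- function(cashflows, rate) {
  if (length(cashflows) == 0L) stopf("cashflows must be non-empty")
  if (any(!is.finite(cashflows))) stopf("cashflows must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= -1)
    stopf("rate must be a single number > -1")
  sum(cashflows / (1 + rate)^seq_along(cashflows))
}

#' Creditable net CO2-equivalent per hectare
#'
#' Forest carbon above the oil-palm reference level, converted to CO2e:
#' `(class midpoint - reference) * co2e_factor`. Negative where the
#' reference exceeds the class mid-point (low-carbon forest on land suited
#' to full-stand palm), in which case REDD+ revenue is negative — no
#' flooring at zero.
#'
#' @param carbon_class class index in 1:6.
#' @param reference_mgc reference level, MgC/ha.
#' @param co2e_factor MgCO2e per MgC, default 3.67.
#' @return Net creditable CO2e, MgCO2e/ha. Vectorised.
#' @export
#' @examples
#' net_co2e_per_ha(3, 46)  # (150 - 46) * 3.67
net_co2e_per_ha <- function(carbon_class, reference_mgc, co2e_factor = 3.67) {
  if (any(reference_mgc < 0)) stopf("reference_mgc must be >= 0")
  (class_midpoint(carbon_class) - reference_mgc) * co2e_factor
}

#' REDD+ cash-flow series for one hectare
#'
#' Upfront stance: all carbon revenue (`net_co2e * price`) in year 1 net of
#' the establishment cost, then running costs alone. Staggered stance: half
#' the carbon revenue in year 1, the other half in equal payments across
#' years 2..horizon, with the same cost structure. Undiscounted revenue is
#' identical across stances.
#'
#' @param net_co2e creditable CO2e, MgCO2e/ha (may be negative).
#' @param scenario a [scenario()].
#' @return Numeric vector of length `horizon_yr` (USD/ha by year).
#' @export
redd_cashflows <- function(net_co2e, scenario) {
  stopifnot(inherits(scenario, "redd_scenario"))
  if (length(net_co2e) != 1L || !is.finite(net_co2e))
    stopf("net_co2e must be a single finite number")
  T <- scenario$horizon_yr
  revenue <- net_co2e * scenario$carbon_price
  cf <- rep(-scenario$run_cost, T)
  if (scenario$stance == "upfront") {
    cf[1] <- revenue - scenario$establish_cost
  } else {
    cf[1] <- 0.5 * revenue - scenario$establish_cost
    if (T > 1) cf[2:T] <- 0.5 * revenue / (T - 1) - scenario$run_cost
  }
  cf
}

#' Annualised REDD+ net present value
#'
#' The 25-year NPV of [redd_cashflows()] divided by the horizon, in
#' USD/ha/yr. Returned unrounded; reports round half away from zero (the
#' coarse-model headline values 37/103/202/409 upfront and 24/68/135/274
#' staggered arise this way).
#'
#' @inheritParams redd_cashflows
#' @return Annualised NPV, USD/ha/yr.
#' @export
#' @examples
#' s <- scenario(3, "upfront", 0.11)
#' redd_annual_npv(net_co2e_per_ha(3, 52), s)
redd_annual_npv <- function(net_co2e, scenario) {
  npv(redd_cashflows(net_co2e, scenario), scenario$discount_rate) /
    scenario$horizon_yr
}
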