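#' Oil-palm planting densities by suitability class
#'
#' Upper-range palms per hectare for each oil-palm suitability class:
#' 136 palms/ha at full stand (100% capacity), 68 at 50% capacity, 34 at
#' 25% capacity.
#'
#' @return Named numeric vector (palms/ha) over the suitability classes.
#' @export
palm_planting_density <- function() {
  c(full_stand = 136, under50 = 68, under25 = 34)
}

#' Complete a partially observed per-palm carbon age series
#'
#' Field data cover only some palm ages between 1 and 19 years. Gaps are
#' filled deterministically: a single missing year takes the mean of the
#' flanking observed years; runs of consecutive missing years are filled
#' with equal annual increments (linear interpolation between the flanking
#' observations); years before the first observation are back-filled with
#' the first observed value; and the last observed value is held constant
#' out to the 25-year crop lifespan (the oldest palms measured are 19, so
#' years 20-25 reuse the year-19 value).
#'
#' @param observed either a named numeric vector (names = ages in years) or
#'   a data frame with columns `age_yr` and `mgc_per_palm`. At least two
#'   observed ages are required. Ages must lie in 1..19 and values be
#'   non-negative.
#' @param lifespan_yr crop lifespan, default 25 years.
#' @return Numeric vector of length `lifespan_yr`: per-palm carbon (MgC) for
#'   ages `1:lifespan_yr`. Observed ages are reproduced exactly.
#' @export
#' @examples
#' complete_palm_series(c(`2` = 0.1, `4` = 0.3))[3]  # 0.2
complete_palm_series <- function(observed, lifespan_yr = 25) {
  if (is.data.frame(observed)) {
    if (!all(c("age_yr", "mgc_per_palm") %in% names(observed)))
      stopf("observed needs columns age_yr, mgc_per_palm")
    ages <- observed$age_yr
    vals <- observed$mgc_per_palm
  } else {
    ages <- as.numeric(names(observed))
    vals <- as.numeric(observed)
  }
  if (any(is.na(ages)) || any(ages < 1) || any(ages > 19) ||
      any(ages != round(ages)))
    stopf("observed ages must be integers in 1..19")
  if (anyDuplicated(ages)) stopf("duplicate observed ages")
  if (length(ages) < 2L)
    stopf("at least two observed ages are needed to complete the series")
  if (any(vals < 0)) stopf("per-palm carbon must be >= 0")
  ord <- order(ages)
  ages <- ages[ord]; vals <- vals[ord]
  # linear interpolation fills both the single-gap (mean of flanking years)
  # and consecutive-gap (equal increments) rules; rule = 2 back-fills before
  # the first observation and holds the last observation afterwards
  filled <- stats::approx(ages, vals, xout = 1:19, rule = 2)$y
  c(filled, rep(filled[19], lifespan_yr - 19))
}

#' Time-averaged oil-palm carbon reference level
#'
#' Mean per-palm carbon over the 25-year crop lifespan multiplied by the
#' planting density, giving the per-hectare reference level against which
#' avoided-deforestation credits are netted.
#'
#' @param complete_series numeric vector of per-palm MgC for every year of
#'   the lifespan (see [complete_palm_series()]).
#' @param palms_per_ha planting density (palms/ha).
#' @return Reference level in MgC/ha.
#' @export
time_averaged_reference <- function(complete_series, palms_per_ha) {
  if (any(!is.finite(complete_series)) || any(complete_series < 0))
    stopf("complete_series must be finite and non-negative")
  if (palms_per_ha < 0) stopf("palms_per_ha must be >= 0")
  mean(complete_series) * palms_per_ha
}

#' Carbon reference levels by oil-palm suitability class
#'
#' With no series supplied, returns the study's reference constants
#' (46, 20 and 7 MgC/ha for full stand, 50% and <=25% capacity), which all
#' downstream economics default to. Given a completed per-palm series, the
#' reference for each class is recomputed as its time average multiplied by
#' the class planting density; note the printed under-productive constants
#' are not proportional to palm counts, so computed references will differ
#' from them for the degraded classes.
#'
#' @param complete_series optional numeric vector of per-palm MgC over the
#'   lifespan.
#' @param palms_per_ha named planting densities, default
#'   [palm_planting_density()].
#' @return Data frame with `suitability`, `palms_per_ha`, `mgc_per_ha`.
#' @export
#' @examples
#' reference_levels()
reference_levels <- function(complete_series = NULL,
                             palms_per_ha = palm_planting_density()) {
  suit <- suitability_levels()
  if (!all(suit %in% names(palms_per_ha)))
    stopf("palms_per_ha must name all suitability classes")
  if (is.null(complete_series)) {
    ref <- c(full_stand = 46, under50 = 20, under25 = 7)
  } else {
    ref <- vapply(suit, function(s)
      time_averaged_reference(complete_series, palms_per_ha[[s]]), numeric(1))
  }
  data.frame(suitability = suit,
             palms_per_ha = unname(palms_per_ha[suit]),
             mgc_per_ha = unname(ref[suit]))
}
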