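#' Closed vocabularies for landscape strata
#'
#' @return Character vectors of the admissible oil-palm suitability classes
#'   and land-tenure classes.
#' @export
suitability_levels <- function() c("full_stand", "under50", "under25")

#' @rdname suitability_levels
#' @export
tenure_levels <- function() {
  c("native_title", "country_lease", "state_demarcated",
    "state_undemarcated", "protected", "other")
}

validate_strata <- function(strata) {
  need <- c("extent_ha", "carbon_class")
  if (!is.data.frame(strata) || !all(need %in% names(strata)))
    stopf("strata must be a data frame with columns %s",
          paste(need, collapse = ", "))
  if (any(strata$extent_ha < 0)) stopf("extent_ha must be >= 0")
  class_midpoint(strata$carbon_class)  # errors on unknown class
  if ("suitability" %in% names(strata) &&
      !all(strata$suitability %in% suitability_levels()))
    stopf("unknown suitability class")
  if ("tenure" %in% names(strata) &&
      !all(strata$tenure %in% tenure_levels()))
    stopf("unknown tenure class")
  invisible(strata)
}

#' Mid-point carbon stock of a stratum
#'
#' Stock accounting multiplies a stratum's extent by the mid-point density
#' of its carbon class; with integer extents the result is exact integer
#' arithmetic (e.g. 15,387 ha of class 3 carries 2,308,050 MgC).
#'
#' @param extent_ha extent in hectares, `>= 0`.
#' @param carbon_class class index in 1:6.
#' @return Carbon stock in MgC. Vectorised.
#' @export
#' @examples
#' stratum_carbon(15387, 3)
stratum_carbon <- function(extent_ha, carbon_class) {
  if (any(extent_ha < 0)) stopf("extent_ha must be >= 0")
  extent_ha * class_midpoint(carbon_class)
}

#' Landscape carbon-stock totals
#'
#' Sums extent and mid-point carbon stock over strata, optionally grouped by
#' carbon class, tenure or suitability. Grouped totals always sum exactly to
#' the ungrouped grand total.
#'
#' @param strata data frame of strata (`extent_ha`, `carbon_class`, and the
#'   grouping column if requested).
#' @param group_by one of `"none"`, `"carbon_class"`, `"tenure"`,
#'   `"suitability"`.
#' @return Data frame with the grouping column (absent for `"none"`),
#'   `extent_ha` and `mgc`.
#' @export
landscape_totals <- function(strata,
                             group_by = c("none", "carbon_class", "tenure",
                                          "suitability")) {
  group_by <- match.arg(group_by)
  validate_strata(strata)
  mgc <- stratum_carbon(strata$extent_ha, strata$carbon_class)
  if (group_by == "none") {
    return(data.frame(extent_ha = sum(strata$extent_ha), mgc = sum(mgc)))
  }
  if (!group_by %in% names(strata))
    stopf("strata has no column '%s'", group_by)
  key <- strata[[group_by]]
  agg <- stats::aggregate(cbind(extent_ha = strata$extent_ha, mgc = mgc),
                          by = stats::setNames(list(key), group_by), FUN = sum)
  agg[order(agg[[group_by]]), , drop = FALSE]
}

#' Mean carbon density of a landscape
#'
#' Total mid-point carbon stock divided by total extent. Returned unrounded;
#' reports conventionally display the nearest integer (the study landscape
#' averages 156 MgC/ha).
#'
#' @param strata data frame of strata.
#' @return Mean density in MgC/ha.
#' @export
mean_density <- function(strata) {
  tot <- landscape_totals(strata)
  if (tot$extent_ha <= 0) stopf("total extent must be positive")
  tot$mgc / tot$extent_ha
}
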