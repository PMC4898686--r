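#' Categorical above-ground carbon classes
#'
#' The six carbon-stock classes used to stratify the forest landscape.
#' Bounds are half-open, lower-inclusive intervals in MgC/ha:
#' \[0,50), \[50,100), \[100,200), \[200,300), \[300,400), \[400,Inf).
#' Class mid-points (25, 75, 150, 250, 350, 450 MgC/ha) drive all stock
#' accounting; the top class uses a conservative 450 rather than an
#' unbounded mid-point.
#'
#' @return A data frame with columns `carbon_class` (1:6), `lower_mgc`,
#'   `upper_mgc` (exclusive; `Inf` for class 6) and `midpoint_mgc`.
#' @export
#' @examples
#' carbon_classes()
carbon_classes <- function() {
  data.frame(
    carbon_class = 1:6,
    label        = c("<50", "50-100", "100-200", "200-300", "300-400", ">400"),
    lower_mgc    = c(0, 50, 100, 200, 300, 400),
    upper_mgc    = c(50, 100, 200, 300, 400, Inf),
    midpoint_mgc = c(25, 75, 150, 250, 350, 450)
  )
}

#' Assign a carbon class from a per-hectare carbon density
#'
#' Classes are lower-inclusive: a plot at exactly 50 MgC/ha falls in class 2,
#' and anything at or above 400 MgC/ha is class 6.
#'
#' @param mgc_per_ha numeric vector of carbon densities (MgC/ha), `>= 0`.
#' @return Integer vector of class indices in 1:6.
#' @export
#' @examples
#' assign_carbon_class(c(0, 50, 150, 450))
assign_carbon_class <- function(mgc_per_ha) {
  if (!is.numeric(mgc_per_ha) || any(!is.finite(mgc_per_ha)))
    stopf("mgc_per_ha must be finite numeric")
  if (any(mgc_per_ha < 0))
    stopf("carbon density cannot be negative")
  findInterval(mgc_per_ha, c(0, 50, 100, 200, 300, 400))
}

#' Class mid-point carbon density
#'
#' @param carbon_class integer vector of class indices in 1:6.
#' @return Mid-point density in MgC/ha for each class.
#' @export
class_midpoint <- function(carbon_class) {
  cls <- carbon_classes()
  if (any(is.na(carbon_class)) || !all(carbon_class %in% cls$carbon_class))
    stopf("unknown carbon class; must be one of 1..6")
  cls$midpoint_mgc[match(carbon_class, cls$carbon_class)]
}
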