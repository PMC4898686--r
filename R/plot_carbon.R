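#' Per-tree above-ground biomass from DBH and wood density
#'
#' Moist-tropical-forest allometry for stems measured at breast height,
#' using diameter and wood density only (no height term; floodplain
#' inventories rarely carry usable heights):
#'
#' \deqn{AGB = \rho \exp(-1.499 + 2.148 \ln D + 0.207 (\ln D)^2
#'             - 0.02081 (\ln D)^3)}
#'
#' where `D` is DBH in cm and `rho` wood density in g/cm3. The returned
#' biomass is in kg (dry weight) per stem.
#'
#' @param dbh_cm diameter at breast height in cm, `> 0` (surveys measure
#'   stems >= 10 cm).
#' @param wood_density wood density in g/cm3, `> 0`.
#' @return Above-ground biomass per stem, kg. Vectorised; the two arguments
#'   are recycled.
#' @export
#' @examples
#' tree_agb(10, 0.5)   # ~36.5 kg
#' tree_agb(50, 0.62)
tree_agb <- function(dbh_cm, wood_density) {
  if (!is.numeric(dbh_cm) || !is.numeric(wood_density))
    stopf("dbh_cm and wood_density must be numeric")
  if (any(!is.finite(dbh_cm)) || any(!is.finite(wood_density)))
    stopf("dbh_cm and wood_density must be finite")
  if (any(dbh_cm <= 0)) stopf("dbh_cm must be positive")
  if (any(wood_density <= 0)) stopf("wood_density must be positive")
  ld <- log(dbh_cm)
  wood_density * exp(-1.499 + 2.148 * ld + 0.207 * ld^2 - 0.02081 * ld^3)
}

#' Wood density lookup with conservative fallback
#'
#' Species- or genus-level wood densities come from published averages; any
#' label not in the table (or an absent table) falls back to a standard
#' conservative 0.5 g/cm3.
#'
#' @param species_label character vector of species/genus labels (may be
#'   `NA`).
#' @param density_table optional lookup: either a named numeric vector or a
#'   data frame with columns `species_label` and `wood_density`.
#' @param fallback density used when the label is missing, default 0.5 g/cm3.
#' @return Numeric vector of densities, g/cm3.
#' @export
default_density <- function(species_label, density_table = NULL,
                            fallback = 0.5) {
  if (is.data.frame(density_table)) {
    if (!all(c("species_label", "wood_density") %in% names(density_table)))
      stopf("density_table needs columns species_label, wood_density")
    density_table <- stats::setNames(density_table$wood_density,
                                     density_table$species_label)
  }
  out <- rep_len(fallback, length(species_label))
  if (length(density_table)) {
    hit <- match(as.character(species_label), names(density_table))
    out[!is.na(hit)] <- unname(density_table[hit[!is.na(hit)]])
  }
  out
}

#' Plot-level carbon density
#'
#' Sums per-tree AGB over a plot, converts kg to Mg, applies the carbon
#' fraction of dry biomass and divides by plot area:
#' `(sum AGB / 1000) * carbon_fraction / area_ha`, in MgC/ha.
#'
#' @param trees data frame of stems with columns `dbh_cm` and `wood_density`
#'   (zero rows allowed: an empty plot has density 0).
#' @param area_ha plot area in hectares, `> 0`.
#' @param carbon_fraction carbon fraction of dry above-ground biomass;
#'   default 0.5.
#' @return Carbon density in MgC/ha.
#' @export
plot_carbon_density <- function(trees, area_ha, carbon_fraction = 0.5) {
  if (!is.numeric(area_ha) || length(area_ha) != 1L || !is.finite(area_ha) ||
      area_ha <= 0)
    stopf("area_ha must be a single positive number")
  if (!is.data.frame(trees))
    stopf("trees must be a data frame")
  if (nrow(trees) == 0L) return(0)
  agb_kg <- tree_agb(trees$dbh_cm, trees$wood_density)
  sum(agb_kg) / 1000 * carbon_fraction / area_ha
}

#' Carbon density and class for every plot in an inventory
#'
#' @param inventory a list with elements `plots` (columns `plot_id`,
#'   `area_ha`) and `trees` (columns `plot_id`, `dbh_cm`, `wood_density`),
#'   as produced by [generate_inventory()] or read from CSV.
#' @param carbon_fraction carbon fraction of AGB, default 0.5.
#' @return Data frame with `plot_id`, `mgc_per_ha` and `carbon_class`.
#' @export
inventory_carbon <- function(inventory, carbon_fraction = 0.5) {
  plots <- inventory$plots
  trees <- inventory$trees
  dens <- vapply(seq_len(nrow(plots)), function(i) {
    plot_carbon_density(trees[trees$plot_id == plots$plot_id[i], , drop = FALSE],
                        plots$area_ha[i], carbon_fraction)
  }, numeric(1))
  data.frame(plot_id = plots$plot_id,
             mgc_per_ha = dens,
             carbon_class = assign_carbon_class(dens))
}
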