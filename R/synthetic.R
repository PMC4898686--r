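#' Configuration for the synthetic landscape generator
#'
#' Bundles and validates every knob of the synthetic-data module. Defaults
#' emulate the study landscape: 230 plots over 110 ha of inventory; a
#' log-normal DBH distribution truncated at the 10 cm measurement floor
#' with median ~25 cm (a plausible logged-forest structure — the source
#' data's distributions are not published); carbon-class extents equal to
#' the unprotected-forest column of the stock table (total 30,173 ha);
#' suitability extents of 9,327 / 4,352 / 16,492 ha (full stand / 50% /
#' <=25%); tenure fractions proportional to the published tenure carbon
#' shares; and palm-series gaps chosen so the observed ages reproduce the
#' 11 surveyed age categories (2-5, 7-8, 13, 15-16, 18-19).
#'
#' @param seed single integer; one global seed governs all generators.
#' @param n_plots number of inventory plots.
#' @param trees_per_plot mean stem count per plot (Poisson).
#' @param plot_area_ha area of each plot, ha.
#' @param dbh_lognormal_params `c(meanlog, sdlog)` of log-DBH (cm); draws
#'   are truncated at >= 10 cm.
#' @param wood_density_range `c(min, max)` g/cm3; densities drawn uniformly.
#' @param class_extents_ha named vector, carbon class (`"1"`..`"6"`) -> ha.
#' @param suitability_extents_ha named vector, suitability class -> ha.
#' @param tenure_fractions named vector of tenure shares summing to 1.
#' @param palm_series_gaps integer ages in 1..19 omitted from the palm
#'   series (ages below 2 are never surveyed: seedlings carry negligible
#'   carbon).
#' @param marginal_tolerance_ha allowed disagreement between the class and
#'   suitability extent totals (the study's own marginals differ by 2 ha).
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, n_plots = 5)
synthetic_config <- function(seed = 1L,
                             n_plots = 230,
                             trees_per_plot = 50,
                             plot_area_ha = 110 / 230,
                             dbh_lognormal_params = c(meanlog = log(25),
                                                      sdlog = 0.5),
                             wood_density_range = c(0.4, 0.8),
                             class_extents_ha = c(`1` = 4249, `2` = 3989,
                                                  `3` = 15387, `4` = 3851,
                                                  `5` = 1841, `6` = 856),
                             suitability_extents_ha = c(full_stand = 9327,
                                                        under50 = 4352,
                                                        under25 = 16492),
                             tenure_fractions = c(native_title = 0.2925,
                                                  country_lease = 0.3406,
                                                  state_demarcated = 0.1256,
                                                  state_undemarcated = 0.2413),
                             palm_series_gaps = c(6, 9:12, 14, 17),
                             marginal_tolerance_ha = 5) {
  if (length(seed) != 1L || is.na(seed)) stopf("seed must be a single integer")
  if (n_plots < 1) stopf("n_plots must be >= 1")
  if (trees_per_plot <= 0) stopf("trees_per_plot must be positive")
  if (plot_area_ha <= 0) stopf("plot_area_ha must be positive")
  if (length(dbh_lognormal_params) != 2L || dbh_lognormal_params[2] <= 0)
    stopf("dbh_lognormal_params must be c(meanlog, sdlog) with sdlog > 0")
  if (length(wood_density_range) != 2L ||
      wood_density_range[1] > wood_density_range[2] ||
      wood_density_range[1] <= 0)
    stopf("wood_density_range must be a positive (min, max) pair")
  if (any(class_extents_ha < 0) || any(suitability_extents_ha < 0))
    stopf("extents must be non-negative")
  if (length(class_extents_ha) &&
      !all(names(class_extents_ha) %in% as.character(1:6)))
    stopf("class_extents_ha names must be carbon classes 1..6")
  if (length(suitability_extents_ha) &&
      !all(names(suitability_extents_ha) %in% suitability_levels()))
    stopf("unknown suitability class in suitability_extents_ha")
  if (!all(names(tenure_fractions) %in% tenure_levels()))
    stopf("unknown tenure class in tenure_fractions")
  if (abs(sum(tenure_fractions) - 1) > 1e-9)
    stopf("tenure_fractions must sum to 1")
  if (any(tenure_fractions < 0)) stopf("tenure_fractions must be >= 0")
  if (length(palm_series_gaps) &&
      (!all(palm_series_gaps %in% 1:19)))
    stopf("palm_series_gaps must lie in 1..19")
  if (length(class_extents_ha) && length(suitability_extents_ha) &&
      abs(sum(class_extents_ha) - sum(suitability_extents_ha)) >
        marginal_tolerance_ha)
    stopf("class and suitability extent totals disagree by more than %g ha",
          marginal_tolerance_ha)
  structure(list(seed = as.integer(seed), n_plots = n_plots,
                 trees_per_plot = trees_per_plot, plot_area_ha = plot_area_ha,
                 dbh_lognormal_params = dbh_lognormal_params,
                 wood_density_range = wood_density_range,
                 class_extents_ha = class_extents_ha,
                 suitability_extents_ha = suitability_extents_ha,
                 tenure_fractions = tenure_fractions,
                 palm_series_gaps = sort(unique(palm_series_gaps)),
                 marginal_tolerance_ha = marginal_tolerance_ha),
            class = "synthetic_config")
}

# truncated log-normal DBH draws (inverse-CDF, floor at 10 cm)
rdbh <- function(n, meanlog, sdlog, floor_cm = 10) {
  p0 <- stats::plnorm(floor_cm, meanlog, sdlog)
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic tree inventory
#'
#' Draws per-plot stem counts (Poisson), DBH (truncated log-normal, >= 10
#' cm), wood densities (uniform within the configured range) and species
#' labels from a small floodplain species pool. Identical output for
#' identical seeds.
#'
#' @param config a [synthetic_config()].
#' @return List with `plots` (`plot_id`, `area_ha`, `habitat_label`) and
#'   `trees` (`plot_id`, `tree_id`, `dbh_cm`, `wood_density`, `species`).
#' @export
generate_inventory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  habitats <- c("lowland dry forest", "seasonal freshwater swamp forest",
                "freshwater swamp forest", "mangrove forest",
                "transitional forest", "degraded mixed")
  species <- c("Shorea sp.", "Dipterocarpus sp.", "Dryobalanops sp.",
               "Eusideroxylon zwageri", "Ficus sp.", "Nauclea sp.",
               "unknown")
  plots <- data.frame(
    plot_id = sprintf("P%03d", seq_len(config$n_plots)),
    area_ha = config$plot_area_ha,
    habitat_label = sample(habitats, config$n_plots, replace = TRUE))
  n_trees <- stats::rpois(config$n_plots, config$trees_per_plot)
  total <- sum(n_trees)
  dmin <- config$wood_density_range[1]
  dmax <- config$wood_density_range[2]
  trees <- data.frame(
    plot_id = rep(plots$plot_id, n_trees),
    tree_id = unlist(lapply(n_trees, seq_len), use.names = FALSE),
    dbh_cm = rdbh(total, config$dbh_lognormal_params[1],
                  config$dbh_lognormal_params[2]),
    wood_density = if (dmin == dmax) rep(dmin, total)
                   else stats::runif(total, dmin, dmax),
    species = sample(species, total, replace = TRUE))
  if (total == 0L) trees <- trees[0, , drop = FALSE]
  list(plots = plots, trees = trees)
}

#' Generate a synthetic landscape of accounting strata
#'
#' Builds one stratum per (carbon class x suitability x tenure) combination
#' with a positive extent, allocating each class's configured extent across
#' suitability classes proportionally to the suitability marginals and then
#' across tenure by the configured fractions. Per-class extent sums
#' therefore match the class marginals exactly, and the suitability sums
#' match their marginals up to the (small) disagreement between the two
#' configured totals.
#'
#' @param config a [synthetic_config()].
#' @return Data frame of strata: `stratum_id`, `extent_ha`, `carbon_class`,
#'   `suitability`, `tenure`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cls <- config$class_extents_ha
  suit <- config$suitability_extents_ha
  ten <- config$tenure_fractions
  if (length(cls) == 0L || sum(cls) == 0) {
    return(data.frame(stratum_id = character(), extent_ha = numeric(),
                      carbon_class = integer(), suitability = character(),
                      tenure = character()))
  }
  suit_frac <- if (length(suit) == 0L || sum(suit) == 0)
    c(full_stand = 1) else suit / sum(suit)
  grid <- expand.grid(carbon_class = as.integer(names(cls)),
                      suitability = names(suit_frac),
                      tenure = names(ten),
                      stringsAsFactors = FALSE)
  grid$extent_ha <- cls[as.character(grid$carbon_class)] *
    suit_frac[grid$suitability] * ten[grid$tenure]
  grid <- grid[grid$extent_ha > 0, , drop = FALSE]
  grid <- grid[order(grid$carbon_class, grid$suitability, grid$tenure), ]
  data.frame(stratum_id = sprintf("S%03d", seq_len(nrow(grid))),
             extent_ha = unname(grid$extent_ha),
             carbon_class = grid$carbon_class,
             suitability = grid$suitability,
             tenure = grid$tenure,
             row.names = NULL)
}

#' Generate a partially observed per-palm carbon age series
#'
#' Emulates a plantation chronosequence: per-palm carbon accumulates
#' monotonically with age (cumulative gamma increments averaging ~0.6 MgC
#' by year 19), surveyed at ages 2-19 minus the configured gaps.
#'
#' @param config a [synthetic_config()].
#' @return Data frame with `age_yr` and `mgc_per_palm`, ascending in age.
#' @export
generate_palm_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ages_all <- 2:19
  observed <- setdiff(ages_all, config$palm_series_gaps)
  if (length(observed) == 0L)
    stopf("all surveyable ages are gapped; nothing to interpolate from")
  set.seed(config$seed)
  # monotone accumulation: positive annual increments from age 0
  inc <- stats::rgamma(19, shape = 4, scale = 0.6 / (19 * 4))
  carbon <- cumsum(inc)                     # per-palm MgC at ages 1..19
  data.frame(age_yr = observed, mgc_per_palm = carbon[observed])
}
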