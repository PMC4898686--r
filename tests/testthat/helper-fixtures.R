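# published stock-table marginals used across tests
unprotected_extents <- c(4249, 3989, 15387, 3851, 1841, 856)
all_forest_extents  <- c(26000, 26308, 91012, 53621, 40103, 14472)

table2_strata <- function(extents = unprotected_extents) {
  data.frame(extent_ha = extents, carbon_class = 1:6)
}

# random small landscape for property tests
random_strata <- function(n, seed) {
  set.seed(seed)
  data.frame(
    extent_ha = round(runif(n, 0, 500), 1),
    carbon_class = sample(1:6, n, replace = TRUE),
    suitability = sample(suitability_levels(), n, replace = TRUE),
    tenure = sample(tenure_levels(), n, replace = TRUE))
}
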