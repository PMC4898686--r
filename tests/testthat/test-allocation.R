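strata_grid <- function() {
  g <- expand.grid(carbon_class = 1:6,
                   suitability = suitability_levels(),
                   stringsAsFactors = FALSE)
  g$extent_ha <- 100
  g
}

test_that("low-suitability strata always go to REDD+, low-carbon full-stand to oil palm", {
  for (p in c(3, 7.8, 15, 30)) {
    for (st in c("upfront", "staggered")) {
      a <- allocate_landscape(strata_grid(), scenario(p, st, 0.11))
      expect_true(all(a$winner[a$suitability == "under25"] == "redd"))
    }
  }
  a30 <- allocate_landscape(strata_grid(), scenario(30, "upfront", 0.11))
  expect_equal(a30$winner[a30$suitability == "full_stand" &
                            a30$carbon_class == 1], "oilpalm")
})

test_that("ties are awarded to REDD+", {
  land <- data.frame(extent_ha = 1, carbon_class = 3,
                     suitability = "full_stand")
  sc <- scenario(15, "upfront", 0.11)
  tied_npv <- redd_annual_npv(net_co2e_per_ha(3, 46), sc)
  a <- allocate_landscape(land, sc,
                          oilpalm_npvs = c(full_stand = tied_npv,
                                           under50 = 0, under25 = 0))
  expect_equal(a$winner, "redd")
})

test_that("break-even structure matches the published thresholds", {
  refs <- reference_levels()
  # full stand, 11% upfront: wins iff (price >= 15 and >= 350 MgC/ha)
  # or (price 30 and >= 250 MgC/ha)
  mids <- c(25, 75, 150, 250, 350, 450)
  for (p in c(3, 7.8, 15, 30)) {
    a <- allocate_landscape(strata_grid(), scenario(p, "upfront", 0.11))
    fs <- a[a$suitability == "full_stand", ]
    fs <- fs[order(fs$carbon_class), ]
    expected <- (p >= 15 & mids >= 350) | (p == 30 & mids >= 250)
    expect_equal(fs$winner == "redd", expected)
    # class 1 (25 MgC/ha) REDD+ NPV is negative at every price
    expect_lt(fs$redd_npv[fs$carbon_class == 1], 0)
    # low suitability: REDD+ wins for every price and class
    expect_true(all(a$winner[a$suitability == "under25"] == "redd"))
  }
})

test_that("roll-up reproduces the published CO2e and fund cells from their MgC inputs", {
  cells <- data.frame(
    stance = rep(c("upfront", "staggered"), each = 4),
    price = rep(c(3, 7.8, 15, 30), 2),
    mgc = c(2495980, 2887380, 3413530, 3779505,
            2461415, 2495980, 2887380, 3449755),
    co2e = c(9160247, 10596685, 12527655, 13870783,
             9033393, 9160247, 10596685, 12660601),
    funds = c(27480740, 82654140, 187914827, 416123501,
              27100179, 71449923, 158950269, 379818026))
  fin <- carbon_finance(cells$mgc, cells$price)
  expect_identical(fin$mgco2e, cells$co2e)
  expect_identical(fin$funds_usd, cells$funds)
  # the roll-up path uses the same arithmetic: a stratum set summing to a
  # round MgC total reproduces its cell exactly
  sc <- scenario(3, "upfront", 0.11)
  land <- data.frame(extent_ha = c(10000, 3973.2), carbon_class = c(3, 6),
                     suitability = "under25")  # 1,500,000 + 1,787,940 MgC
  roll <- allocation_rollup(allocate_landscape(land, sc), sc)
  expect_equal(roll$total_mgc, 3287940)
  expect_identical(roll$funds_usd, carbon_finance(3287940, 3)$funds_usd)
})

test_that("landscape shares round like the published percentages", {
  total <- 30173
  ext <- c(16629, 18999, 20376, 22178, 16546, 20859)
  expect_equal(round_half_up(100 * ext / total), c(55, 63, 68, 74, 55, 69))
})

test_that("empty winner set rolls up to zeros", {
  land <- data.frame(extent_ha = 10, carbon_class = 1,
                     suitability = "full_stand")
  sc <- scenario(3, "upfront", 0.11)
  roll <- allocation_rollup(allocate_landscape(land, sc), sc)
  expect_equal(roll$extent_ha, 0)
  expect_equal(roll$total_mgc, 0)
  expect_equal(roll$funds_usd, 0)
})

test_that("REDD+ coverage is monotone in carbon price and upfront covers staggered", {
  land <- generate_landscape(synthetic_config(seed = 3))
  winners <- function(p, st) {
    a <- allocate_landscape(land, scenario(p, st, 0.11))
    a$stratum_id[a$winner == "redd"]
  }
  for (st in c("upfront", "staggered")) {
    prev <- character()
    for (p in c(3, 7.8, 15, 30)) {
      cur <- winners(p, st)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
  for (p in c(3, 7.8, 15, 30)) {
    expect_true(all(winners(p, "staggered") %in% winners(p, "upfront")))
  }
})

test_that("allocation recovers a known winner set exactly", {
  # REDD+ NPV is strictly increasing in carbon class, so planting the
  # oil-palm threshold between the class-k and class-(k+1) NPVs makes the
  # winner set exactly classes k+1..6 — known without running the allocator
  sc <- scenario(7.8, "upfront", 0.11)
  refs <- reference_levels()
  land <- random_strata(60, 21)
  for (cut in c(1, 3, 5)) {
    op <- vapply(suitability_levels(), function(s) {
      ref <- refs$mgc_per_ha[refs$suitability == s]
      lo <- redd_annual_npv(net_co2e_per_ha(cut, ref), sc)
      hi <- redd_annual_npv(net_co2e_per_ha(cut + 1, ref), sc)
      (lo + hi) / 2
    }, numeric(1))
    a <- allocate_landscape(land, sc, refs, oilpalm_npvs = op)
    expect_identical(a$winner == "redd", land$carbon_class > cut)
  }
})

test_that("allocation_table enumerates the full scenario grid", {
  land <- generate_landscape(synthetic_config(seed = 1))
  tab <- allocation_table(land)
  expect_equal(nrow(tab), 8)
  expect_equal(sort(unique(tab$price)), c(3, 7.8, 15, 30))
  expect_true(all(tab$extent_ha <= sum(land$extent_ha)))
  expect_error(allocate_landscape(
    data.frame(extent_ha = 1, carbon_class = 1, suitability = "swampy"),
    scenario(3, "upfront")), "suitability")
})
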