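test_that("allometry matches hand evaluation of the published formula", {
  # frozen from an independent pre-build evaluation of
  # rho * exp(-1.499 + 2.148 ln D + 0.207 (ln D)^2 - 0.02081 (ln D)^3)
  expect_equal(tree_agb(10, 0.5), 36.497674, tolerance = 1e-6)
  expect_equal(tree_agb(50, 0.5), 3404.6939, tolerance = 1e-6)
})

test_that("allometry is linear in wood density and increasing in DBH", {
  d <- c(10, 23.7, 55, 120)
  expect_equal(tree_agb(d, 2 * 0.47), 2 * tree_agb(d, 0.47))
  grid <- seq(10, 200, by = 0.5)
  expect_true(all(diff(tree_agb(grid, 0.5)) > 0))
})

test_that("allometry rejects non-positive inputs", {
  expect_error(tree_agb(0, 0.5), "positive")
  expect_error(tree_agb(-5, 0.5), "positive")
  expect_error(tree_agb(30, 0), "positive")
  expect_error(tree_agb(NA_real_, 0.5), "finite")
})

test_that("wood density lookup falls back to the conservative 0.5", {
  tab <- c("Shorea sp." = 0.62, "Ficus sp." = 0.39)
  expect_equal(default_density("Shorea sp.", tab), 0.62)
  expect_equal(default_density("never seen", tab), 0.5)
  expect_equal(default_density(c("x", "y"), NULL), c(0.5, 0.5))
  df <- data.frame(species_label = "Shorea sp.", wood_density = 0.62)
  expect_equal(default_density(c("Shorea sp.", NA), df), c(0.62, 0.5))
})

test_that("plot carbon density does the unit arithmetic", {
  expect_equal(plot_carbon_density(data.frame(dbh_cm = numeric(),
                                              wood_density = numeric()),
                                   1), 0)
  # one stem: (AGB kg / 1000) * fraction / area
  tr <- data.frame(dbh_cm = 40, wood_density = 0.55)
  agb <- tree_agb(40, 0.55)
  expect_equal(plot_carbon_density(tr, 0.5, carbon_fraction = 0.5),
               agb / 1000 * 0.5 / 0.5)
  # 100 identical stems on the same area give exactly 100x the density
  tr100 <- tr[rep(1, 100), , drop = FALSE]
  expect_equal(plot_carbon_density(tr100, 0.25),
               100 * plot_carbon_density(tr, 0.25))
  expect_error(plot_carbon_density(tr, 0), "positive")
})

test_that("plot carbon density is order-invariant, additive and matches a naive loop", {
  set.seed(42)
  for (k in 1:5) {
    n <- sample(3:30, 1)
    tr <- data.frame(dbh_cm = runif(n, 10, 120),
                     wood_density = runif(n, 0.3, 0.9))
    area <- runif(1, 0.1, 2)
    # independent oracle: explicit per-tree loop on the printed formula
    acc <- 0
    for (i in seq_len(n)) {
      ld <- log(tr$dbh_cm[i])
      acc <- acc + tr$wood_density[i] *
        exp(-1.499 + 2.148 * ld + 0.207 * ld^2 - 0.02081 * ld^3)
    }
    expect_equal(plot_carbon_density(tr, area), acc / 1000 * 0.5 / area)
    shuf <- tr[sample(n), , drop = FALSE]
    expect_equal(plot_carbon_density(shuf, area),
                 plot_carbon_density(tr, area))
    split1 <- tr[1:2, , drop = FALSE]
    split2 <- tr[-(1:2), , drop = FALSE]
    expect_equal(plot_carbon_density(split1, area) +
                   plot_carbon_density(split2, area),
                 plot_carbon_density(tr, area))
  }
})

test_that("carbon classes use lower-inclusive half-open bounds", {
  expect_identical(assign_carbon_class(150), 3L)
  expect_identical(assign_carbon_class(50), 2L)   # boundary joins upper class
  expect_identical(assign_carbon_class(450), 6L)
  expect_identical(assign_carbon_class(c(0, 49.99, 400, 1e4)),
                   c(1L, 1L, 6L, 6L))
  expect_error(assign_carbon_class(-1), "negative")
})

test_that("each class midpoint maps back to its own class", {
  cls <- carbon_classes()
  expect_identical(assign_carbon_class(cls$midpoint_mgc), cls$carbon_class)
  expect_equal(class_midpoint(1:6), c(25, 75, 150, 250, 350, 450))
  expect_error(class_midpoint(7), "unknown")
})

test_that("inventory_carbon reproduces per-plot computation", {
  cfg <- synthetic_config(seed = 7, n_plots = 4, trees_per_plot = 12)
  inv <- generate_inventory(cfg)
  tab <- inventory_carbon(inv)
  expect_equal(nrow(tab), 4)
  p2 <- inv$plots$plot_id[2]
  manual <- plot_carbon_density(inv$trees[inv$trees$plot_id == p2, ],
                                inv$plots$area_ha[2])
  expect_equal(tab$mgc_per_ha[2], manual)
  expect_identical(tab$carbon_class, assign_carbon_class(tab$mgc_per_ha))
})
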