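# The coupling operator: conservation, linearity, decomposition,
# species-routing rules and uncertainty propagation.

test_that("single species under a constant curve conserves the yield", {
  comp <- toyComposition(species = "proton", w = 1, yD = 40)
  pt <- couple(comp, list(proton = constantCurve(7.5)), "dsb_clusters")
  expect_equal(damageYield(pt), 7.5)
  expect_equal(speciesContributions(pt)$contribution, 7.5)
})

test_that("two-species weighted sum matches hand calculation", {
  # Y(proton at 40) = 10, Y(alpha at 150) = 100 via tailored power laws
  curves <- list(
    proton = DamageCurve("proton", "dsb_clusters", "power_law",
                         c(a = 10 / 40, n = 1), c(1, 300)),
    alpha = DamageCurve("alpha", "dsb_clusters", "power_law",
                        c(a = 100 / 150, n = 1), c(1, 300)))
  pt <- couple(toyComposition(w = c(0.7, 0.3), yD = c(40, 150)),
               curves, "dsb_clusters")
  expect_equal(damageYield(pt), 0.7 * 10 + 0.3 * 100)
  # exact decomposition into per-species contributions
  expect_equal(sum(speciesContributions(pt)$contribution), damageYield(pt))
})

test_that("relabeled species with identical curves give identical totals", {
  shared <- c(a = 0.2, n = 1.1)
  curves <- list(
    proton = DamageCurve("proton", "dsb_clusters", "power_law", shared, c(1, 500)),
    alpha = DamageCurve("alpha", "dsb_clusters", "power_law", shared, c(1, 500)))
  a <- couple(toyComposition(species = c("proton", "alpha"),
                             w = c(0.5, 0.5), yD = c(60, 90)), curves, "dsb_clusters")
  b <- couple(toyComposition(species = c("alpha", "proton"),
                             w = c(0.5, 0.5), yD = c(60, 90)), curves, "dsb_clusters")
  expect_equal(damageYield(a), damageYield(b))
})

test_that("deuterons and electrons ride the proton curve, electrons clamped low", {
  curves <- list(proton = DamageCurve("proton", "dsb_clusters", "power_law",
                                      c(a = 0.1, n = 1), c(5, 100)))
  comp <- FieldComposition(0.001, "outer", data.frame(
    species = c("electron", "deuteron"),
    doseFraction = c(0.9, 0.1), doseFractionErr = c(0, 0),
    yD = c(2, 15), yDErr = c(0, 0)))
  pt <- couple(comp, curves, "dsb_clusters")
  ct <- speciesContributions(pt)
  # electron yD = 2 sits below the span: clamped to Y(5), flagged
  expect_equal(ct$speciesYield[ct$species == "electron"], 0.5)
  expect_true(ct$clamped[ct$species == "electron"])
  expect_equal(ct$speciesYield[ct$species == "deuteron"], 1.5)
  expect_false(ct$clamped[ct$species == "deuteron"])
})

test_that("missing curves and missing yD raise configuration errors", {
  comp <- toyComposition()
  expect_error(couple(comp, list(proton = constantCurve(1)), "dsb_clusters"),
               "no dsb_clusters damage curve")
  wrongEndpoint <- list(proton = constantCurve(1, endpoint = "short_fragments"),
                        alpha = constantCurve(1, endpoint = "short_fragments"))
  expect_error(couple(comp, wrongEndpoint, "dsb_clusters"), "endpoint")
})

test_that("coupling is linear in the damage curves", {
  tab <- generateCompositionTable(
    fieldGeneratorConfig(energyGrid = 10^seq(-2, 2, length.out = 9)))
  curves <- defaultDamageCurves("dsb_clusters")
  doubled <- lapply(curves, function(cv) {
    p <- curveParams(cv)
    amp <- if (cv@form == "power_law") "a" else "A"
    p[[amp]] <- 2 * p[[amp]]
    DamageCurve(cv@species, cv@endpoint, cv@form, p, letRange(cv))
  })
  d1 <- neutronDamageCurve(tab, curves, "dsb_clusters")
  d2 <- neutronDamageCurve(tab, doubled, "dsb_clusters")
  expect_equal(d2$yield, 2 * d1$yield, tolerance = 1e-12)
  expect_true(all(d1$yield > 0))
})

test_that("uniform curves across species collapse to the common curve value", {
  pl <- DamageCurve("proton", "dsb_clusters", "power_law",
                    c(a = 0.3, n = 1.2), c(1, 1000))
  curves <- list(proton = pl, alpha = pl, C = pl, N = pl, O = pl)
  for (w in list(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1))) {
    pt <- couple(toyComposition(species = c("alpha", "C"), w = w,
                                yD = c(70, 70)), curves, "dsb_clusters")
    expect_equal(damageYield(pt), as.numeric(evalDamage(pl, 70)),
                 tolerance = 1e-12)
  }
})

test_that("boosting the highest-yield species never decreases the total", {
  curves <- defaultDamageCurves("dsb_clusters")
  comp <- toyComposition(species = c("proton", "N"), w = c(0.6, 0.4),
                         yD = c(40, 500))
  base <- damageYield(couple(comp, curves, "dsb_clusters"))
  ct <- speciesContributions(couple(comp, curves, "dsb_clusters"))
  top <- ct$species[which.max(ct$speciesYield)]
  for (delta in c(0.1, 0.2, 0.3)) {
    r <- speciesRecords(comp)
    i <- r$species == top
    w2 <- r$doseFraction
    w2[i] <- w2[i] + delta
    w2[!i] <- w2[!i] * (1 - w2[i]) / sum(w2[!i])
    boosted <- FieldComposition(1, "outer",
      transform(r, doseFraction = w2))
    expect_gte(damageYield(couple(boosted, curves, "dsb_clusters")), base)
  }
})

test_that("dose-fraction errors propagate in quadrature", {
  curves <- list(
    proton = constantCurve(10), alpha = constantCurve(100, species = "alpha"))
  comp <- toyComposition(w = c(0.7, 0.3), yD = c(40, 150),
                         wErr = c(0.07, 0.03))
  pt <- couple(comp, curves, "dsb_clusters")
  expect_equal(damageYieldErr(pt), sqrt((10 * 0.07)^2 + (100 * 0.03)^2),
               tolerance = 1e-12)
})

test_that("flat composition tables give flat damage curves with no interior maxima", {
  rec <- data.frame(species = c("proton", "alpha"),
                    doseFraction = c(0.6, 0.4), doseFractionErr = c(0, 0),
                    yD = c(40, 150), yDErr = c(0, 0))
  tab <- lapply(c(0.1, 1, 10, 100), function(E)
    FieldComposition(E, "outer", rec))
  d <- neutronDamageCurve(tab, defaultDamageCurves("dsb_clusters"), "dsb_clusters")
  expect_equal(diff(range(d$yield)), 0, tolerance = 1e-12)
  expect_length(attr(d, "maxima"), 0)
  expect_error(neutronDamageCurve(tab[1], defaultDamageCurves("dsb_clusters")),
               "two energies")
})

test_that("damage curve CSV writers emit the documented columns", {
  tab <- generateCompositionTable(
    fieldGeneratorConfig(energyGrid = 10^seq(-1, 1, length.out = 3)))
  d <- neutronDamageCurve(tab, defaultDamageCurves("dsb_clusters"), "dsb_clusters")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeDamageCurveCSV(d, f1, f2)
  main <- read.csv(f1); comp <- read.csv(f2)
  expect_named(main, c("E_n_MeV", "region", "endpoint", "yield", "yield_err"))
  expect_true(all(c("E_n_MeV", "species", "contribution") %in% names(comp)))
  unlink(c(f1, f2))
})
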