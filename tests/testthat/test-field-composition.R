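# Kinematics, Q values, LET helpers and the composition data model.

test_that("embedded Q values reproduce the capture energetics", {
  expect_equal(reactionQValue("H(n,g)d"), 2.2246, tolerance = 1e-4)
  expect_equal(round(reactionQValue("H(n,g)d"), 1), 2.2)
  expect_equal(reactionQValue("N14(n,p)C14") * 1000, 626, tolerance = 1e-3)
  expect_error(reactionQValue("Fe56(n,g)Fe57"), "unknown reaction")
})

test_that("reverse reactions flip the Q value sign exactly", {
  for (rx in c("H(n,g)d", "N14(n,p)C14"))
    expect_identical(reactionQValue(rx, reverse = TRUE), -reactionQValue(rx))
})

test_that("maximal elastic energy transfer follows two-body kinematics", {
  mn <- 1.00866491588
  expect_equal(maxEnergyTransfer(5, mn), 5)            # symmetric masses
  expect_equal(maxEnergyTransfer(1, 12), 0.28610, tolerance = 1e-4)
  # kinematic fraction in (0, 1], strictly decreasing above the neutron mass
  mt <- seq(1.1, 20, length.out = 50)
  frac <- maxEnergyTransfer(1, mt)
  expect_true(all(frac > 0 & frac <= 1))
  expect_true(all(diff(frac) < 0))
  expect_error(maxEnergyTransfer(-1, 12), ">= 0")
  expect_error(maxEnergyTransfer(1, -12), "positive")
})

test_that("fluence-dose-LET relation round trips with the grid fluence", {
  # 15 particles over 15 pixels of 16 um^2 each
  fluence <- 15 / (15 * 16)
  expect_equal(fluence, 0.0625)
  dose <- doseFromLetFluence(10, fluence)
  expect_equal(dose, 0.100125, tolerance = 1e-6)
  expect_equal(letFromDoseFluence(dose, fluence), 10, tolerance = 1e-12)
  expect_equal(letFromDoseFluence(0, fluence), 0)
  expect_error(letFromDoseFluence(1, 0), "positive")
})

test_that("track-average LET is initial energy over track length", {
  expect_equal(trackAverageLET(1, function(E) 10), 100)
  # constant-stopping-power toy range R = E/S returns S exactly
  S <- 37.5
  expect_equal(trackAverageLET(2.4, function(E) 1000 * E / S), S)
  expect_error(trackAverageLET(1, function(E) 0), "positive")
})

test_that("embedded proton range agrees with an independent quadrature of 1/S", {
  E0 <- 1
  Eg <- seq(1e-4, E0, length.out = 20000)
  S <- stoppingPower("proton", Eg)          # keV/um
  invS <- 1000 / S
  oracle <- sum(diff(Eg) * (head(invS, -1) + tail(invS, -1)) / 2)
  expect_equal(particleRange("proton", E0), oracle, tolerance = 0.02)
})

test_that("composition validation renormalizes small deficits and rejects large ones", {
  rec <- data.frame(species = c("electron", "proton"),
                    doseFraction = c(0.47, 0.50),
                    doseFractionErr = c(0.01, 0.01),
                    yD = c(2, 60), yDErr = c(0, 0))
  comp <- suppressWarnings(
    validateComposition(FieldComposition(1, "outer", rec)))
  expect_equal(sum(speciesRecords(comp)$doseFraction), 1, tolerance = 1e-12)
  expect_equal(speciesRecords(comp)$doseFraction[1], 0.47 / 0.97,
               tolerance = 1e-12)
  expect_warning(validateComposition(FieldComposition(1, "outer", rec)),
                 "renormalizing")

  one <- validateComposition(FieldComposition(
    1, "outer", data.frame(species = "proton", doseFraction = 1,
                           doseFractionErr = 0, yD = 50, yDErr = 0)))
  expect_equal(speciesRecords(one)$doseFraction, 1)

  rec$doseFraction <- c(0.2, 0.3)
  expect_error(validateComposition(FieldComposition(1, "outer", rec)),
               "outside")
})

test_that("composition interpolation is log-linear with threshold gating", {
  mk <- function(E, wA, wB, yA = 50, yB = 2) FieldComposition(E, "outer",
    data.frame(species = c("proton", "electron"),
               doseFraction = c(wA, wB), doseFractionErr = c(0, 0),
               yD = c(yA, yB), yDErr = c(0, 0)))
  tab <- list(mk(0.01, 0.2, 0.8), mk(1, 0.4, 0.6))
  # node hit returns node values exactly
  at <- interpolateComposition(tab, 0.01)
  expect_equal(speciesRecords(at)$doseFraction[1], 0.2)
  # log midpoint of the fractions
  mid <- interpolateComposition(tab, 0.1)
  r <- speciesRecords(mid)
  expect_equal(r$doseFraction[r$species == "proton"], 0.3, tolerance = 1e-12)
  # yD interpolates log-log
  tab2 <- list(mk(0.01, 0.5, 0.5, yA = 10), mk(1, 0.5, 0.5, yA = 1000))
  r2 <- speciesRecords(interpolateComposition(tab2, 0.1))
  expect_equal(r2$yD[r2$species == "proton"], 100, tolerance = 1e-9)
  expect_error(interpolateComposition(tab, 5), "outside")

  # threshold rule: channel absent below stays exactly zero at the node
  lo <- FieldComposition(1, "outer",
    data.frame(species = c("proton"), doseFraction = 1,
               doseFractionErr = 0, yD = 50, yDErr = 0))
  hi <- FieldComposition(10, "outer",
    data.frame(species = c("proton", "alpha"),
               doseFraction = c(0.8, 0.2), doseFractionErr = c(0, 0),
               yD = c(30, 150), yDErr = c(0, 0)))
  atLo <- interpolateComposition(list(lo, hi), 1)
  rl <- speciesRecords(atLo)
  expect_false("alpha" %in% rl$species[rl$doseFraction > 0])
  above <- speciesRecords(interpolateComposition(list(lo, hi), 2))
  expect_gt(above$doseFraction[above$species == "alpha"], 0)
})

test_that("interpolated compositions satisfy the composition invariants", {
  tab <- generateCompositionTable(fieldGeneratorConfig())
  set.seed(5)
  Es <- 10^runif(12, -4.8, 2.8)
  for (E in Es) {
    comp <- interpolateComposition(tab, E)
    expect_s4_class(comp, "FieldComposition")
    expect_equal(sum(speciesRecords(comp)$doseFraction), 1, tolerance = 1e-9)
    expect_true(validObject(comp))
  }
})

test_that("phantom geometry enforces containment", {
  g <- PhantomGeometry()
  expect_equal(g@scoringOffsets[["outer"]] + g@scoringRadius, g@phantomRadius)
  expect_error(PhantomGeometry(scoringOffsets = c(outer = 14.5)), "inside")
})

test_that("the shipped synthetic composition fixture loads and validates", {
  f <- system.file("extdata", "synthetic_outer_composition.csv",
                   package = "neutronRBE")
  tab <- readCompositionCSV(f)
  expect_length(tab, 7)
  expect_true(all(vapply(tab, function(c) isTRUE(validObject(c)), TRUE)))
  expect_equal(unique(vapply(tab, region, "")), "outer")
  mid <- interpolateComposition(tab, 0.05)
  expect_equal(sum(speciesRecords(mid)$doseFraction), 1, tolerance = 1e-9)
})

test_that("composition table round trips losslessly through CSV and JSON", {
  tab <- generateCompositionTable(
    fieldGeneratorConfig(energyGrid = 10^seq(-3, 2, length.out = 7)))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  writeCompositionCSV(tab, fc); writeCompositionJSON(tab, fj)
  for (back in list(readCompositionCSV(fc), readCompositionJSON(fj))) {
    expect_length(back, length(tab))
    for (i in seq_along(tab)) {
      expect_identical(region(back[[i]]), region(tab[[i]]))
      expect_equal(neutronEnergy(back[[i]]), neutronEnergy(tab[[i]]))
      expect_equal(speciesRecords(back[[i]])$doseFraction,
                   speciesRecords(tab[[i]])$doseFraction, tolerance = 1e-15)
      expect_equal(speciesRecords(back[[i]])$yD,
                   speciesRecords(tab[[i]])$yD, tolerance = 1e-15)
    }
  }
  unlink(c(fc, fj))
})
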