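# Moment arithmetic on lineal-energy spectra: worked discrete examples,
# quadrature against an independent oracle, saturation limits, mixing.

test_that("discrete two-line spectrum reproduces hand-computed moments", {
  sp <- LinealEnergySpectrum(c(1, 3), c(0.5, 0.5), discrete = TRUE)
  expect_equal(frequencyMean(sp), 2.0)
  expect_equal(doseMean(sp), 2.5)  # (1 + 9) / (1 + 3)
  d <- doseDistribution(sp)
  expect_equal(fDensity(d), c(0.25, 0.75))
  expect_equal(sum(fDensity(d)), 1)
})

test_that("single-line spectrum is a fixed point of dose weighting", {
  sp <- LinealEnergySpectrum(7.3, 1, discrete = TRUE)
  expect_equal(frequencyMean(sp), 7.3)
  expect_equal(doseMean(sp), 7.3)
  expect_equal(fDensity(doseDistribution(sp)), 1)
})

test_that("log-normal moments match independent fine-grid quadrature", {
  mu <- log(10); sigma <- log(2)
  y <- exp(seq(mu - 7 * sigma, mu + 7 * sigma, length.out = 400))
  sp <- LinealEnergySpectrum(y, dlnorm(y, mu, sigma), normTol = 1e-3)
  dens <- function(x) dlnorm(x, mu, sigma)
  lo <- exp(mu - 9 * sigma); hi <- exp(mu + 9 * sigma)
  yF <- quadOracle(function(x) x * dens(x), lo, hi)
  yD <- quadOracle(function(x) x^2 * dens(x), lo, hi) / yF
  expect_equal(frequencyMean(sp), yF, tolerance = 1e-4)
  expect_equal(doseMean(sp), yD, tolerance = 1e-4)
})

test_that("constructor normalizes small deviations and rejects unit mistakes", {
  sp <- LinealEnergySpectrum(c(1, 2), c(0.502, 0.502), discrete = TRUE)
  expect_equal(sum(fDensity(sp)), 1)
  expect_gt(sp@rawIntegral, 1)
  expect_error(LinealEnergySpectrum(c(1, 2), c(5, 5), discrete = TRUE), "units")
  expect_error(LinealEnergySpectrum(c(2, 1), c(0.5, 0.5)), "increasing")
  expect_error(LinealEnergySpectrum(c(-1, 2), c(0.5, 0.5)), "positive")
  expect_error(LinealEnergySpectrum(c(1, 2), c(-0.5, 1.5), discrete = TRUE),
               "non-negative")
})

test_that("saturation correction has the closed-form value at y = y0", {
  y0 <- 120
  sp <- LinealEnergySpectrum(y0, 1, discrete = TRUE)
  expect_equal(saturationCorrected(sp, y0), y0 * (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("saturation correction approaches the dose mean for large y0", {
  sp <- generateSpeciesSpectrum("proton", targetYD = 60, gsd = 1.8)
  yD <- doseMean(sp)
  y0 <- 100 * max(yGrid(sp))
  expect_equal(saturationCorrected(sp, y0), yD, tolerance = 1e-3)
})

test_that("y* is monotone in y0, bounded by yD and by y0^2/yF", {
  set.seed(7)
  for (i in 1:20) {
    yD <- runif(1, 5, 400)
    sp <- generateSpeciesSpectrum("proton", yD, gsd = runif(1, 1.2, 2.5))
    y0s <- c(100, 150, 200, 400)
    ys <- vapply(y0s, function(y0) saturationCorrected(sp, y0), 0)
    expect_true(all(diff(ys) >= -1e-9))
    expect_true(all(ys <= doseMean(sp) * (1 + 1e-9)))
    expect_true(all(ys <= y0s^2 / frequencyMean(sp) * (1 + 1e-9)))
  }
  expect_error(saturationCorrected(sp, -1), "positive")
})

test_that("yF <= yD for random spectra (Cauchy-Schwarz)", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    y <- sort(runif(n, 0.01, 500))
    y <- y[!duplicated(y)]
    f <- runif(length(y))
    f <- f / sum(f)
    sp <- LinealEnergySpectrum(y, f, discrete = TRUE)
    expect_lte(frequencyMean(sp), doseMean(sp) * (1 + 1e-12))
  }
})

test_that("microdosimetric summary satisfies its invariants", {
  sp <- generateSpeciesSpectrum("alpha", 150, gsd = 2)
  s <- microdoseSummary(sp, y0 = 150)
  expect_s4_class(s, "MicrodoseSummary")
  expect_lte(s@yF, s@yD)
  expect_lte(s@yStar, s@yD)
})

test_that("mixing is exact for discrete spectra and obeys the weighted-mean identity", {
  a <- LinealEnergySpectrum(c(1, 3), c(0.5, 0.5), discrete = TRUE)   # yD 2.5
  b <- LinealEnergySpectrum(10, 1, discrete = TRUE)                  # yD 10
  mx <- mixSpectra(list(a, b), c(0.5, 0.5))
  expect_equal(mx$summary@yD, 0.5 * 2.5 + 0.5 * 10)
  one <- mixSpectra(list(a), 1)
  expect_equal(one$summary@yD, 2.5)
})

test_that("continuous mixture dose mean equals the brute-force moment of the summed density", {
  set.seed(23)
  for (rep in 1:5) {
    k <- 3
    yDs <- runif(k, 3, 300)
    specs <- lapply(yDs, function(t) generateSpeciesSpectrum("proton", t, gsd = 1.6))
    w <- runif(k); w <- w / sum(w)
    mx <- mixSpectra(specs, w, nGrid = 2048)
    grid <- yGrid(mx$spectrum)
    dmix <- rep(0, length(grid))
    comp_yD <- numeric(k)
    for (i in seq_len(k)) {
      ds <- doseDistribution(specs[[i]])
      di <- approx(yGrid(ds), fDensity(ds), xout = grid, yleft = 0, yright = 0)$y
      I <- pracma::trapz(grid, di)
      dmix <- dmix + w[i] * di / I
      comp_yD[i] <- pracma::trapz(grid, grid * di / I)
    }
    oracle <- pracma::trapz(grid, grid * dmix)
    expect_equal(mx$summary@yD, oracle, tolerance = 1e-6)
    expect_equal(mx$summary@yD, sum(w * comp_yD), tolerance = 1e-6)
  }
})

test_that("mixing rejects bad weights and empty input", {
  a <- LinealEnergySpectrum(c(1, 3), c(0.5, 0.5), discrete = TRUE)
  expect_error(mixSpectra(list(), numeric(0)), "no spectra")
  expect_error(mixSpectra(list(a, a), c(0.6, 0.6)), "sum")
  expect_error(mixSpectra(list(a, a), c(-0.2, 1.2)), ">= 0")
})

test_that("moments are stable under grid refinement", {
  mk <- function(n) {
    mu <- log(30); sigma <- log(1.9)
    y <- exp(seq(mu - 7 * sigma, mu + 7 * sigma, length.out = n))
    LinealEnergySpectrum(y, dlnorm(y, mu, sigma), normTol = 1e-3)
  }
  coarse <- mk(256); fine <- mk(512)
  expect_equal(doseMean(coarse), doseMean(fine), tolerance = 1e-4)
  expect_equal(frequencyMean(coarse), frequencyMean(fine), tolerance = 1e-4)
  expect_equal(saturationCorrected(coarse, 150), saturationCorrected(fine, 150),
               tolerance = 1e-4)
})

test_that("frequencyDistribution inverts doseDistribution", {
  sp <- generateSpeciesSpectrum("C", 300, gsd = 2)
  back <- frequencyDistribution(doseDistribution(sp))
  expect_equal(fDensity(back), fDensity(sp), tolerance = 1e-9)
})

test_that("spectrum CSV round trip preserves the spectrum", {
  sp <- generateSpeciesSpectrum("proton", 50, gsd = 1.5, nGrid = 128)
  f <- tempfile(fileext = ".csv")
  writeSpectrumCSV(sp, f)
  back <- readSpectrumCSV(f, normTol = 1e-3)
  expect_equal(yGrid(back), yGrid(sp), tolerance = 1e-12)
  expect_equal(doseMean(back), doseMean(sp), tolerance = 1e-10)
  unlink(f)
})
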