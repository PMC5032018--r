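# Moment arithmetic for lineal-energy spectra.
#
# Continuous spectra live on (typically log-spaced) grids and are integrated
# with trapezoidal quadrature; discrete line spectra carry probability masses
# and are handled by exact summation, so worked examples with a handful of
# lines incur no quadrature error.

.spectrumIntegral <- function(y, v, discrete) {
  if (discrete) sum(v) else pracma::trapz(y, v)
}

#' Construct a lineal-energy spectrum
#'
#' Builds a [LinealEnergySpectrum-class] from a y grid and density values.
#' The constructor records the raw integral and renormalizes the density to
#' unit integral when the deviation is below `normTol` (default 1%, a guard
#' against unit mistakes such as keV vs keV/um); larger deviations are an
#' error.
#'
#' @param y lineal energy grid, keV/um, strictly increasing, positive.
#' @param f density per keV/um (continuous) or probability masses (discrete).
#' @param discrete logical, TRUE for a line spectrum.
#' @param siteDiameter um, metadata only (default 1).
#' @param label free text.
#' @param normTol maximal tolerated deviation of the raw integral from 1.
#' @return a `LinealEnergySpectrum`
#' @examples
#' sp <- LinealEnergySpectrum(c(1, 3), c(0.5, 0.5), discrete = TRUE)
#' frequencyMean(sp)  # 2
#' doseMean(sp)       # 2.5
#' @export
LinealEnergySpectrum <- function(y, f, discrete = FALSE, siteDiameter = 1.0,
                                 label = "", normTol = 0.01) {
  y <- as.numeric(y)
  f <- as.numeric(f)
  if (length(y) == 0L || length(y) != length(f))
    stop("y and f must be non-empty vectors of equal length")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("lineal energies must be positive and finite")
  if (length(y) > 1L && any(diff(y) <= 0))
    stop("y grid must be strictly increasing")
  if (any(!is.finite(f)) || any(f < 0))
    stop("density values must be non-negative and finite")
  I <- .spectrumIntegral(y, f, discrete)
  if (!is.finite(I) || I <= 0)
    stop("degenerate spectrum: density integrates to zero")
  if (abs(I - 1) > normTol)
    stop(sprintf(
      "density integral %.6g deviates from 1 by more than %g; check units",
      I, normTol))
  new("LinealEnergySpectrum",
      yGrid = y, fDensity = f / I, discrete = discrete,
      siteDiameter = siteDiameter, label = label, rawIntegral = I)
}

#' @rdname LinealEnergySpectrum-class
#' @export
setMethod("yGrid", "LinealEnergySpectrum", function(object) object@yGrid)

#' @rdname LinealEnergySpectrum-class
#' @export
setMethod("fDensity", "LinealEnergySpectrum", function(object) object@fDensity)

#' @rdname LinealEnergySpectrum-class
#' @export
setMethod("siteDiameter", "LinealEnergySpectrum", function(object) object@siteDiameter)

setMethod("show", "LinealEnergySpectrum", function(object) {
  cat(sprintf(
    "LinealEnergySpectrum (%s, %d %s, y in [%.4g, %.4g] keV/um, site %.3g um)\n",
    if (nzchar(object@label)) object@label else "unlabelled",
    length(object@yGrid),
    if (object@discrete) "lines" else "grid points",
    min(object@yGrid), max(object@yGrid), object@siteDiameter))
  cat(sprintf("  yF = %.4g, yD = %.4g keV/um\n",
              frequencyMean(object), doseMean(object)))
})

#' @rdname frequencyMean
#' @export
setMethod("frequencyMean", "LinealEnergySpectrum", function(spec) {
  .spectrumIntegral(spec@yGrid, spec@yGrid * spec@fDensity, spec@discrete)
})

#' @rdname doseMean
#' @export
setMethod("doseMean", "LinealEnergySpectrum", function(spec) {
  yF <- frequencyMean(spec)
  if (yF <= 0) stop("degenerate spectrum: yF = 0")
  .spectrumIntegral(spec@yGrid, spec@yGrid^2 * spec@fDensity, spec@discrete) / yF
})

#' @rdname saturationCorrected
#' @export
setMethod("saturationCorrected", "LinealEnergySpectrum", function(spec, y0) {
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0) || y0 <= 0)
    stop("saturation parameter y0 must be a positive number")
  yF <- frequencyMean(spec)
  if (yF <= 0) stop("degenerate spectrum: yF = 0")
  sat <- -expm1(-(spec@yGrid / y0)^2)  # 1 - exp(-y^2/y0^2), accurately
  y0^2 * .spectrumIntegral(spec@yGrid, sat * spec@fDensity, spec@discrete) / yF
})

#' @rdname doseDistribution
#' @export
setMethod("doseDistribution", "LinealEnergySpectrum", function(spec) {
  yF <- frequencyMean(spec)
  if (yF <= 0) stop("degenerate spectrum: yF = 0")
  new("LinealEnergySpectrum",
      yGrid = spec@yGrid,
      fDensity = spec@yGrid * spec@fDensity / yF,
      discrete = spec@discrete,
      siteDiameter = spec@siteDiameter,
      label = paste0(spec@label, if (nzchar(spec@label)) " " else "", "[dose distribution]"),
      rawIntegral = 1)
})

#' @rdname frequencyDistribution
#' @export
setMethod("frequencyDistribution", "LinealEnergySpectrum", function(spec) {
  v <- spec@fDensity / spec@yGrid
  I <- .spectrumIntegral(spec@yGrid, v, spec@discrete)
  if (!is.finite(I) || I <= 0) stop("degenerate spectrum")
  new("LinealEnergySpectrum",
      yGrid = spec@yGrid, fDensity = v / I, discrete = spec@discrete,
      siteDiameter = spec@siteDiameter,
      label = sub(" ?\\[dose distribution\\]$", "", spec@label),
      rawIntegral = 1)
})

#' Summarize a spectrum by its microdosimetric moments
#'
#' @param spec a `LinealEnergySpectrum` (frequency distribution)
#' @param y0 saturation parameter, keV/um (default 150)
#' @return a [MicrodoseSummary-class]
#' @export
microdoseSummary <- function(spec, y0 = 150) {
  new("MicrodoseSummary",
      yF = frequencyMean(spec),
      yD = doseMean(spec),
      yStar = saturationCorrected(spec, y0),
      y0 = y0)
}

setMethod("show", "MicrodoseSummary", function(object) {
  cat(sprintf(
    "MicrodoseSummary: yF = %.4g, yD = %.4g, y* = %.4g keV/um (y0 = %g)\n",
    object@yF, object@yD, object@yStar, object@y0))
})

#' Mix lineal-energy spectra by dose fractions
#'
#' Dose-weighted mixing of component spectra: the mixed dose distribution is
#' the dose-fraction-weighted sum of the component dose distributions,
#' `d_mix = sum(w_s * d_s)`, so that the mixed dose-mean lineal energy is
#' exactly the weighted mean of the component values.  Continuous components
#' are resampled onto a common log-spaced grid (each resampled component
#' renormalized before summation, so the identity holds to quadrature
#' precision); all-discrete inputs are combined exactly.
#'
#' @param spectra list of `LinealEnergySpectrum` (frequency distributions)
#' @param doseFractions non-negative weights summing to 1 within 1e-6
#' @param y0 saturation parameter for the returned summary, keV/um
#' @param nGrid size of the common grid for continuous mixing
#' @return list with elements `spectrum` (the mixed dose distribution, a
#'   `LinealEnergySpectrum`) and `summary` (a `MicrodoseSummary` of the
#'   mixed field)
#' @export
mixSpectra <- function(spectra, doseFractions, y0 = 150, nGrid = 1024) {
  if (length(spectra) == 0L) stop("no spectra to mix")
  if (!all(vapply(spectra, is, TRUE, "LinealEnergySpectrum")))
    stop("all components must be LinealEnergySpectrum objects")
  w <- as.numeric(doseFractions)
  if (length(w) != length(spectra)) stop("one dose fraction per spectrum required")
  if (any(w < 0)) stop("dose fractions must be >= 0")
  if (abs(sum(w) - 1) > 1e-6)
    stop(sprintf("dose fractions sum to %.8g, not 1", sum(w)))

  doseSpecs <- lapply(spectra, doseDistribution)
  allDiscrete <- all(vapply(spectra, function(s) s@discrete, TRUE))

  if (allDiscrete) {
    y <- unlist(lapply(doseSpecs, yGrid))
    v <- unlist(Map(function(s, wi) fDensity(s) * wi, doseSpecs, w))
    agg <- tapply(v, y, sum)
    yy <- as.numeric(names(agg))
    o <- order(yy)
    mixed <- new("LinealEnergySpectrum",
                 yGrid = yy[o], fDensity = as.numeric(agg)[o],
                 discrete = TRUE, siteDiameter = spectra[[1]]@siteDiameter,
                 label = "mixed field [dose distribution]", rawIntegral = 1)
  } else {
    ylim <- range(unlist(lapply(spectra, yGrid)))
    grid <- exp(seq(log(ylim[1]), log(ylim[2]), length.out = nGrid))
    dens <- rep(0, nGrid)
    for (i in seq_along(doseSpecs)) {
      if (w[i] == 0) next
      s <- doseSpecs[[i]]
      d <- approx(yGrid(s), fDensity(s), xout = grid, yleft = 0, yright = 0)$y
      I <- pracma::trapz(grid, d)
      if (I <= 0) stop("component spectrum lost under resampling; widen nGrid")
      dens <- dens + w[i] * d / I
    }
    mixed <- new("LinealEnergySpectrum",
                 yGrid = grid, fDensity = dens, discrete = FALSE,
                 siteDiameter = spectra[[1]]@siteDiameter,
                 label = "mixed field [dose distribution]", rawIntegral = 1)
  }
  fmix <- frequencyDistribution(mixed)
  list(spectrum = mixed, summary = microdoseSummary(fmix, y0 = y0))
}

#' Read / write a lineal-energy spectrum as CSV
#'
#' Columns `y_keV_um, f_density`; a header row is mandatory and `#` comment
#' lines are allowed.
#'
#' @param file path
#' @param ... passed to [LinealEnergySpectrum()]
#' @return `readSpectrumCSV`: a `LinealEnergySpectrum`
#' @export
readSpectrumCSV <- function(file, ...) {
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("y_keV_um", "f_density") %in% names(d)))
    stop("spectrum CSV must have columns y_keV_um, f_density")
  LinealEnergySpectrum(d$y_keV_um, d$f_density, ...)
}

#' @rdname readSpectrumCSV
#' @param spec a `LinealEnergySpectrum`
#' @export
writeSpectrumCSV <- function(spec, file) {
  utils::write.csv(
    data.frame(y_keV_um = yGrid(spec), f_density = fDensity(spec)),
    file, row.names = FALSE)
  invisible(file)
}
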