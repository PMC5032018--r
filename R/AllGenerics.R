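#' @rdname LinealEnergySpectrum-class
#' @param object,spec a `LinealEnergySpectrum`
#' @export
setGeneric("yGrid", function(object) standardGeneric("yGrid"))

#' @rdname LinealEnergySpectrum-class
#' @export
setGeneric("fDensity", function(object) standardGeneric("fDensity"))

#' @rdname LinealEnergySpectrum-class
#' @export
setGeneric("siteDiameter", function(object) standardGeneric("siteDiameter"))

#' Frequency-mean lineal energy
#'
#' First moment of the frequency distribution f(y).
#' @param spec a `LinealEnergySpectrum` (frequency distribution)
#' @return keV/um
#' @export
setGeneric("frequencyMean", function(spec) standardGeneric("frequencyMean"))

#' Dose-mean lineal energy
#'
#' First moment of the dose distribution d(y), i.e. the second moment of f(y)
#' over its first moment.  The dose-mean lineal energy is the lineal energy
#' with which, on average, dose is delivered in the site.
#' @param spec a `LinealEnergySpectrum` (frequency distribution)
#' @return keV/um
#' @export
setGeneric("doseMean", function(spec) standardGeneric("doseMean"))

#' Saturation-corrected dose-mean lineal energy
#'
#' Kellerer saturation correction: down-weights very high lineal energies to
#' mimic the overkill effect in survival-related effectiveness,
#' `y* = y0^2 * int (1 - exp(-y^2/y0^2)) f(y) dy / int y f(y) dy`.
#' Monotone non-decreasing in y0, bounded above by the dose-mean lineal
#' energy, which it approaches as y0 grows.
#' @param spec a `LinealEnergySpectrum` (frequency distribution)
#' @param y0 saturation parameter, keV/um (> 0; typically 100-200)
#' @return keV/um
#' @export
setGeneric("saturationCorrected", function(spec, y0) standardGeneric("saturationCorrected"))

#' Dose distribution of lineal energy
#'
#' Converts a frequency distribution f(y) into the dose distribution
#' `d(y) = y f(y) / yF`, which integrates to 1 by construction.
#' @param spec a `LinealEnergySpectrum` (frequency distribution)
#' @return a `LinealEnergySpectrum` holding d(y)
#' @export
setGeneric("doseDistribution", function(spec) standardGeneric("doseDistribution"))

#' Frequency distribution from a dose distribution
#'
#' Inverse of [doseDistribution()]: `f(y)` proportional to `d(y)/y`,
#' renormalized.
#' @param spec a `LinealEnergySpectrum` (dose distribution)
#' @return a `LinealEnergySpectrum` holding f(y)
#' @export
setGeneric("frequencyDistribution", function(spec) standardGeneric("frequencyDistribution"))

#' @rdname FieldComposition-class
#' @param object a `FieldComposition`
#' @export
setGeneric("neutronEnergy", function(object) standardGeneric("neutronEnergy"))

#' @rdname FieldComposition-class
#' @export
setGeneric("region", function(object) standardGeneric("region"))

#' @rdname FieldComposition-class
#' @export
setGeneric("speciesRecords", function(object) standardGeneric("speciesRecords"))

#' @rdname DamageCurve-class
#' @param object a `DamageCurve`
#' @export
setGeneric("curveParams", function(object) standardGeneric("curveParams"))

#' @rdname DamageCurve-class
#' @export
setGeneric("letRange", function(object) standardGeneric("letRange"))

#' @rdname BreakPattern-class
#' @param object a `BreakPattern`
#' @export
setGeneric("chromSizes", function(object) standardGeneric("chromSizes"))

#' @rdname BreakPattern-class
#' @export
setGeneric("dsbPositions", function(object) standardGeneric("dsbPositions"))

#' Score genomic damage endpoints on a break pattern
#'
#' @param pattern a `BreakPattern`
#' @param ... scoring options, see the method
#' @return a `DamageScore`
#' @export
setGeneric("scoreBreaks", function(pattern, ...) standardGeneric("scoreBreaks"))
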