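#' @import methods
#' @importFrom stats approx lm vcov coef setNames rpois runif
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics lines legend
#' @importClassesFrom GenomicRanges GRanges
NULL

# Closed enumeration of secondary charged species tracked in the mixed field.
# Tissue species with Z > 8 are excluded; their dose is carried as a logged
# residual on the composition object.
.SPECIES <- c("electron", "proton", "deuteron", "alpha", "C", "N", "O")

.ENDPOINTS <- c("short_fragments", "dsb_clusters")
.REGIONS <- c("inner", "intermediate", "outer")
.CURVE_FORMS <- c("power_law", "power_law_clustered")

#' LinealEnergySpectrum: a tabulated lineal-energy distribution
#'
#' Holds a probability distribution of lineal energy y (keV/um) in a
#' micrometric sensitive site, either as a continuous density tabulated on a
#' strictly increasing grid (integrated by trapezoidal quadrature) or as a
#' discrete line spectrum (probability masses at a set of y values, integrated
#' exactly by summation).  The same container is used for frequency
#' distributions f(y) and for dose distributions d(y); which one it is, is a
#' matter of bookkeeping by the caller (see [doseDistribution()] and
#' [frequencyDistribution()]).
#'
#' @slot yGrid numeric, lineal energy values in keV/um, strictly increasing,
#'   all positive.
#' @slot fDensity numeric, probability density per keV/um (continuous) or
#'   probability masses (discrete); non-negative, finite, normalized to unit
#'   integral/sum at construction.
#' @slot discrete logical, TRUE for a line spectrum.
#' @slot siteDiameter numeric, diameter of the sensitive site in um
#'   (metadata only; default 1 um, the scale of chromosome domains).
#' @slot label character, free-text description.
#' @slot rawIntegral numeric, the integral of the density as supplied before
#'   renormalization.
#' @export
setClass("LinealEnergySpectrum",
  representation(
    yGrid = "numeric",
    fDensity = "numeric",
    discrete = "logical",
    siteDiameter = "numeric",
    label = "character",
    rawIntegral = "numeric"
  )
)

setValidity("LinealEnergySpectrum", function(object) {
  y <- object@yGrid
  f <- object@fDensity
  if (length(y) == 0L) return("empty y grid")
  if (length(y) != length(f)) return("yGrid and fDensity lengths differ")
  if (any(!is.finite(y)) || any(y <= 0)) return("yGrid must be positive and finite")
  if (length(y) > 1L && any(diff(y) <= 0)) return("yGrid must be strictly increasing")
  if (any(!is.finite(f)) || any(f < 0)) return("fDensity must be non-negative and finite")
  I <- if (object@discrete) sum(f) else pracma::trapz(y, f)
  if (abs(I - 1) > 1e-6) return(sprintf("density not normalized (integral %.8g)", I))
  TRUE
})

#' MicrodoseSummary: moment summary of a lineal-energy spectrum
#'
#' @slot yF frequency-mean lineal energy, keV/um.
#' @slot yD dose-mean lineal energy, keV/um.
#' @slot yStar saturation-corrected dose-mean lineal energy, keV/um.
#' @slot y0 saturation parameter, keV/um.
#' @export
setClass("MicrodoseSummary",
  representation(yF = "numeric", yD = "numeric", yStar = "numeric", y0 = "numeric")
)

setValidity("MicrodoseSummary", function(object) {
  tol <- 1e-8
  if (object@yF > object@yD * (1 + 1e-9) + tol)
    return("yF must not exceed yD")
  if (object@yStar > object@yD * (1 + 1e-9) + tol)
    return("yStar must not exceed yD")
  if (object@yStar > object@y0^2 / object@yF * (1 + 1e-9) + tol)
    return("yStar must not exceed y0^2 / yF")
  TRUE
})

#' FieldComposition: per-species condensation of the mixed field
#'
#' The two-number-per-species condensation of the neutron-induced secondary
#' charged-particle field at one neutron energy and one scoring region: for
#' each species its relative contribution to the total neutron dose and its
#' dose-mean lineal energy, both with uncertainties.
#'
#' @slot neutronEnergy primary neutron energy, MeV.
#' @slot region scoring region, one of "inner", "intermediate", "outer".
#' @slot records data.frame with one row per species and columns
#'   `species`, `doseFraction`, `doseFractionErr`, `yD`, `yDErr`.
#' @slot residualZ numeric, dose fraction attributed to excluded Z > 8
#'   species (logged, not modelled; must be <= 0.05).
#' @export
setClass("FieldComposition",
  representation(
    neutronEnergy = "numeric",
    region = "character",
    records = "data.frame",
    residualZ = "numeric"
  )
)

setValidity("FieldComposition", function(object) {
  r <- object@records
  need <- c("species", "doseFraction", "doseFractionErr", "yD", "yDErr")
  if (!all(need %in% names(r))) return("records must have columns species, doseFraction, doseFractionErr, yD, yDErr")
  if (nrow(r) == 0L) return("composition has no species records")
  if (!all(r$species %in% .SPECIES)) return("unknown species label")
  if (anyDuplicated(r$species)) return("duplicate species records")
  if (any(r$doseFraction < 0 | r$doseFraction > 1)) return("dose fractions must lie in [0, 1]")
  if (any(r$doseFractionErr < 0)) return("dose fraction errors must be >= 0")
  if (any(r$yD <= 0)) return("yD must be positive")
  if (any(r$yDErr < 0)) return("yD errors must be >= 0")
  if (abs(sum(r$doseFraction) - 1) > 1e-3)
    return(sprintf("dose fractions sum to %.6f, not 1 within 1e-3", sum(r$doseFraction)))
  if (!object@region %in% .REGIONS) return("region must be inner, intermediate or outer")
  if (length(object@residualZ) != 1L || object@residualZ < 0 || object@residualZ > 0.05)
    return("residual Z>8 dose fraction must lie in [0, 0.05]")
  TRUE
})

#' PhantomGeometry: scoring geometry of the tissue phantom
#'
#' Spherical soft-tissue phantom with spherical scoring regions positioned at
#' different offsets from the centre along a common diameter (metadata for
#' the depth-dependent moderation model).
#'
#' @slot phantomRadius cm (default 15).
#' @slot scoringRadius cm (default 1.5).
#' @slot scoringOffsets named numeric, cm offsets of the region centres
#'   (defaults inner 0, intermediate 7.5, outer 13.5).
#' @export
setClass("PhantomGeometry",
  representation(
    phantomRadius = "numeric",
    scoringRadius = "numeric",
    scoringOffsets = "numeric"
  )
)

setValidity("PhantomGeometry", function(object) {
  if (object@phantomRadius <= 0 || object@scoringRadius <= 0)
    return("radii must be positive")
  if (any(object@scoringOffsets + object@scoringRadius > object@phantomRadius + 1e-12))
    return("scoring regions must fit inside the phantom")
  TRUE
})

#' DamageCurve: analytic damage-yield-versus-LET model
#'
#' An analytic model of DNA damage yield per Gy per cell as a function of
#' LET for one species and one damage endpoint.  Two forms are supported:
#' a pure power law `Y = a * L^n` and a clustered form
#' `Y = A * L^N * exp(-B * L)` which nests the power law at B = 0 and has a
#' single interior maximum at L = N/B, reproducing the rise and fall of
#' cluster yields for heavy ions.
#'
#' @slot species species label.
#' @slot endpoint "short_fragments" or "dsb_clusters".
#' @slot form "power_law" or "power_law_clustered".
#' @slot params named numeric: `a`, `n` or `A`, `N`, `B`.
#' @slot letRange numeric length 2, LET span of the fitted data (keV/um);
#'   evaluation outside the span clamps to the endpoints and flags it.
#' @slot covariance parameter covariance matrix.
#' @export
setClass("DamageCurve",
  representation(
    species = "character",
    endpoint = "character",
    form = "character",
    params = "numeric",
    letRange = "numeric",
    covariance = "matrix"
  )
)

setValidity("DamageCurve", function(object) {
  if (!object@endpoint %in% .ENDPOINTS) return("unknown endpoint")
  if (!object@form %in% .CURVE_FORMS) return("unknown curve form")
  p <- object@params
  if (object@form == "power_law") {
    if (!all(c("a", "n") %in% names(p))) return("power_law needs params a, n")
    if (p[["a"]] <= 0) return("amplitude a must be positive")
  } else {
    if (!all(c("A", "N", "B") %in% names(p))) return("power_law_clustered needs params A, N, B")
    if (p[["A"]] <= 0) return("amplitude A must be positive")
  }
  lr <- object@letRange
  if (length(lr) != 2L || lr[1] <= 0 || lr[1] >= lr[2])
    return("letRange must be 0 < Lmin < Lmax")
  TRUE
})

#' BreakPattern: genomic DSB positions against a chromosome-sizes table
#'
#' DNA double-strand-break positions stored as a `GRanges` of unit-width
#' intervals with `seqlengths` carrying the chromosome sizes.  Break
#' coordinates are 0-based points between base pairs; fragment length between
#' two breaks is the difference of their coordinates.
#'
#' @slot breaks `GRanges` with one range per DSB (width 1), sorted, with
#'   seqlengths set for every chromosome.
#' @export
setClass("BreakPattern", representation(breaks = "GRanges"))

setValidity("BreakPattern", function(object) {
  gr <- object@breaks
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) return("all chromosomes must have a declared length")
  if (length(gr)) {
    if (any(GenomicRanges::width(gr) != 1L)) return("breaks must be unit-width points")
    pos0 <- GenomicRanges::start(gr) - 1L
    if (any(pos0 < 0L)) return("positions must be >= 0")
    lens <- sl[as.character(GenomeInfoDb::seqnames(gr))]
    if (any(pos0 >= lens)) return("positions must lie within chromosome bounds")
    if (S4Vectors::isSorted(gr) != TRUE && !identical(order(gr), seq_along(gr)))
      return("breaks must be sorted")
  }
  TRUE
})

#' DamageScore: genomic damage-endpoint counts for one break pattern
#'
#' @slot nShortFragments count of inter-DSB fragments shorter than the
#'   fragment threshold (default 30 bp, strict).
#' @slot nClusters count of DSB clusters (>= 2 DSBs linked at the cluster
#'   distance threshold, default < 25 bp).
#' @slot multiplicities integer vector of per-cluster DSB counts (each >= 2).
#' @slot nIsolated count of DSBs belonging to no cluster.
#' @export
setClass("DamageScore",
  representation(
    nShortFragments = "integer",
    nClusters = "integer",
    multiplicities = "integer",
    nIsolated = "integer"
  )
)

setValidity("DamageScore", function(object) {
  if (length(object@multiplicities) != object@nClusters)
    return("one multiplicity per cluster required")
  if (object@nClusters > 0L && any(object@multiplicities < 2L))
    return("cluster multiplicities must be >= 2")
  TRUE
})

#' NeutronDamagePoint: coupled neutron-induced damage at one energy
#'
#' @slot neutronEnergy MeV.
#' @slot region scoring region.
#' @slot endpoint damage endpoint.
#' @slot yield damage yield per Gy per cell.
#' @slot yieldErr propagated uncertainty on the yield.
#' @slot contributions data.frame (species, yD used as LET, species yield,
#'   dose-weighted contribution, clamping flag).
#' @export
setClass("NeutronDamagePoint",
  representation(
    neutronEnergy = "numeric",
    region = "character",
    endpoint = "character",
    yield = "numeric",
    yieldErr = "numeric",
    contributions = "data.frame"
  )
)

setValidity("NeutronDamagePoint", function(object) {
  ct <- object@contributions
  if (!all(c("species", "let", "speciesYield", "contribution") %in% names(ct)))
    return("contributions must have species, let, speciesYield, contribution")
  if (any(ct$contribution < 0)) return("contributions must be >= 0")
  if (abs(sum(ct$contribution) - object@yield) > 1e-9 * max(1, object@yield))
    return("yield must equal the sum of per-species contributions")
  TRUE
})

#' RBECurve: RBE values on a neutron-energy grid
#'
#' @slot model "ystar" (saturation-corrected lineal-energy ratio) or
#'   "dsb_cluster" (DSB-cluster yield ratio).
#' @slot y0 saturation parameter used, keV/um (NA for the cluster model).
#' @slot region scoring region.
#' @slot energies MeV.
#' @slot rbe unitless RBE values, >= 0.
#' @slot rbeErr propagated uncertainties.
#' @slot reference label of the reference field.
#' @export
setClass("RBECurve",
  representation(
    model = "character",
    y0 = "numeric",
    region = "character",
    energies = "numeric",
    rbe = "numeric",
    rbeErr = "numeric",
    reference = "character"
  )
)

setValidity("RBECurve", function(object) {
  if (!object@model %in% c("ystar", "dsb_cluster")) return("unknown RBE model")
  n <- length(object@energies)
  if (length(object@rbe) != n || length(object@rbeErr) != n)
    return("energies, rbe and rbeErr must have equal length")
  if (any(object@rbe < 0)) return("RBE values must be >= 0")
  TRUE
})

#' ReferenceField: photon reference field scalars for RBE ratios
#'
#' Reference low-LET photon field characterised by its saturation-corrected
#' dose-mean lineal energy (one value per saturation parameter y0) and its
#' DSB-cluster yield per Gy per cell.  Defaults are produced by the synthetic
#' photon fixture (see [syntheticReferenceField()]); the label describes the
#' field they emulate.
#'
#' @slot label free text, default "X-ray 220 kV, 2 mm Cu (synthetic)".
#' @slot yStarRef named numeric, keV/um, names are y0 values.
#' @slot clusterYieldRef DSB-cluster yield per Gy per cell.
#' @export
setClass("ReferenceField",
  representation(
    label = "character",
    yStarRef = "numeric",
    clusterYieldRef = "numeric"
  )
)

setValidity("ReferenceField", function(object) {
  if (any(object@yStarRef <= 0) || any(object@clusterYieldRef <= 0))
    return("reference values must be positive")
  if (is.null(names(object@yStarRef))) return("yStarRef must be named by y0")
  TRUE
})

#' FieldGeneratorConfig: configuration of the synthetic mixed-field generator
#'
#' All calibrated constants of the synthetic composition generator live here
#' with documented provenance (see the package vignette).  The generator is an
#' emulator of the mechanisms governing the neutron-induced secondary field
#' (capture dominance at low energy, elastic proton recoil at intermediate
#' energy, threshold-gated alpha/heavy-recoil channels, depth-dependent
#' moderation), not a transport code.
#'
#' @slot energyGrid neutron energies, MeV (default 49 log-spaced nodes over
#'   1e-5 to 1e3 MeV).
#' @slot region scoring region.
#' @slot captureCrossover named numeric, MeV per region: energy at which
#'   electron (capture-photon) dose dominance gives way to proton recoil.
#' @slot thresholds named numeric, MeV: opening energies of the reaction
#'   channels feeding N, O, C recoils and alpha emission.
#' @slot moderationStrength named numeric per region: asymptotic fraction of
#'   dose delivered by the moderated (capture-dominated) field component.
#' @slot moderationEnergy named numeric, MeV per region: energy scale above
#'   which moderation becomes ineffective.
#' @slot seed integer seed for any sampled generator (the composition table
#'   itself is deterministic).
#' @export
setClass("FieldGeneratorConfig",
  representation(
    energyGrid = "numeric",
    region = "character",
    captureCrossover = "numeric",
    thresholds = "numeric",
    moderationStrength = "numeric",
    moderationEnergy = "numeric",
    seed = "integer"
  )
)

setValidity("FieldGeneratorConfig", function(object) {
  if (length(object@energyGrid) < 2L || any(diff(object@energyGrid) <= 0))
    return("energy grid must be increasing with >= 2 nodes")
  if (any(object@energyGrid <= 0)) return("energies must be positive")
  if (!object@region %in% .REGIONS) return("unknown region")
  if (any(object@thresholds <= 0)) return("thresholds must be positive")
  if (!all(c("N", "O", "C", "alpha") %in% names(object@thresholds)))
    return("thresholds must be named for N, O, C and alpha")
  TRUE
})

#' StoppingPowerTable: tabulated electronic stopping power and range
#'
#' Embedded analytic parameterization of electronic stopping power in
#' unit-density soft tissue for one ion species, with CSDA-style range
#' obtained by quadrature.  A stand-in for track-structure physics: accuracy
#' at the few-per-cent level is sufficient because only the placement of
#' dose-mean lineal energies, not dosimetry, depends on it.
#'
#' @slot species ion species label.
#' @slot energyGrid kinetic energy per nucleon, MeV/u.
#' @slot stopping electronic stopping power, keV/um at unit density.
#' @slot range range in um (total kinetic energy over the same grid).
#' @export
setClass("StoppingPowerTable",
  representation(
    species = "character",
    energyGrid = "numeric",
    stopping = "numeric",
    range = "numeric"
  )
)

setValidity("StoppingPowerTable", function(object) {
  if (any(object@stopping <= 0)) return("stopping power must be positive")
  if (any(diff(object@range) <= 0)) return("range must increase with energy")
  s <- object@stopping
  imax <- which.max(s)
  if (imax == 1L || imax == length(s))
    return("stopping power must have an interior maximum (Bragg peak)")
  TRUE
})
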