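# Two energy-dependent neutron RBE models and the regulatory reference
# curves plotted alongside them for qualitative comparison.
#
# The phenomenological model divides the neutron field's saturation-corrected
# dose-mean lineal energy y* by the reference photon field's y* at the same
# saturation parameter.  The mechanistic model divides the neutron-induced
# DSB-cluster yield per Gy per cell (linear in dose: cooperation of two
# tracks on a < 25 bp genomic stretch is negligible, so the cluster yield
# scales with the number of tracks and hence with dose) by the photon
# cluster yield.

#' Reference photon field constructor
#'
#' @param label free text
#' @param yStarRef named numeric keV/um, names are the y0 values (keV/um)
#' @param clusterYieldRef DSB-cluster yield per Gy per cell
#' @return a [ReferenceField-class]
#' @export
ReferenceField <- function(label, yStarRef, clusterYieldRef) {
  new("ReferenceField", label = label, yStarRef = yStarRef,
      clusterYieldRef = clusterYieldRef)
}

setMethod("show", "ReferenceField", function(object) {
  cat(sprintf("ReferenceField: %s\n", object@label))
  cat("  y* [keV/um]:",
      paste(sprintf("y0=%s: %.4g", names(object@yStarRef), object@yStarRef),
            collapse = ", "), "\n")
  cat(sprintf("  DSB-cluster yield: %.4g per Gy per cell\n",
              object@clusterYieldRef))
})

#' Synthetic photon reference field
#'
#' Builds the default reference field from the synthetic low-LET photon
#' fixture: a single-species (electron-like) log-normal lineal-energy
#' spectrum with dose-mean lineal energy `yDRef` (keV/um, default 5, typical
#' of a filtered 200-kV X-ray field in a 1-um site), whose y* values per
#' saturation parameter are computed by quadrature, and whose DSB-cluster
#' yield is read from the proton cluster curve at the same dose-mean lineal
#' energy (the low-LET end of the proton curve, exactly as electron damage
#' is handled in the coupling).  The actual machine spectrum the label
#' describes is a transport-code output and is not reproduced; this is a
#' synthetic stand-in, so only RBE shapes, not absolute levels, are
#' quantitatively meaningful.
#'
#' @param y0s saturation parameters for which y* is tabulated, keV/um
#' @param yDRef dose-mean lineal energy of the reference field, keV/um
#' @param gsd geometric standard deviation of the reference spectrum
#' @param protonClusterCurve `DamageCurve` used for the cluster yield
#'   (default: the package's default proton DSB-cluster curve)
#' @return a [ReferenceField-class]
#' @export
syntheticReferenceField <- function(y0s = c(100, 150, 200), yDRef = 5.0,
                                    gsd = 2.5,
                                    protonClusterCurve = NULL) {
  spec <- generateSpeciesSpectrum("electron", targetYD = yDRef, gsd = gsd)
  ys <- vapply(y0s, function(y0) saturationCorrected(spec, y0), 0)
  names(ys) <- as.character(y0s)
  if (is.null(protonClusterCurve))
    protonClusterCurve <- defaultDamageCurves("dsb_clusters")[["proton"]]
  cl <- as.numeric(evalDamage(protonClusterCurve, yDRef))
  ReferenceField("X-ray 220 kV, 2 mm Cu (synthetic)", ys, cl)
}

.refYStar <- function(ref, y0) {
  key <- as.character(y0)
  if (!key %in% names(ref@yStarRef))
    stop(sprintf("reference field has no y* for y0 = %s keV/um (available: %s)",
                 key, paste(names(ref@yStarRef), collapse = ", ")))
  ref@yStarRef[[key]]
}

#' RBE from saturation-corrected dose-mean lineal energies
#'
#' Ratio of the neutron field's y* to the reference photon field's y* at the
#' same saturation parameter, with relative errors propagated as
#' independent.
#'
#' @param yStarN neutron y*, keV/um (vectorized)
#' @param ref a `ReferenceField`
#' @param y0 saturation parameter, keV/um; must be tabulated in `ref`
#' @param yStarNErr absolute uncertainty on `yStarN` (default 0)
#' @param refErr absolute uncertainty on the reference y* (default 0)
#' @return RBE values with attribute `err`
#' @export
rbeYstar <- function(yStarN, ref, y0, yStarNErr = 0, refErr = 0) {
  if (any(yStarN <= 0)) stop("neutron y* must be positive")
  yr <- .refYStar(ref, y0)
  rbe <- yStarN / yr
  attr(rbe, "err") <- rbe * sqrt((yStarNErr / yStarN)^2 + (refErr / yr)^2)
  rbe
}

#' RBE from DSB-cluster induction
#'
#' Ratio of the neutron-induced DSB-cluster yield per Gy per cell to the
#' reference photon field's cluster yield.
#'
#' @param Yn neutron cluster yield per Gy per cell (vectorized)
#' @param ref a `ReferenceField`
#' @param YnErr absolute uncertainty on `Yn` (default 0)
#' @param refErr absolute uncertainty on the reference yield (default 0)
#' @return RBE values with attribute `err`
#' @export
rbeCluster <- function(Yn, ref, YnErr = 0, refErr = 0) {
  if (any(Yn < 0)) stop("cluster yields must be >= 0")
  yr <- ref@clusterYieldRef
  if (yr <= 0) stop("reference cluster yield must be positive")
  rbe <- Yn / yr
  attr(rbe, "err") <- ifelse(Yn > 0,
    rbe * sqrt((YnErr / pmax(Yn, .Machine$double.xmin))^2 + (refErr / yr)^2), 0)
  rbe
}

#' RBE curve from a composition table (y* model)
#'
#' Builds per-node mixed lineal-energy spectra from the composition table
#' (moment-matched log-normal per species), computes y* at each node and
#' divides by the reference photon y*.
#'
#' @param table list of `FieldComposition`, one region
#' @param ref a `ReferenceField`
#' @param y0 saturation parameter, keV/um
#' @param gsd geometric standard deviation of the per-species spectra
#' @return an [RBECurve-class]
#' @export
rbeCurveYstar <- function(table, ref, y0 = 150, gsd = 1.8) {
  ys <- ystarCurve(table, y0 = y0, gsd = gsd)
  rbe <- rbeYstar(ys$ystar, ref, y0)
  new("RBECurve", model = "ystar", y0 = y0,
      region = unique(ys$region), energies = ys$E_n_MeV,
      rbe = as.numeric(rbe), rbeErr = as.numeric(attr(rbe, "err")),
      reference = ref@label)
}

#' RBE curve from a coupled damage curve (DSB-cluster model)
#'
#' @param damage result of [neutronDamageCurve()] for endpoint
#'   `"dsb_clusters"`
#' @param ref a `ReferenceField`
#' @return an [RBECurve-class]
#' @export
rbeCurveCluster <- function(damage, ref) {
  if (unique(damage$endpoint) != "dsb_clusters")
    stop("cluster RBE requires a dsb_clusters damage curve")
  rbe <- rbeCluster(damage$yield, ref, YnErr = damage$yield_err)
  new("RBECurve", model = "dsb_cluster", y0 = NA_real_,
      region = unique(damage$region), energies = damage$E_n_MeV,
      rbe = as.numeric(rbe), rbeErr = as.numeric(attr(rbe, "err")),
      reference = ref@label)
}

setMethod("show", "RBECurve", function(object) {
  cat(sprintf(
    "RBECurve (%s model%s, %s region, %d energies, reference: %s)\n",
    object@model,
    if (!is.na(object@y0)) sprintf(", y0 = %g keV/um", object@y0) else "",
    object@region, length(object@energies), object@reference))
  cat(sprintf("  RBE range [%.3g, %.3g], peak at E_n = %.3g MeV\n",
              min(object@rbe), max(object@rbe),
              object@energies[which.max(object@rbe)]))
})

#' @rdname RBECurve-class
#' @param x an `RBECurve`
#' @export
rbeValues <- function(x) {
  data.frame(E_n_MeV = x@energies, rbe = x@rbe, rbe_err = x@rbeErr)
}

# ---- regulatory reference curves -------------------------------------------

#' ICRP Publication 103 neutron radiation weighting factor
#'
#' The continuous three-branch w_R function of neutron energy from ICRP
#' Publication 103 (transcribed from the regulation): for E < 1 MeV,
#' `2.5 + 18.2 exp(-(ln E)^2 / 6)`; for 1 <= E <= 50 MeV,
#' `5.0 + 17.0 exp(-(ln 2E)^2 / 6)`; above 50 MeV,
#' `2.5 + 3.25 exp(-(ln 0.04E)^2 / 6)`.  The published branches agree at the
#' boundaries to about 0.01 (the regulation's own rounding), not exactly.
#' For radiation protection purposes only; plotted for qualitative
#' comparison with RBE models.
#'
#' @param En neutron energy, MeV (> 0), vectorized
#' @return w_R, unitless
#' @export
icrp103Wr <- function(En) {
  if (any(!is.finite(En)) || any(En <= 0)) stop("neutron energy must be positive")
  ifelse(En < 1,
         2.5 + 18.2 * exp(-log(En)^2 / 6),
         ifelse(En <= 50,
                5.0 + 17.0 * exp(-log(2 * En)^2 / 6),
                2.5 + 3.25 * exp(-log(0.04 * En)^2 / 6)))
}

# U.S. NRC 10 CFR 20.1004 table: mean quality factor Q for monoenergetic
# neutrons, transcribed from the regulation.
.NRC_Q_TABLE <- data.frame(
  E_MeV = c(2.5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 5e-1,
            1, 2.5, 5, 7, 10, 14, 20, 40, 60, 1e2, 2e2, 3e2, 4e2),
  Q = c(2, 2, 2, 2, 2, 2, 2.5, 7.5, 11,
        11, 9, 8, 7, 6.5, 7.5, 8, 7, 5.5, 4, 3.5, 3.5, 3.5)
)

#' U.S. NRC neutron quality factor
#'
#' Log-linear interpolation (in energy) of the mean quality factor table for
#' monoenergetic neutrons embedded from 10 CFR 20.1004; energies outside the
#' tabulated range are clamped to the nearest table endpoint.
#'
#' @param En neutron energy, MeV (> 0), vectorized
#' @return quality factor Q, unitless
#' @export
nrcQualityFactor <- function(En) {
  if (any(!is.finite(En)) || any(En <= 0)) stop("neutron energy must be positive")
  tab <- .NRC_Q_TABLE
  x <- pmin(pmax(En, tab$E_MeV[1]), tab$E_MeV[nrow(tab)])
  approx(log10(tab$E_MeV), tab$Q, xout = log10(x))$y
}

#' Write an RBE curve with the regulatory comparison columns
#'
#' CSV columns `E_n_MeV, rbe, rbe_err, wr_icrp103, q_nrc`.
#'
#' @param rbeCurve an `RBECurve`
#' @param file path
#' @export
writeRBECurveCSV <- function(rbeCurve, file) {
  d <- rbeValues(rbeCurve)
  d$wr_icrp103 <- icrp103Wr(d$E_n_MeV)
  d$q_nrc <- nrcQualityFactor(d$E_n_MeV)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Plot an RBE curve against the regulatory reference curves
#'
#' Base-graphics comparison plot on a log energy axis; the regulatory curves
#' are labelled "for qualitative comparison" because weighting factors are
#' defined for radiation protection purposes only.
#'
#' @param rbeCurve an `RBECurve`
#' @param ... passed to `plot`
#' @export
plotRBEComparison <- function(rbeCurve, ...) {
  d <- rbeValues(rbeCurve)
  eg <- exp(seq(log(min(d$E_n_MeV)), log(max(d$E_n_MeV)), length.out = 400))
  ylim <- range(0, d$rbe, icrp103Wr(eg), nrcQualityFactor(eg))
  plot(d$E_n_MeV, d$rbe, log = "x", type = "b", pch = 4,
       xlab = "neutron energy [MeV]", ylab = "RBE / weighting factor",
       ylim = ylim, ...)
  lines(eg, icrp103Wr(eg), col = "red")
  lines(eg, nrcQualityFactor(eg), col = "blue", lty = 2)
  legend("topleft", bty = "n",
         legend = c(sprintf("RBE (%s model)", rbeCurve@model),
                    "ICRP 103 w_R (qualitative comparison)",
                    "U.S. NRC Q (qualitative comparison)"),
         col = c("black", "red", "blue"), lty = c(1, 1, 2), pch = c(4, NA, NA))
  invisible(rbeCurve)
}
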