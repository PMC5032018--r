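# Data model and physics helpers for the per-species condensation of the
# neutron-induced mixed field.

# Atomic masses in unified atomic mass units (AME2020 rounding, quoted to
# ~1e-8 u, ample for keV-level Q values) and the u -> MeV conversion.
.AMU_MEV <- 931.49410242
.NEUTRON_MASS_U <- 1.00866491588
.ATOMIC_MASSES_U <- c(
  n   = 1.00866491588,
  H1  = 1.00782503207,
  H2  = 2.01410177785,
  He4 = 4.00260325413,
  C12 = 12.0,
  C14 = 14.00324198843,
  N14 = 14.00307400443,
  O16 = 15.99491461957
)

# Recoil mass (u) used for elastic kinematics, per species label.
.SPECIES_MASS_U <- c(
  proton = 1.00782503207, deuteron = 2.01410177785, alpha = 4.00260325413,
  C = 12.0, N = 14.00307400443, O = 15.99491461957
)

# Charge and nucleon number per ion species (for stopping-power scaling).
.SPECIES_Z <- c(proton = 1, deuteron = 1, alpha = 2, C = 6, N = 7, O = 8)
.SPECIES_A <- c(proton = 1, deuteron = 2, alpha = 4, C = 12, N = 14, O = 16)

.REACTIONS <- list(
  "H(n,g)d" = list(reactants = c("H1", "n"), products = c("H2")),
  "N14(n,p)C14" = list(reactants = c("N14", "n"), products = c("H1", "C14"))
)

#' Q value of an embedded two-body neutron reaction
#'
#' Energy release of a neutron-induced reaction computed from the embedded
#' atomic-mass table (photons are massless and carry the balance).  The two
#' reactions that dominate the capture regime are embedded: radiative capture
#' on hydrogen, `H(n,g)d`, whose 2.22 MeV photon drives the electron dose at
#' low neutron energy, and `N14(n,p)C14`, whose 626 keV release is shared by
#' the proton and the carbon recoil.
#'
#' @param reactionId one of `"H(n,g)d"`, `"N14(n,p)C14"`
#' @param reverse if TRUE, the Q value of the reverse reaction (exact sign
#'   flip by mass-difference antisymmetry)
#' @return Q value in MeV
#' @examples
#' reactionQValue("H(n,g)d")      # 2.2246
#' reactionQValue("N14(n,p)C14")  # 0.6259
#' @export
reactionQValue <- function(reactionId, reverse = FALSE) {
  if (!reactionId %in% names(.REACTIONS))
    stop(sprintf("unknown reaction '%s'; embedded set: %s",
                 reactionId, paste(names(.REACTIONS), collapse = ", ")))
  rx <- .REACTIONS[[reactionId]]
  q <- (sum(.ATOMIC_MASSES_U[rx$reactants]) - sum(.ATOMIC_MASSES_U[rx$products])) * .AMU_MEV
  if (reverse) -q else q
}

#' Maximal elastic energy transfer from a neutron to a nucleus
#'
#' Head-on elastic collision kinematics:
#' `E_max = 4 m_n m_t / (m_n + m_t)^2 * E_n`.  The kinematic fraction is 1
#' exactly when the target mass equals the neutron mass and decreases
#' strictly for heavier targets, which is why recoil protons dominate the
#' neutron dose in the elastic regime.
#'
#' @param En incoming neutron energy, MeV (>= 0)
#' @param mt target nucleus mass, atomic mass units (> 0)
#' @return maximal transferred energy, MeV
#' @examples
#' maxEnergyTransfer(1, 1.00782503)  # ~ 1 MeV (hydrogen target)
#' maxEnergyTransfer(1, 12)          # 0.2861 MeV (carbon target)
#' @export
maxEnergyTransfer <- function(En, mt) {
  if (any(En < 0)) stop("neutron energy must be >= 0")
  if (any(mt <= 0)) stop("target mass must be positive")
  mn <- .NEUTRON_MASS_U
  4 * mn * mt / (mn + mt)^2 * En
}

#' LET from dose and fluence over a microscopic volume
#'
#' Standard fluence-dose relation for charged particles,
#' `D[Gy] = 0.1602 * LET[keV/um] * Phi[um^-2] / rho[g/cm^3]`, inverted for
#' LET.  With the track-structure irradiation grid of 15 pixels of 16 um^2
#' traversed by one particle each, the fluence is 0.0625 particles/um^2.
#'
#' @param dose Gy
#' @param fluence particles per um^2 (> 0)
#' @param density g/cm^3 (default 1, unit-density tissue)
#' @return LET in keV/um
#' @export
letFromDoseFluence <- function(dose, fluence, density = 1.0) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(fluence <= 0)) stop("fluence must be positive")
  if (any(density <= 0)) stop("density must be positive")
  dose * density / (0.1602 * fluence)
}

#' @rdname letFromDoseFluence
#' @param let LET in keV/um
#' @export
doseFromLetFluence <- function(let, fluence, density = 1.0) {
  if (any(let < 0)) stop("LET must be >= 0")
  if (any(fluence <= 0)) stop("fluence must be positive")
  0.1602 * let * fluence / density
}

#' Track-averaged LET of a stopping particle
#'
#' For particles that stop inside the nucleus, the fluence-based LET
#' estimator breaks down and a better indicator is simply the initial
#' kinetic energy divided by the track length.
#'
#' @param E0 initial kinetic energy, MeV
#' @param rangeFn function mapping MeV to range in um
#' @return keV/um
#' @export
trackAverageLET <- function(E0, rangeFn) {
  r <- rangeFn(E0)
  if (any(!is.finite(r)) || any(r <= 0)) stop("range must be positive")
  1000 * E0 / r
}

#' Construct a field composition
#'
#' @param neutronEnergy MeV
#' @param region "inner", "intermediate" or "outer"
#' @param records data.frame with columns `species`, `doseFraction`,
#'   `doseFractionErr`, `yD`, `yDErr` (one row per species)
#' @param residualZ dose fraction of excluded Z > 8 species (logged only)
#' @details Dose-fraction sums inside `[0.95, 1.05]` but off 1 by more than
#'   1e-3 are renormalized at construction with a warning naming the energy
#'   and region (an excluded-species residual, not an error); sums outside
#'   that window are rejected as a broken table.
#' @return a [FieldComposition-class]
#' @export
FieldComposition <- function(neutronEnergy, region, records, residualZ = 0) {
  records <- as.data.frame(records)
  records$species <- as.character(records$species)
  rownames(records) <- NULL
  s <- sum(records$doseFraction)
  if (s < 0.95 || s > 1.05)
    stop(sprintf(
      "dose fractions at E_n = %.4g MeV (%s region) sum to %.4f, outside [0.95, 1.05]",
      neutronEnergy, region, s))
  if (abs(s - 1) > 1e-3) {
    warning(sprintf(
      "renormalizing dose fractions at E_n = %.4g MeV (%s region): sum %.4f",
      neutronEnergy, region, s))
    records$doseFraction <- records$doseFraction / s
    records$doseFractionErr <- records$doseFractionErr / s
  }
  new("FieldComposition",
      neutronEnergy = neutronEnergy, region = region,
      records = records, residualZ = residualZ)
}

#' @rdname FieldComposition-class
#' @export
setMethod("neutronEnergy", "FieldComposition", function(object) object@neutronEnergy)

#' @rdname FieldComposition-class
#' @export
setMethod("region", "FieldComposition", function(object) object@region)

#' @rdname FieldComposition-class
#' @export
setMethod("speciesRecords", "FieldComposition", function(object) object@records)

setMethod("show", "FieldComposition", function(object) {
  cat(sprintf("FieldComposition at E_n = %.4g MeV (%s region, %d species",
              object@neutronEnergy, object@region, nrow(object@records)))
  if (object@residualZ > 0)
    cat(sprintf(", Z>8 residual %.3g", object@residualZ))
  cat(")\n")
  print(object@records, digits = 4)
})

#' Validate (and if needed renormalize) a field composition
#'
#' Enforces the composition invariants.  Dose-fraction sums within
#' `[0.95, 1.05]` are renormalized to 1 (with a warning naming the energy
#' and region); sums outside that window are an error, as they indicate a
#' broken table rather than an excluded-species residual.
#'
#' @param comp a `FieldComposition` or the arguments of [FieldComposition()]
#' @return a validated `FieldComposition`
#' @export
validateComposition <- function(comp) {
  r <- comp@records
  s <- sum(r$doseFraction)
  if (s < 0.95 || s > 1.05)
    stop(sprintf(
      "dose fractions at E_n = %.4g MeV (%s region) sum to %.4f, outside [0.95, 1.05]",
      comp@neutronEnergy, comp@region, s))
  if (abs(s - 1) > 1e-9) {
    r$doseFraction <- r$doseFraction / s
    r$doseFractionErr <- r$doseFractionErr / s
  }
  FieldComposition(comp@neutronEnergy, comp@region, r, comp@residualZ)
}

#' Interpolate a composition table at an arbitrary neutron energy
#'
#' Per-species dose fractions are interpolated linearly in log10 of the
#' neutron energy and renormalized; dose-mean lineal energies are
#' interpolated log-log.  A species absent (zero fraction or missing row) at
#' the lower bracketing node gets fraction 0 at that node, so reaction
#' channels are never extrapolated below their threshold; its yD is carried
#' from the side where the species exists.
#'
#' @param table list of `FieldComposition`, all one region, energies distinct
#' @param En neutron energy, MeV, within the tabulated range
#' @return a `FieldComposition` at `En`
#' @export
interpolateComposition <- function(table, En) {
  if (length(table) == 0L) stop("empty composition table")
  regs <- unique(vapply(table, region, ""))
  if (length(regs) != 1L) stop("all compositions must share one region")
  Es <- vapply(table, neutronEnergy, 0)
  o <- order(Es)
  table <- table[o]; Es <- Es[o]
  if (En < Es[1] || En > Es[length(Es)])
    stop(sprintf("E_n = %.4g MeV outside tabulated range [%.4g, %.4g]",
                 En, Es[1], Es[length(Es)]))
  hit <- which(abs(log10(Es) - log10(En)) < 1e-12)
  if (length(hit)) return(table[[hit[1]]])
  i <- findInterval(En, Es)
  lo <- table[[i]]; hi <- table[[i + 1L]]
  t <- (log10(En) - log10(Es[i])) / (log10(Es[i + 1L]) - log10(Es[i]))

  sp <- union(speciesRecords(lo)$species, speciesRecords(hi)$species)
  pick <- function(comp, s) {
    r <- speciesRecords(comp)
    j <- match(s, r$species)
    if (is.na(j)) list(w = 0, we = 0, yD = NA_real_, ye = 0)
    else list(w = r$doseFraction[j], we = r$doseFractionErr[j],
              yD = r$yD[j], ye = r$yDErr[j])
  }
  rows <- lapply(sp, function(s) {
    a <- pick(lo, s); b <- pick(hi, s)
    w <- (1 - t) * a$w + t * b$w
    we <- (1 - t) * a$we + t * b$we
    yD <- if (!is.na(a$yD) && a$w > 0 && !is.na(b$yD) && b$w > 0)
      exp((1 - t) * log(a$yD) + t * log(b$yD))
    else if (!is.na(b$yD) && b$w > 0) b$yD
    else if (!is.na(a$yD)) a$yD
    else b$yD
    ye <- (1 - t) * a$ye + t * b$ye
    data.frame(species = s, doseFraction = w, doseFractionErr = we,
               yD = yD, yDErr = ye)
  })
  rec <- do.call(rbind, rows)
  rec <- rec[rec$doseFraction > 0 | rec$species %in% speciesRecords(lo)$species, , drop = FALSE]
  rz <- (1 - t) * lo@residualZ + t * hi@residualZ
  validateComposition(FieldComposition(En, regs, rec, rz))
}

#' Phantom scoring geometry constructor
#'
#' @param phantomRadius cm
#' @param scoringRadius cm
#' @param scoringOffsets named numeric, cm
#' @return a [PhantomGeometry-class]
#' @export
PhantomGeometry <- function(phantomRadius = 15, scoringRadius = 1.5,
                            scoringOffsets = c(inner = 0, intermediate = 7.5, outer = 13.5)) {
  new("PhantomGeometry", phantomRadius = phantomRadius,
      scoringRadius = scoringRadius, scoringOffsets = scoringOffsets)
}

setMethod("show", "PhantomGeometry", function(object) {
  cat(sprintf(
    "PhantomGeometry: R = %g cm, scoring r = %g cm at offsets %s cm\n",
    object@phantomRadius, object@scoringRadius,
    paste(sprintf("%s=%g", names(object@scoringOffsets), object@scoringOffsets),
          collapse = ", ")))
})

# ---- composition table I/O -------------------------------------------------

.compositionToDF <- function(table) {
  do.call(rbind, lapply(table, function(comp) {
    r <- speciesRecords(comp)
    data.frame(
      E_n_MeV = neutronEnergy(comp), region = region(comp),
      species = r$species,
      dose_fraction = r$doseFraction, dose_fraction_err = r$doseFractionErr,
      yD_keV_um = r$yD, yD_err = r$yDErr)
  }))
}

.compositionFromDF <- function(d) {
  need <- c("E_n_MeV", "region", "species", "dose_fraction",
            "dose_fraction_err", "yD_keV_um", "yD_err")
  if (!all(need %in% names(d)))
    stop("composition table must have columns ", paste(need, collapse = ", "))
  keys <- unique(d[, c("E_n_MeV", "region")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$E_n_MeV == keys$E_n_MeV[i] & d$region == keys$region[i], ]
    FieldComposition(
      keys$E_n_MeV[i], keys$region[i],
      data.frame(species = sub$species,
                 doseFraction = sub$dose_fraction,
                 doseFractionErr = sub$dose_fraction_err,
                 yD = sub$yD_keV_um, yDErr = sub$yD_err))
  })
}

#' Read / write composition tables (CSV and JSON mirrors)
#'
#' CSV columns: `E_n_MeV, region, species, dose_fraction, dose_fraction_err,
#' yD_keV_um, yD_err`, one row per species per energy per region.  The JSON
#' mirror carries identical field names.  Round trips are lossless to full
#' float precision.
#'
#' @param table list of `FieldComposition`
#' @param file path
#' @return readers return a list of `FieldComposition`
#' @export
writeCompositionCSV <- function(table, file) {
  d <- .compositionToDF(table)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = ","), con)
  # %.17g keeps doubles lossless through the text round trip
  writeLines(sprintf("%.17g,%s,%s,%.17g,%.17g,%.17g,%.17g",
                     d$E_n_MeV, d$region, d$species,
                     d$dose_fraction, d$dose_fraction_err,
                     d$yD_keV_um, d$yD_err), con)
  invisible(file)
}

#' @rdname writeCompositionCSV
#' @export
readCompositionCSV <- function(file) {
  .compositionFromDF(utils::read.csv(file, comment.char = "#"))
}

#' @rdname writeCompositionCSV
#' @export
writeCompositionJSON <- function(table, file) {
  jsonlite::write_json(.compositionToDF(table), file, digits = I(17),
                       auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeCompositionCSV
#' @export
readCompositionJSON <- function(file) {
  .compositionFromDF(as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE)))
}
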