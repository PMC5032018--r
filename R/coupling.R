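# Coupling of the condensed mixed-field description to the damage-versus-LET
# models: per species, its dose-mean lineal energy is identified with the LET
# at which its damage curve is read (dose averaging evens out the difference
# between the two estimators), the species yield is weighted by its dose
# fraction, and the weighted yields are summed into a neutron-induced damage
# yield per Gy per cell.

#' Couple a field composition with damage curves at one neutron energy
#'
#' For each species s in the composition: `L_s := yD_s` (exact
#' identification of the dose-mean lineal energy with LET), the species
#' yield is `Y_s = evalDamage(curve_s, L_s)`, and its contribution is
#' `w_s * Y_s`.  Deuterons and electrons are evaluated on the proton curve
#' (deuteron damage versus LET matches the proton one; electrons sit at
#' their almost constant low LET on the proton curve's low-LET end, clamped
#' to the fitted span when below it).  The total yield is the sum of the
#' contributions; its uncertainty propagates the dose-fraction errors as
#' independent, `sigma_Y^2 = sum((Y_s * sigma_ws)^2)`, optionally augmented
#' with the yD errors through the local curve slope.
#'
#' @param comp a validated `FieldComposition`
#' @param curves named list of `DamageCurve` (names: species); curves for
#'   proton, alpha, C, N, O are required for a full composition
#' @param endpoint "short_fragments" or "dsb_clusters"; all curves must
#'   match
#' @param propagateYD if TRUE, also propagate yD uncertainties through a
#'   numerical derivative of the damage curve (off by default; dose-fraction
#'   errors dominate the standard error budget)
#' @return a [NeutronDamagePoint-class]
#' @export
couple <- function(comp, curves, endpoint = c("dsb_clusters", "short_fragments"),
                   propagateYD = FALSE) {
  endpoint <- match.arg(endpoint)
  comp <- validateComposition(comp)
  r <- speciesRecords(comp)
  bad <- vapply(curves, function(cv) cv@endpoint != endpoint, TRUE)
  if (any(bad))
    stop("all damage curves must be fitted for endpoint ", endpoint)

  curveFor <- function(s) {
    key <- if (s %in% c("proton", "deuteron", "electron")) "proton" else s
    if (is.null(curves[[key]]))
      stop(sprintf("no %s damage curve available for species '%s'", endpoint, s))
    curves[[key]]
  }

  rows <- lapply(seq_len(nrow(r)), function(i) {
    s <- r$species[i]
    if (r$doseFraction[i] > 0 && (is.na(r$yD[i]) || r$yD[i] <= 0))
      stop(sprintf("species '%s' has dose fraction > 0 but no valid yD", s))
    cv <- curveFor(s)
    Ys <- evalDamage(cv, r$yD[i])
    dYdL <- if (propagateYD) {
      h <- r$yD[i] * 1e-4
      (evalDamage(cv, r$yD[i] + h) - evalDamage(cv, max(r$yD[i] - h, 1e-12))) / (2 * h)
    } else 0
    data.frame(
      species = s, let = r$yD[i],
      speciesYield = as.numeric(Ys),
      contribution = r$doseFraction[i] * as.numeric(Ys),
      clamped = attr(Ys, "clamped"),
      varW = (as.numeric(Ys) * r$doseFractionErr[i])^2,
      varYD = (r$doseFraction[i] * dYdL * r$yDErr[i])^2)
  })
  ct <- do.call(rbind, rows)
  yield <- sum(ct$contribution)
  err <- sqrt(sum(ct$varW) + sum(ct$varYD))
  new("NeutronDamagePoint",
      neutronEnergy = neutronEnergy(comp), region = region(comp),
      endpoint = endpoint, yield = yield, yieldErr = err,
      contributions = ct[, c("species", "let", "speciesYield",
                             "contribution", "clamped")])
}

setMethod("show", "NeutronDamagePoint", function(object) {
  cat(sprintf(
    "NeutronDamagePoint: E_n = %.4g MeV (%s), %s = %.4g +/- %.3g per Gy per cell\n",
    object@neutronEnergy, object@region, object@endpoint,
    object@yield, object@yieldErr))
})

#' @rdname NeutronDamagePoint-class
#' @param x a `NeutronDamagePoint`
#' @export
damageYield <- function(x) x@yield

#' @rdname NeutronDamagePoint-class
#' @export
damageYieldErr <- function(x) x@yieldErr

#' @rdname NeutronDamagePoint-class
#' @export
speciesContributions <- function(x) x@contributions

#' Interior maxima of a tabulated curve
#'
#' Three-point comparison: node i is an interior maximum when its value
#' strictly exceeds both neighbours.
#'
#' @param x abscissa (increasing)
#' @param y values
#' @return numeric vector of abscissa values of the interior maxima
#' @export
interiorMaxima <- function(x, y) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  x[i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]]
}

#' Neutron-induced damage as a function of neutron energy
#'
#' Couples every composition in a (single-region) table and reports the
#' damage yield per Gy per cell at every tabulated neutron energy, together
#' with the energies of the interior maxima of the resulting curve.
#'
#' @param table list of `FieldComposition`, one region, >= 2 energies
#' @param curves named list of `DamageCurve`
#' @param endpoint damage endpoint
#' @param ... passed to [couple()]
#' @return data.frame with columns `E_n_MeV`, `region`, `endpoint`, `yield`,
#'   `yield_err`, ordered by energy, with attributes `maxima` (energies of
#'   interior maxima) and `points` (the list of `NeutronDamagePoint`)
#' @export
neutronDamageCurve <- function(table, curves,
                               endpoint = c("dsb_clusters", "short_fragments"),
                               ...) {
  endpoint <- match.arg(endpoint)
  if (length(table) < 2L) stop("at least two energies required")
  regs <- unique(vapply(table, region, ""))
  if (length(regs) != 1L) stop("all compositions must share one region")
  o <- order(vapply(table, neutronEnergy, 0))
  table <- table[o]
  pts <- lapply(table, couple, curves = curves, endpoint = endpoint, ...)
  d <- data.frame(
    E_n_MeV = vapply(pts, function(p) p@neutronEnergy, 0),
    region = regs, endpoint = endpoint,
    yield = vapply(pts, damageYield, 0),
    yield_err = vapply(pts, damageYieldErr, 0))
  attr(d, "maxima") <- interiorMaxima(d$E_n_MeV, d$yield)
  attr(d, "points") <- pts
  d
}

#' Write a neutron damage curve (and its per-species companion) as CSV
#'
#' @param curve result of [neutronDamageCurve()]
#' @param file path for the main CSV (`E_n_MeV, region, endpoint, yield,
#'   yield_err`)
#' @param speciesFile optional path for the long-format per-species
#'   companion (`E_n_MeV, species, let, speciesYield, contribution`)
#' @export
writeDamageCurveCSV <- function(curve, file, speciesFile = NULL) {
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  if (!is.null(speciesFile)) {
    pts <- attr(curve, "points")
    long <- do.call(rbind, lapply(pts, function(p) {
      ct <- speciesContributions(p)
      cbind(E_n_MeV = p@neutronEnergy,
            ct[, c("species", "let", "speciesYield", "contribution")])
    }))
    utils::write.csv(long, speciesFile, row.names = FALSE)
  }
  invisible(file)
}
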