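# Analytic damage-versus-LET models, their weighted fitting, and the genomic
# endpoint scorers that define what "damage" means: inter-break fragments
# shorter than 30 bp, and clusters of >= 2 DSBs within less than 25 bp.

#' Construct a damage curve from known parameters
#'
#' @param species species label
#' @param endpoint "short_fragments" or "dsb_clusters"
#' @param form "power_law" (`Y = a L^n`) or "power_law_clustered"
#'   (`Y = A L^N exp(-B L)`)
#' @param params named numeric (`a`, `n`) or (`A`, `N`, `B`)
#' @param letRange numeric length 2, validity span in keV/um
#' @param covariance optional parameter covariance matrix
#' @return a [DamageCurve-class]
#' @export
DamageCurve <- function(species, endpoint, form, params, letRange,
                        covariance = matrix(0, length(params), length(params))) {
  new("DamageCurve", species = species, endpoint = endpoint, form = form,
      params = params, letRange = as.numeric(letRange),
      covariance = covariance)
}

#' @rdname DamageCurve-class
#' @export
setMethod("curveParams", "DamageCurve", function(object) object@params)

#' @rdname DamageCurve-class
#' @export
setMethod("letRange", "DamageCurve", function(object) object@letRange)

setMethod("show", "DamageCurve", function(object) {
  cat(sprintf("DamageCurve: %s / %s, %s over LET [%.3g, %.3g] keV/um\n",
              object@species, object@endpoint, object@form,
              object@letRange[1], object@letRange[2]))
  cat("  params:", paste(sprintf("%s = %.6g", names(object@params), object@params),
                         collapse = ", "), "\n")
})

#' Evaluate a damage curve at given LET values
#'
#' Power law `Y = a L^n`, or clustered form `Y = A L^N exp(-B L)` (which
#' reduces exactly to the power law at B = 0 and peaks at L = N/B).  LET
#' values outside the curve's fitted span are clamped to the nearest
#' endpoint; the returned vector carries a logical `clamped` attribute
#' flagging them.
#'
#' @param curve a `DamageCurve`
#' @param L LET, keV/um (> 0), vectorized
#' @return yield per Gy per cell, with attribute `clamped`
#' @export
evalDamage <- function(curve, L) {
  if (any(!is.finite(L)) || any(L <= 0)) stop("LET must be positive")
  lr <- letRange(curve)
  clamped <- L < lr[1] | L > lr[2]
  Lc <- pmin(pmax(L, lr[1]), lr[2])
  p <- curveParams(curve)
  y <- if (curve@form == "power_law") {
    p[["a"]] * Lc^p[["n"]]
  } else {
    p[["A"]] * Lc^p[["N"]] * exp(-p[["B"]] * Lc)
  }
  attr(y, "clamped") <- clamped
  y
}

#' Fit a damage curve to yield-versus-LET points
#'
#' Weighted least squares in log-yield space, where both forms are linear:
#' `log Y = log a + n log L` and `log Y = log A + N log L - B L`.  Weights
#' are inverse variances of log yield, with `sigma_log ~ Y_err / Y` when
#' point errors are supplied.  The data's LET span becomes the curve's
#' validity range; the parameter covariance is mapped from the log-amplitude
#' scale by the delta method.
#'
#' @param points data.frame with columns `LET_keV_um`,
#'   `yield_per_Gy_per_cell`, and optionally `yield_err`
#' @param form "power_law" (>= 3 points) or "power_law_clustered"
#'   (>= 4 points)
#' @param species,endpoint labels for the fitted curve
#' @return a [DamageCurve-class]
#' @export
fitDamageCurve <- function(points, form = c("power_law", "power_law_clustered"),
                           species = "proton", endpoint = "dsb_clusters") {
  form <- match.arg(form)
  points <- as.data.frame(points)
  if (!all(c("LET_keV_um", "yield_per_Gy_per_cell") %in% names(points)))
    stop("points must have columns LET_keV_um, yield_per_Gy_per_cell")
  L <- points$LET_keV_um
  Y <- points$yield_per_Gy_per_cell
  if (any(L <= 0) || any(Y <= 0)) stop("LET and yields must be positive")
  nmin <- if (form == "power_law") 3L else 4L
  if (length(L) < nmin)
    stop(sprintf("at least %d points required to fit %s", nmin, form))
  w <- if ("yield_err" %in% names(points) && any(points$yield_err > 0)) {
    s <- points$yield_err / Y
    s[s <= 0] <- min(s[s > 0])
    1 / s^2
  } else rep(1, length(L))

  fit <- if (form == "power_law") {
    lm(log(Y) ~ log(L), weights = w)
  } else {
    lm(log(Y) ~ log(L) + L, weights = w)
  }
  b <- coef(fit)
  if (any(!is.finite(b)))
    stop("damage-curve fit failed: singular design (degenerate LET values?)")
  # vcov warns on noiseless (numerically perfect) fits; the zero covariance
  # it returns is exactly right there
  V <- suppressWarnings(vcov(fit))
  if (form == "power_law") {
    params <- c(a = unname(exp(b[1])), n = unname(b[2]))
    J <- diag(c(params[["a"]], 1))
  } else {
    params <- c(A = unname(exp(b[1])), N = unname(b[2]), B = unname(-b[3]))
    J <- diag(c(params[["A"]], 1, -1))
  }
  covar <- J %*% V %*% t(J)
  dimnames(covar) <- list(names(params), names(params))
  DamageCurve(species, endpoint, form, params, range(L), covar)
}

# ---- genomic break patterns ------------------------------------------------

#' Construct a break pattern from chromosome sizes and DSB positions
#'
#' Positions are 0-based base-pair coordinates of break points between base
#' pairs; fragment length between two breaks is the coordinate difference.
#'
#' @param chromSizes data.frame with columns `chrom`, `length`
#' @param positions data.frame with columns `chrom`, `pos` (0-based), or NULL
#'   for an empty pattern
#' @return a [BreakPattern-class]
#' @export
BreakPattern <- function(chromSizes, positions = NULL) {
  chromSizes <- as.data.frame(chromSizes)
  if (!all(c("chrom", "length") %in% names(chromSizes)))
    stop("chromSizes must have columns chrom, length")
  sl <- setNames(as.integer(chromSizes$length), as.character(chromSizes$chrom))
  if (is.null(positions) || nrow(as.data.frame(positions)) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
  } else {
    positions <- as.data.frame(positions)
    if (!all(c("chrom", "pos") %in% names(positions)))
      stop("positions must have columns chrom, pos")
    if (!all(positions$chrom %in% names(sl)))
      stop("position on undeclared chromosome")
    if (any(positions$pos < 0L) ||
        any(positions$pos >= sl[as.character(positions$chrom)]))
      stop("positions must lie within chromosome bounds")
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(positions$chrom),
      ranges = IRanges::IRanges(start = as.integer(positions$pos) + 1L, width = 1L),
      seqinfo = GenomeInfoDb::Seqinfo(names(sl), sl))
    gr <- GenomicRanges::sort(gr)
  }
  new("BreakPattern", breaks = gr)
}

#' @rdname BreakPattern-class
#' @export
setMethod("chromSizes", "BreakPattern", function(object) {
  sl <- GenomeInfoDb::seqlengths(object@breaks)
  data.frame(chrom = names(sl), length = unname(sl))
})

#' @rdname BreakPattern-class
#' @export
setMethod("dsbPositions", "BreakPattern", function(object) {
  gr <- object@breaks
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1L)
})

setMethod("show", "BreakPattern", function(object) {
  cat(sprintf("BreakPattern: %d DSBs on %d chromosomes (%s bp genome)\n",
              length(object@breaks),
              length(GenomeInfoDb::seqlengths(object@breaks)),
              format(sum(as.numeric(GenomeInfoDb::seqlengths(object@breaks))),
                     big.mark = ",")))
})

setMethod("length", "BreakPattern", function(x) length(x@breaks))

#' Score genomic damage endpoints
#'
#' Per chromosome, DSBs are chained: with `linkage = "chain"` (default),
#' consecutive DSBs separated by less than `clusterDistance` bp (strict)
#' belong to one cluster, and clusters are maximal chains with >= 2 members.
#' With `linkage = "pairwise"` a cluster is a maximal run whose total span is
#' below `clusterDistance`, i.e. every pair in the cluster satisfies the
#' distance criterion.  Short fragments are inter-DSB intervals shorter than
#' `fragmentLength` bp (strict), counted genome-wide.
#'
#' @param pattern a `BreakPattern`
#' @param clusterDistance bp, default 25 (strict inequality)
#' @param fragmentLength bp, default 30 (strict inequality)
#' @param linkage "chain" (transitive linkage) or "pairwise" (span bound)
#' @return a [DamageScore-class]
#' @export
setMethod("scoreBreaks", "BreakPattern",
  function(pattern, clusterDistance = 25L, fragmentLength = 30L,
           linkage = c("chain", "pairwise")) {
    linkage <- match.arg(linkage)
    df <- dsbPositions(pattern)
    nFrag <- 0L
    mult <- integer(0)
    nIso <- 0L
    for (ch in unique(df$chrom)) {
      pos <- sort(df$pos[df$chrom == ch])
      n <- length(pos)
      if (n == 0L) next
      if (n == 1L) { nIso <- nIso + 1L; next }
      gaps <- diff(pos)
      nFrag <- nFrag + sum(gaps < fragmentLength)
      if (linkage == "chain") {
        linked <- gaps < clusterDistance
        r <- rle(linked)
        sizes <- integer(0)
        iso <- 0L
        # runs of TRUE of length k link k+1 breaks into one cluster
        k <- r$lengths[r$values]
        sizes <- k + 1L
        # breaks not adjacent to any link are isolated
        inCluster <- sum(sizes)
        iso <- n - inCluster
        mult <- c(mult, sizes)
        nIso <- nIso + iso
      } else {
        i <- 1L
        while (i <= n) {
          j <- i
          while (j < n && pos[j + 1L] - pos[i] < clusterDistance) j <- j + 1L
          if (j > i) mult <- c(mult, j - i + 1L) else nIso <- nIso + 1L
          i <- j + 1L
        }
      }
    }
    new("DamageScore",
        nShortFragments = as.integer(nFrag),
        nClusters = length(mult),
        multiplicities = as.integer(mult),
        nIsolated = as.integer(nIso))
  })

setMethod("show", "DamageScore", function(object) {
  cat(sprintf(
    "DamageScore: %d short fragments, %d clusters (multiplicities %s), %d isolated DSBs\n",
    object@nShortFragments, object@nClusters,
    if (object@nClusters) paste(object@multiplicities, collapse = ",") else "-",
    object@nIsolated))
})

#' @rdname DamageScore-class
#' @param x a `DamageScore`
#' @export
nShortFragments <- function(x) x@nShortFragments

#' @rdname DamageScore-class
#' @export
nClusters <- function(x) x@nClusters

#' @rdname DamageScore-class
#' @export
clusterMultiplicities <- function(x) x@multiplicities

#' @rdname DamageScore-class
#' @export
nIsolatedDSB <- function(x) x@nIsolated

# ---- break pattern and damage point I/O ------------------------------------

#' Read / write break patterns as BED3 plus a chrom.sizes file
#'
#' Breaks are exported as unit intervals (`start`, `start + 1`) in 0-based
#' BED convention; the companion two-column chrom.sizes file carries the
#' chromosome lengths.
#'
#' @param pattern a `BreakPattern`
#' @param bedFile path to the BED3 file
#' @param chromSizesFile path to the two-column chrom.sizes file
#' @return readers return a `BreakPattern`
#' @export
writeBreakPatternBED <- function(pattern, bedFile, chromSizesFile) {
  rtracklayer::export(pattern@breaks, bedFile, format = "BED")
  cs <- chromSizes(pattern)
  utils::write.table(cs, chromSizesFile, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bedFile)
}

#' @rdname writeBreakPatternBED
#' @export
readBreakPatternBED <- function(bedFile, chromSizesFile) {
  cs <- utils::read.table(chromSizesFile, sep = "\t",
                          col.names = c("chrom", "length"))
  gr <- rtracklayer::import(bedFile, format = "BED")
  BreakPattern(cs, data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                              pos = GenomicRanges::start(gr) - 1L))
}

#' Read / write damage point sets as CSV
#'
#' Columns `LET_keV_um, yield_per_Gy_per_cell, yield_err`.
#'
#' @param points data.frame of damage points
#' @param file path
#' @return the reader returns a data.frame
#' @export
writeDamagePointsCSV <- function(points, file) {
  utils::write.csv(points[, c("LET_keV_um", "yield_per_Gy_per_cell", "yield_err")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeDamagePointsCSV
#' @export
readDamagePointsCSV <- function(file) {
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("LET_keV_um", "yield_per_Gy_per_cell") %in% names(d)))
    stop("damage CSV must have columns LET_keV_um, yield_per_Gy_per_cell")
  d
}
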