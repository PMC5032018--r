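# Synthetic damage-versus-LET datasets with known ground truth, default
# damage curves for the coupling pipeline, and a seeded genomic break
# pattern generator with a tunable clustered component.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Ground-truth damage model parameters used by the default synthetic
# pipeline.  Chosen once to reproduce the qualitative structure of
# track-structure results: light-ion yields follow pure power laws; for the
# cluster endpoint, heavy-ion curves carry the clustering factor and turn
# over at LET values inside their fitted span (overkill of spatially
# saturated damage), which is what tames the high-LET contribution relative
# to the fragment endpoint.  Fragment yields rise as pure power laws for
# every species.  Magnitudes are per Gy per cell.
.DEFAULT_TRUE_PARAMS <- list(
  dsb_clusters = list(
    proton = list(form = "power_law", params = c(a = 0.05, n = 1.30),
                  letRange = c(1.5, 85)),
    alpha = list(form = "power_law", params = c(a = 0.035, n = 1.25),
                 letRange = c(5, 260)),
    C = list(form = "power_law_clustered",
             params = c(A = 0.0107, N = 1.45, B = 0.00223),
             letRange = c(20, 1000)),
    N = list(form = "power_law_clustered",
             params = c(A = 0.0127, N = 1.45, B = 0.00264),
             letRange = c(20, 900)),
    O = list(form = "power_law_clustered",
             params = c(A = 0.0116, N = 1.45, B = 0.00242),
             letRange = c(20, 950))
  ),
  short_fragments = list(
    proton = list(form = "power_law", params = c(a = 0.08, n = 1.40),
                  letRange = c(1.5, 85)),
    alpha = list(form = "power_law", params = c(a = 0.06, n = 1.35),
                 letRange = c(5, 260)),
    C = list(form = "power_law", params = c(a = 0.009, n = 1.60),
             letRange = c(20, 1000)),
    N = list(form = "power_law", params = c(a = 0.011, n = 1.60),
             letRange = c(20, 900)),
    O = list(form = "power_law", params = c(a = 0.010, n = 1.60),
             letRange = c(20, 950))
  )
)

#' Ground-truth damage curves of the synthetic pipeline
#'
#' @param endpoint "dsb_clusters" or "short_fragments"
#' @return named list of [DamageCurve-class] built directly from the true
#'   parameters (no fitting)
#' @export
trueDamageCurves <- function(endpoint = c("dsb_clusters", "short_fragments")) {
  endpoint <- match.arg(endpoint)
  pars <- .DEFAULT_TRUE_PARAMS[[endpoint]]
  out <- lapply(names(pars), function(s) {
    p <- pars[[s]]
    DamageCurve(species = s, endpoint = endpoint, form = p$form,
                params = p$params, letRange = p$letRange)
  })
  names(out) <- names(pars)
  out
}

#' Generate a synthetic damage-versus-LET dataset
#'
#' Yields are drawn log-normally around the true curve with coefficient of
#' variation `noiseCv` (mean-preserving), and the truth is returned
#' alongside the data so parameter-recovery tests can close the loop.
#'
#' @param species species label with default parameters, or supply `curve`
#' @param endpoint damage endpoint
#' @param letPoints LET values, keV/um (> 0); default 12 log-spaced points
#'   across the species' default LET span
#' @param noiseCv multiplicative noise coefficient of variation (0 = exact)
#' @param seed integer seed
#' @param curve optional `DamageCurve` overriding the default truth
#' @return list with `points` (data.frame `LET_keV_um,
#'   yield_per_Gy_per_cell, yield_err`) and `truth` (the generating
#'   `DamageCurve`)
#' @export
generateDamageDataset <- function(species = "proton",
                                  endpoint = c("dsb_clusters", "short_fragments"),
                                  letPoints = NULL, noiseCv = 0.1,
                                  seed = 34033L, curve = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(curve)) {
    p <- .DEFAULT_TRUE_PARAMS[[endpoint]][[species]]
    if (is.null(p)) stop("no default parameters for species ", species)
    curve <- DamageCurve(species, endpoint, p$form, p$params, p$letRange)
  }
  if (is.null(letPoints)) {
    lr <- letRange(curve)
    letPoints <- exp(seq(log(lr[1]), log(lr[2]), length.out = 12))
  }
  if (any(letPoints <= 0)) stop("LET points must be positive")
  Yt <- as.numeric(evalDamage(curve, letPoints))
  Y <- if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    .withSeed(seed, Yt * exp(stats::rnorm(length(Yt), -sdlog^2 / 2, sdlog)))
  } else Yt
  list(points = data.frame(LET_keV_um = letPoints,
                           yield_per_Gy_per_cell = Y,
                           yield_err = noiseCv * Y),
       truth = curve)
}

#' Default fitted damage curves for the coupling pipeline
#'
#' Noiseless synthetic datasets are generated from the ground-truth
#' parameters for every species and refitted, exercising the same fitting
#' path a user of external damage data would go through; on noiseless data
#' the fit recovers the truth to numerical precision.
#'
#' @param endpoint damage endpoint
#' @return named list of fitted [DamageCurve-class]
#' @export
defaultDamageCurves <- function(endpoint = c("dsb_clusters", "short_fragments")) {
  endpoint <- match.arg(endpoint)
  sp <- names(.DEFAULT_TRUE_PARAMS[[endpoint]])
  out <- lapply(sp, function(s) {
    ds <- generateDamageDataset(s, endpoint, noiseCv = 0)
    fitDamageCurve(ds$points, form = ds$truth@form, species = s,
                   endpoint = endpoint)
  })
  names(out) <- sp
  out
}

#' Generate a synthetic genomic break pattern
#'
#' Emulates DSB induction by `nTracks` particle tracks: each track deposits
#' a Poisson number of DSBs; a fraction `clusterFraction` of tracks are
#' "densely ionizing" and deposit their DSBs (at least two) in a burst
#' within `clusterSpanBp` on one chromosome, the remainder place their DSBs
#' uniformly over the genome.  Chromosomes are chosen with probability
#' proportional to length.  Deterministic given the seed; the number and
#' sizes of generated bursts are returned as truth.
#'
#' @param chromSizes data.frame `chrom, length`
#' @param nTracks number of tracks (>= 0)
#' @param dsbPerTrackMean mean DSBs per track (> 0)
#' @param clusterFraction fraction of clustered tracks, in `[0, 1]`
#' @param clusterSpanBp genomic span of a burst, bp (< every chromosome
#'   length)
#' @param seed integer seed
#' @return list with `pattern` (a [BreakPattern-class]) and `truth`
#'   (list: `nBursts`, `burstSizes`)
#' @export
generateBreakPattern <- function(chromSizes, nTracks, dsbPerTrackMean = 2,
                                 clusterFraction = 0, clusterSpanBp = 10L,
                                 seed = 34033L) {
  chromSizes <- as.data.frame(chromSizes)
  if (nTracks < 0 || dsbPerTrackMean < 0 || clusterFraction < 0 ||
      clusterFraction > 1 || clusterSpanBp < 1)
    stop("generator parameters must be non-negative (clusterFraction in [0,1])")
  if (any(clusterSpanBp >= chromSizes$length))
    stop("cluster span must be smaller than every chromosome")
  lens <- as.numeric(chromSizes$length)
  probs <- lens / sum(lens)
  .withSeed(seed, {
    chromIdx <- integer(0); pos <- integer(0)
    burstSizes <- integer(0)
    if (nTracks > 0) {
      clustered <- runif(nTracks) < clusterFraction
      for (tr in seq_len(nTracks)) {
        if (clustered[tr]) {
          k <- max(2L, rpois(1L, dsbPerTrackMean))
          ci <- sample.int(nrow(chromSizes), 1L, prob = probs)
          anchor <- floor(runif(1L, 0, lens[ci] - clusterSpanBp))
          offs <- sort(sample.int(clusterSpanBp, k, replace = TRUE) - 1L)
          chromIdx <- c(chromIdx, rep(ci, k))
          pos <- c(pos, anchor + offs)
          burstSizes <- c(burstSizes, k)
        } else {
          k <- rpois(1L, dsbPerTrackMean)
          if (k > 0L) {
            ci <- sample.int(nrow(chromSizes), k, replace = TRUE, prob = probs)
            chromIdx <- c(chromIdx, ci)
            pos <- c(pos, floor(runif(k, 0, lens[ci])))
          }
        }
      }
    }
    pat <- BreakPattern(chromSizes,
                        if (length(pos))
                          data.frame(chrom = chromSizes$chrom[chromIdx], pos = pos)
                        else NULL)
    list(pattern = pat,
         truth = list(nBursts = length(burstSizes), burstSizes = burstSizes))
  })
}
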