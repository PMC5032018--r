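# Independent oracles used across the suite.

# Fine-grid trapezoidal quadrature of a function over [lo, hi] (log-spaced),
# independent of the package's spectrum arithmetic.
quadOracle <- function(f, lo, hi, n = 20000) {
  x <- exp(seq(log(lo), log(hi), length.out = n))
  y <- f(x)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Brute-force O(n^2) cluster scorer: pairwise adjacency at < dist bp,
# connected components by label propagation, clusters are components with
# >= 2 members.  Short fragments: all pairs of breaks with no other break
# between them and separation < fragLen.
bruteScore <- function(df, dist = 25L, fragLen = 30L) {
  nFrag <- 0L; mult <- integer(0); nIso <- 0L
  for (ch in unique(df$chrom)) {
    pos <- sort(df$pos[df$chrom == ch])
    n <- length(pos)
    if (n == 0L) next
    if (n >= 2L) {
      for (i in 1:(n - 1L)) {
        # adjacent pair (no break strictly between by construction of sort)
        if (pos[i + 1L] - pos[i] < fragLen) nFrag <- nFrag + 1L
      }
    }
    comp <- seq_len(n)
    if (n >= 2L) {
      repeat {
        changed <- FALSE
        for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
          if (abs(pos[j] - pos[i]) < dist && comp[j] != comp[i]) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
    sizes <- table(comp)
    mult <- c(mult, as.integer(sizes[sizes >= 2L]))
    nIso <- nIso + sum(sizes == 1L)
  }
  list(nFrag = nFrag, mult = sort(mult), nClusters = length(mult), nIso = nIso)
}

# Tiny two-chromosome genome reused by break-pattern tests.
toyGenome <- function(lenA = 5000L, lenB = 3000L) {
  data.frame(chrom = c("chrA", "chrB"), length = c(lenA, lenB))
}

# Deterministic small composition used by coupling unit tests.
toyComposition <- function(E = 1, region = "outer",
                           species = c("proton", "alpha"),
                           w = c(0.7, 0.3), yD = c(40, 150),
                           wErr = rep(0, length(w))) {
  FieldComposition(E, region,
    data.frame(species = species, doseFraction = w, doseFractionErr = wErr,
               yD = yD, yDErr = rep(0, length(w))))
}

# Constant-yield damage curve: power law with n = 0.
constantCurve <- function(value, species = "proton",
                          endpoint = "dsb_clusters",
                          letRange = c(0.1, 2000)) {
  DamageCurve(species, endpoint, "power_law", c(a = value, n = 0), letRange)
}
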