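# Fixtures and independent oracles used across the suite.

# A homologous pair realizing the canonical worked-example topology: the two
# homologues are IBD on [0, 0.8) with the shared origin changing at 0.5
# (a shared internal junction inside the IBD tract), and non-IBD on [0.8, 1]
# (one external junction at 0.8 carried by homologue 1).
figPair <- function() {
  individual(mosaic(c(0, 0.5, 1), c(1L, 2L)),
             mosaic(c(0, 0.5, 0.8, 1), c(1L, 2L, 3L)))
}

# Random normalized mosaic on [0, l] with ~nSeg segments drawn from a small
# label pool (so random pairs share ancestry often enough to be interesting).
randomMosaic <- function(l = 1, nSeg = 5, labels = 1:4) {
  m <- max(1L, stats::rpois(1, nSeg))
  bp <- c(0, sort(stats::runif(m - 1, 0, l)), l)
  org <- integer(m)
  org[1] <- sample(labels, 1)
  if (m > 1) for (j in 2:m) org[j] <- sample(setdiff(labels, org[j - 1]), 1)
  mosaic(bp, org)
}

# Grid-based IBD caller: compare origin labels at grid points and merge runs.
# Completely independent of the interval-merge implementation; boundaries are
# recovered to within one grid step.
gridRelaxed <- function(ind, step = 1e-4) {
  l <- chromLength(ind)
  x <- seq(step / 2, l - step / 2, by = step)
  o0 <- segAt(ind@maternal, x)
  o1 <- segAt(ind@paternal, x)
  ibd <- o0 == o1
  r <- rle(ibd)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  keep <- r$values
  data.frame(start = (lo[keep] - 1L) * step, end = hi[keep] * step)
}

segAt <- function(m, x) m@origins[findInterval(x, m@breakpoints,
                                               rightmost.closed = TRUE)]

# Label-only single-locus simulation of the same mating scheme (ordered pair
# of distinct parents, uniform with replacement across offspring; each parent
# transmits one of its two alleles by a fair coin). No recombination is
# needed at a single locus, so this is an independent oracle for the
# per-locus non-IBD probability of the full simulator.
# Returns an R x (T+1) matrix of per-replicate non-IBD frequencies.
singleLocusOracle <- function(N, nGen, R) {
  A <- matrix(rep(seq_len(N) * 2L - 1L, each = R), R, N)
  B <- matrix(rep(seq_len(N) * 2L, each = R), R, N)
  out <- matrix(NA_real_, R, nGen + 1)
  out[, 1] <- rowMeans(A != B)
  rows <- seq_len(R)
  for (t in seq_len(nGen)) {
    A2 <- A; B2 <- B
    for (o in seq_len(N)) {
      p1 <- sample.int(N, R, replace = TRUE)
      p2 <- sample.int(N - 1L, R, replace = TRUE)
      p2 <- p2 + (p2 >= p1)
      pickA1 <- stats::runif(R) < 0.5
      A2[, o] <- ifelse(pickA1, A[cbind(rows, p1)], B[cbind(rows, p1)])
      pickA2 <- stats::runif(R) < 0.5
      B2[, o] <- ifelse(pickA2, A[cbind(rows, p2)], B[cbind(rows, p2)])
    }
    A <- A2; B <- B2
    out[, t + 1] <- rowMeans(A != B)
  }
  out
}

# Build a ReplicateSet by hand from per-replicate, per-individual block
# length lists, to test the estimators against hand arithmetic.
# blockLists: list over replicates; each element a list over individuals of
# numeric block-length vectors (possibly empty).
handDataset <- function(blockLists, l = 1, generationIdx = 1L) {
  N <- max(vapply(blockLists, length, integer(1)))
  R <- length(blockLists)
  gs <- do.call(rbind, lapply(seq_len(R), function(r) {
    lens <- blockLists[[r]]
    d <- vapply(lens, sum, numeric(1))
    k <- vapply(lens, length, integer(1))
    data.frame(replicate = r, generation = generationIdx,
               sumD = sum(d), sumK = sum(k),
               sumZ = NA_integer_, sumTips = NA_integer_,
               nIndWithBlocks = sum(k > 0),
               sumIndMean = sum(ifelse(k > 0, d / pmax(k, 1L), 0)))
  }))
  blocks <- do.call(rbind, lapply(seq_len(R), function(r) {
    lens <- blockLists[[r]]
    do.call(rbind, lapply(seq_along(lens), function(i) {
      if (length(lens[[i]]) == 0) return(NULL)
      data.frame(replicate = r, generation = generationIdx,
                 individual = i, start = 0, end = lens[[i]],
                 length = lens[[i]])
    }))
  }))
  if (is.null(blocks))
    blocks <- data.frame(replicate = integer(0), generation = integer(0),
                         individual = integer(0), start = numeric(0),
                         end = numeric(0), length = numeric(0))
  p <- simParams(popSize = max(N, 2L), chromLength = l,
                 nGenerations = generationIdx, nReplicates = R, seed = 1L,
                 recordGenerations = generationIdx)
  new("ReplicateSet", params = p, generationStats = gs,
      individuals = data.frame(), blocks = blocks,
      childSeeds = seq_len(R))
}
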