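#' @include AllClasses.R
NULL

.statsAt <- function(x, t) {
  gs <- x@generationStats
  gs[gs$generation == t, , drop = FALSE]
}

.checkGen <- function(x, t) {
  if (!t %in% x@generationStats$generation)
    stop(sprintf("generation %d was not simulated", t))
}

#' Across-replicate mean IBD block length
#'
#' The mean length of a block drawn uniformly from the pooled dataset: the
#' sum of all relaxed block lengths over all replicates and individuals,
#' divided by the total number of blocks. Identical, by construction, to the
#' ratio of pooled means `mean(d) / mean(k)`, which is why it converges to
#' the theoretical E(L) = E(D)/E(K) as the number of replicates grows.
#'
#' @param x a [ReplicateSet].
#' @param t generation to evaluate.
#' @param from `"stats"` (per-replicate aggregates; always available) or
#'   `"blocks"` (recompute from the pooled block records; needs `t` among the
#'   recorded generations with block recording on).
#' @return a single numeric value; `NA` (with a warning) when the pooled
#'   dataset contains no block at `t`.
#' @examples
#' rs <- runReplicates(simParams(popSize = 10, nGenerations = 10,
#'                               nReplicates = 50, seed = 1,
#'                               recordGenerations = 10))
#' lengthAR(rs, 10)
#' @export
lengthAR <- function(x, t, from = c("stats", "blocks")) {
  from <- match.arg(from)
  .checkGen(x, t)
  if (from == "blocks") {
    bl <- x@blocks[x@blocks$generation == t, , drop = FALSE]
    if (nrow(bl) == 0L) {
      warning("no block recorded at generation ", t)
      return(NA_real_)
    }
    return(sum(bl$length) / nrow(bl))
  }
  gs <- .statsAt(x, t)
  if (sum(gs$sumK) == 0L) {
    warning("no IBD block in the pooled dataset at generation ", t)
    return(NA_real_)
  }
  sum(gs$sumD) / sum(gs$sumK)
}

#' Population-wise mean IBD block length
#'
#' The mean over replicates of the within-replicate mean block length: the
#' length of a block drawn from a randomly drawn population. Because
#' populations carrying many blocks are not over-represented (as they are in
#' [lengthAR()]), this measure is size-biased relative to the pooled one and
#' is bounded below by it asymptotically.
#'
#' @inheritParams lengthAR
#' @param zeroBlockPolicy `"exclude"` (default): replicates without any block
#'   contribute no term (their within-replicate mean is 0/0); `"zero"`: they
#'   contribute a 0 term. The exclusion count is always reported.
#' @param details if `TRUE`, return a list with the per-replicate values, the
#'   between-replicate standard error and the exclusion count.
#' @return numeric value, or a list when `details = TRUE`.
#' @export
lengthPW <- function(x, t, zeroBlockPolicy = c("exclude", "zero"),
                     details = FALSE) {
  zeroBlockPolicy <- match.arg(zeroBlockPolicy)
  .checkGen(x, t)
  gs <- .statsAt(x, t)
  has <- gs$sumK > 0L
  perRep <- ifelse(has, gs$sumD / ifelse(has, gs$sumK, 1L), NA_real_)
  used <- if (zeroBlockPolicy == "exclude") perRep[has] else
    ifelse(has, perRep, 0)
  nExcluded <- sum(!has)
  if (length(used) == 0L || all(is.na(used))) {
    warning("every replicate is blockless at generation ", t)
    val <- NA_real_; se <- NA_real_
  } else {
    val <- mean(used)
    se <- stats::sd(used) / sqrt(length(used))
  }
  if (!details) return(val)
  list(value = val, perReplicate = perRep, se = se,
       nExcluded = if (zeroBlockPolicy == "exclude") nExcluded else 0L)
}

#' Individual-wise mean IBD block length
#'
#' The mean over all individuals in all replicates of the per-individual
#' mean block length: the length of a block drawn from a randomly drawn
#' individual. The strongest size-biasing of the three measures.
#'
#' @inheritParams lengthPW
#' @param zeroBlockPolicy `"exclude"` (default): individuals without blocks
#'   contribute no term; `"zero"`: they contribute a 0 term.
#' @return numeric value, or a list when `details = TRUE` (the standard
#'   error is the between-replicate one, computed on per-replicate means).
#' @export
lengthIW <- function(x, t, zeroBlockPolicy = c("exclude", "zero"),
                     details = FALSE) {
  zeroBlockPolicy <- match.arg(zeroBlockPolicy)
  .checkGen(x, t)
  gs <- .statsAt(x, t)
  nInd <- x@params@popSize * nrow(gs)
  nWith <- sum(gs$nIndWithBlocks)
  if (nWith == 0L) {
    warning("every individual is blockless at generation ", t)
    val <- NA_real_; se <- NA_real_; perRep <- rep(NA_real_, nrow(gs))
  } else if (zeroBlockPolicy == "exclude") {
    val <- sum(gs$sumIndMean) / nWith
    perRep <- ifelse(gs$nIndWithBlocks > 0L,
                     gs$sumIndMean / ifelse(gs$nIndWithBlocks > 0L,
                                            gs$nIndWithBlocks, 1L), NA_real_)
    pr <- perRep[!is.na(perRep)]
    se <- stats::sd(pr) / sqrt(length(pr))
  } else {
    val <- sum(gs$sumIndMean) / nInd
    perRep <- gs$sumIndMean / x@params@popSize
    se <- stats::sd(perRep) / sqrt(length(perRep))
  }
  if (!details) return(val)
  list(value = val, perReplicate = perRep, se = se,
       nExcluded = if (zeroBlockPolicy == "exclude") nInd - nWith else 0L)
}

#' Empirical moments of the IBD process at one generation
#'
#' Plug-in estimates of the quantities entering the theoretical block-length
#' formulas: `EH` (expected non-IBD proportion of a randomly drawn
#' individual), `EZ` (expected external junctions per Morgan per individual),
#' `ED` (expected total IBD length) and `EK` (expected block count), all
#' pooled over replicates and individuals.
#'
#' @inheritParams lengthAR
#' @return list with elements `EH`, `EZ`, `ED`, `EK` and `l`.
#' @export
empiricalMoments <- function(x, t) {
  .checkGen(x, t)
  gs <- .statsAt(x, t)
  l <- x@params@chromLength
  nInd <- x@params@popSize * nrow(gs)
  ED <- sum(gs$sumD) / nInd
  list(EH = 1 - ED / l,
       EZ = sum(gs$sumZ) / nInd / l,
       ED = ED,
       EK = sum(gs$sumK) / nInd,
       l = l)
}

#' Expected block length as a ratio of moments
#'
#' The central identity of the renewal argument: the expected length of an
#' IBD block drawn uniformly from all blocks of all populations equals
#' E(D)/E(K) — the expected total IBD length of a randomly drawn individual
#' over its expected block count. It holds at any generation, for any
#' population model with equal sizes at that generation; demography and
#' selection enter only through E(D) and E(K).
#'
#' @param ED expected total IBD length per individual, Morgan.
#' @param EK expected IBD block count per individual (> 0).
#' @return ED / EK; `NA` with a warning when `EK = 0` (no blocks expected).
#' @examples
#' expectedLRatio(0.5, 2)   # 0.25
#' @export
expectedLRatio <- function(ED, EK) {
  if (EK < 0 || ED < 0) stop("ED and EK must be non-negative")
  if (EK == 0) {
    warning("EK = 0: no blocks expected, E(L) undefined")
    return(NA_real_)
  }
  ED / EK
}

#' Expected total IBD length on a finite chromosome
#'
#' E(D) = l (1 - E(H)): the IBD fraction of the chromosome times its length.
#'
#' @param EH expected non-IBD proportion, in `[0, 1]`.
#' @param l chromosome length in Morgan.
#' @return expected total IBD length, Morgan.
#' @export
expectedD <- function(EH, l) {
  .checkTheory(EH, 0, l)
  l * (1 - EH)
}

#' Expected IBD block count on a finite chromosome
#'
#' E(K) = 0.5 l E(Z) + (1 - E(H)): half the expected number of block edges.
#' Each block has two edges; an edge is either an external junction (l E(Z)
#' of them on average over l Morgan) or a chromosome tip lying in an IBD
#' tract (each of the two tips is IBD with probability 1 - E(H)).
#'
#' @param EH expected non-IBD proportion, in `[0, 1]`.
#' @param EZ expected external junctions per Morgan per individual (>= 0).
#' @param l chromosome length in Morgan.
#' @return expected block count.
#' @export
expectedK <- function(EH, EZ, l) {
  .checkTheory(EH, EZ, l)
  0.5 * l * EZ + (1 - EH)
}

#' Expected block length on a finite chromosome
#'
#' E(L) = l (1 - E(H)) / (0.5 l E(Z) + (1 - E(H))): the ratio of
#' [expectedD()] to [expectedK()]. This is the finite-length prediction that
#' the across-replicate measure [lengthAR()] converges to; it differs from
#' the stationary (infinite-chromosome) formula by the tip term (1 - E(H))
#' in the denominator, which shortens the mean.
#'
#' @inheritParams expectedK
#' @return expected block length, Morgan; `NA` with a warning when the
#'   denominator is 0.
#' @examples
#' expectedLFinite(EH = 0.5, EZ = 1, l = 1)   # 0.5
#' @export
expectedLFinite <- function(EH, EZ, l) {
  .checkTheory(EH, EZ, l)
  den <- 0.5 * l * EZ + (1 - EH)
  if (den == 0) {
    warning("denominator 0: no blocks expected, E(L) undefined")
    return(NA_real_)
  }
  l * (1 - EH) / den
}

#' Stationary (infinite-chromosome) expected block length
#'
#' L* = (1 - E(H)) / (0.5 E(Z)): the classical renewal-theory result,
#' derived under stationarity of the IBD process along the map — which
#' amounts to assuming an infinitely long chromosome. For the same inputs it
#' is strictly larger than [expectedLFinite()] whenever `EH < 1` and
#' `EZ > 0` (no tip correction).
#'
#' @param EH expected non-IBD proportion, in `[0, 1]`.
#' @param EZ expected external junctions per Morgan per individual (> 0).
#' @return expected block length, Morgan; `NA` with a warning when `EZ = 0`.
#' @export
expectedLStam <- function(EH, EZ) {
  .checkTheory(EH, EZ, 1)
  if (EZ == 0) {
    warning("EZ = 0: the stationary formula needs junctions")
    return(NA_real_)
  }
  (1 - EH) / (0.5 * EZ)
}

.checkTheory <- function(EH, EZ, l) {
  if (is.na(EH) || EH < 0 || EH > 1) stop("EH must lie in [0, 1]")
  if (is.na(EZ) || EZ < 0) stop("EZ must be >= 0")
  if (is.na(l) || l <= 0) stop("l must be > 0 Morgan")
  invisible(TRUE)
}

#' Bootstrap standard error of the across-replicate measure
#'
#' Nonparametric bootstrap over replicates of the pooled ratio
#' `sum(d) / sum(k)`.
#'
#' @inheritParams lengthAR
#' @param B number of bootstrap resamples.
#' @return numeric standard error.
#' @export
bootstrapSE_AR <- function(x, t, B = 1000L) {
  .checkGen(x, t)
  gs <- .statsAt(x, t)
  R <- nrow(gs)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(R, R, replace = TRUE)
    kk <- sum(gs$sumK[idx])
    if (kk == 0L) NA_real_ else sum(gs$sumD[idx]) / kk
  }, numeric(1))
  stats::sd(vals, na.rm = TRUE)
}

#' Per-generation estimate report
#'
#' Evaluates the three mean block-length measures, the empirical moments and
#' the finite-chromosome prediction at each requested generation, with
#' between-replicate standard errors for the population- and individual-wise
#' measures. Suitable for plotting the measures against the prediction over
#' time.
#'
#' @param x a [ReplicateSet].
#' @param generations generations to evaluate; defaults to all simulated.
#' @param zeroBlockPolicy handling of blockless units, see [lengthPW()].
#' @param bootstrapB if > 0, also compute the bootstrap SE of the
#'   across-replicate measure with this many resamples per generation.
#' @return data.frame with one row per generation: `generation`, `L_AR`,
#'   `L_PW`, `L_IW`, `EH_hat`, `EZ_hat`, `ED_hat`, `EK_hat`, `EL_pred`,
#'   `se_PW`, `se_IW`, `se_AR` (NA unless requested),
#'   `nExcludedReplicates`, `nExcludedIndividuals`.
#' @export
estimateReport <- function(x, generations = NULL,
                           zeroBlockPolicy = c("exclude", "zero"),
                           bootstrapB = 0L) {
  zeroBlockPolicy <- match.arg(zeroBlockPolicy)
  if (is.null(generations))
    generations <- sort(unique(x@generationStats$generation))
  rows <- lapply(generations, function(t) {
    mom <- empiricalMoments(x, t)
    pw <- suppressWarnings(lengthPW(x, t, zeroBlockPolicy, details = TRUE))
    iw <- suppressWarnings(lengthIW(x, t, zeroBlockPolicy, details = TRUE))
    ar <- suppressWarnings(lengthAR(x, t))
    pred <- if (mom$EK > 0) expectedLFinite(mom$EH, mom$EZ, mom$l) else NA_real_
    seAR <- if (bootstrapB > 0L && !is.na(ar))
      bootstrapSE_AR(x, t, bootstrapB) else NA_real_
    data.frame(generation = t, L_AR = ar, L_PW = pw$value, L_IW = iw$value,
               EH_hat = mom$EH, EZ_hat = mom$EZ, ED_hat = mom$ED,
               EK_hat = mom$EK, EL_pred = pred,
               se_PW = pw$se, se_IW = iw$se, se_AR = seAR,
               nExcludedReplicates = pw$nExcluded,
               nExcludedIndividuals = iw$nExcluded)
  })
  do.call(rbind, rows)
}
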