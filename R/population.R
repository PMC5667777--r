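#' @include AllClasses.R
NULL

#' Simulation parameters
#'
#' Configuration for the forward simulation of a constant-size, panmictic,
#' monoecious diploid population without selfing, undergoing drift only.
#' Founders are unrelated and non-inbred. Defaults follow the reference
#' drift experiment: N = 20 individuals on a 1 Morgan chromosome.
#'
#' @param popSize N, number of diploid individuals (>= 2).
#' @param chromLength l, chromosome length in Morgan (> 0).
#' @param nGenerations T, generations to simulate after founding.
#' @param nReplicates R, independent population trajectories.
#' @param seed integer root seed; each replicate runs on its own child seed
#'   drawn reproducibly from the root seed.
#' @param recordGenerations generations (subset of 0..T) at which
#'   per-individual summaries and block records are kept; defaults to the
#'   final generation.
#' @param recordBlocks keep per-block records at recorded generations.
#' @param pairing `"within-individual"` (default; homozygosity by descent) or
#'   `"random-pair"` (chromosomes re-paired at random each generation).
#' @return a [SimParams].
#' @examples
#' simParams(popSize = 20, nGenerations = 10, nReplicates = 100, seed = 1)
#' @export
simParams <- function(popSize = 20L, chromLength = 1.0, nGenerations = 100L,
                      nReplicates = 100L, seed = 1L,
                      recordGenerations = nGenerations,
                      recordBlocks = TRUE,
                      pairing = c("within-individual", "random-pair")) {
  new("SimParams", popSize = as.integer(popSize),
      chromLength = as.numeric(chromLength),
      nGenerations = as.integer(nGenerations),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed),
      recordGenerations = as.integer(sort(unique(recordGenerations))),
      recordBlocks = isTRUE(recordBlocks), pairing = match.arg(pairing))
}

#' Found a population of unrelated, non-inbred individuals
#'
#' Every founder chromosome copy receives its own origin label (2N distinct
#' labels), so no founder carries any IBD and no two founders share ancestry.
#'
#' @param popSize N, number of diploid individuals (>= 2).
#' @param chromLength l, chromosome length in Morgan.
#' @return a [Population] at generation 0.
#' @examples
#' p0 <- initFounders(4, 1)
#' summarizeIBD(members(p0)[[1]])
#' @export
initFounders <- function(popSize, chromLength) {
  if (popSize < 2L)
    stop("popSize must be >= 2: mating without selfing needs two parents")
  inds <- lapply(seq_len(popSize), function(i)
    individual(founderMosaic(2L * i - 1L, chromLength),
               founderMosaic(2L * i, chromLength)))
  new("Population", members = inds, generation = 0L)
}

#' Advance a population by one generation
#'
#' Wright–Fisher-style reproduction without selfing: for each of the N
#' offspring independently, an ordered pair of two distinct parents is drawn
#' uniformly at random (with replacement across offspring, so family sizes
#' are multinomial), and each parent contributes one gamete by [meiosis()].
#'
#' @param pop a [Population] of size >= 2.
#' @return the offspring [Population], generation index incremented.
#' @examples
#' set.seed(1)
#' p1 <- nextGeneration(initFounders(4, 1))
#' @export
nextGeneration <- function(pop) {
  n <- length(pop@members)
  if (n < 2L) stop("need at least two individuals to mate without selfing")
  offspring <- lapply(seq_len(n), function(o) {
    p1 <- sample.int(n, 1L)
    p2 <- sample.int(n - 1L, 1L)
    if (p2 >= p1) p2 <- p2 + 1L
    individual(meiosis(pop@members[[p1]]), meiosis(pop@members[[p2]]))
  })
  new("Population", members = offspring, generation = pop@generation + 1L)
}

#' Summaries of every individual in a population
#'
#' @param pop a [Population].
#' @return data.frame with one row per individual: `individual`, `d`, `k`,
#'   `h`, `zCount`, `ibdTips`, `strictCount`, `strictLength`.
#' @export
populationSummary <- function(pop) {
  s <- do.call(rbind, lapply(pop@members, summarizeIBD))
  cbind(individual = seq_len(nrow(s)), s)
}

#' Run replicated forward simulations
#'
#' Simulates R independent population trajectories of the drift-only model
#' using the compiled engine. Each replicate runs on its own child seed drawn
#' reproducibly from the root seed, so a run is exactly reproducible from
#' (seed, parameters) and individual replicates can be re-run in isolation.
#'
#' Per-generation aggregates are kept for every replicate and generation;
#' per-individual summaries and (optionally) relaxed-block records are kept
#' at the recorded generations only.
#'
#' @param params a [SimParams].
#' @param verbose log progress every 10\% of replicates.
#' @return a [ReplicateSet].
#' @examples
#' rs <- runReplicates(simParams(popSize = 10, nGenerations = 5,
#'                               nReplicates = 20, seed = 7))
#' head(generationStats(rs))
#' @export
runReplicates <- function(params, verbose = FALSE) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  R <- params@nReplicates
  nGen <- params@nGenerations
  set.seed(params@seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, R)
  nrowGS <- (nGen + 1L) * R
  gs <- matrix(NA_real_, nrowGS, 6L)
  indList <- vector("list", R)
  blkList <- vector("list", R)
  pairMode <- if (params@pairing == "random-pair") 1L else 0L
  tick <- max(1L, R %/% 10L)
  for (r in seq_len(R)) {
    set.seed(childSeeds[r])
    res <- sim_replicate_cpp(params@popSize, params@chromLength, nGen,
                             params@recordGenerations, params@recordBlocks,
                             pairMode)
    gs[((r - 1L) * (nGen + 1L) + 1L):(r * (nGen + 1L)), ] <- res$genStats
    if (nrow(res$ind) > 0L)
      indList[[r]] <- cbind(r, res$ind)
    if (nrow(res$blocks) > 0L)
      blkList[[r]] <- cbind(r, res$blocks)
    if (verbose && r %% tick == 0L)
      message(sprintf("replicate %d / %d (%d%%)", r, R,
                      as.integer(round(100 * r / R))))
  }
  gsDF <- data.frame(replicate = rep(seq_len(R), each = nGen + 1L),
                     generation = rep(0:nGen, R),
                     sumD = gs[, 1L], sumK = as.integer(gs[, 2L]),
                     sumZ = as.integer(gs[, 3L]),
                     sumTips = as.integer(gs[, 4L]),
                     nIndWithBlocks = as.integer(gs[, 5L]),
                     sumIndMean = gs[, 6L])
  ind <- do.call(rbind, indList)
  if (is.null(ind)) ind <- matrix(numeric(0), 0L, 9L)
  indDF <- data.frame(replicate = as.integer(ind[, 1L]),
                      generation = as.integer(ind[, 2L]),
                      individual = as.integer(ind[, 3L]),
                      d = ind[, 4L], k = as.integer(ind[, 5L]),
                      h = 1 - ind[, 4L] / params@chromLength,
                      zCount = as.integer(ind[, 6L]),
                      ibdTips = as.integer(ind[, 7L]),
                      strictCount = as.integer(ind[, 8L]),
                      strictLength = ind[, 9L])
  blk <- do.call(rbind, blkList)
  if (is.null(blk)) blk <- matrix(numeric(0), 0L, 5L)
  blkDF <- data.frame(replicate = as.integer(blk[, 1L]),
                      generation = as.integer(blk[, 2L]),
                      individual = as.integer(blk[, 3L]),
                      start = blk[, 4L], end = blk[, 5L],
                      length = blk[, 5L] - blk[, 4L])
  new("ReplicateSet", params = params, generationStats = gsDF,
      individuals = indDF, blocks = blkDF, childSeeds = childSeeds)
}
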