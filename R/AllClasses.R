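#' @import methods
NULL

#' Mosaic: a chromosome as a founder-origin mosaic
#'
#' A chromosome is represented by the positions (in Morgan) at which its
#' ancestral origin changes, together with one origin label per segment.
#' Internal breakpoints are the chromosome's junctions in Fisher's sense:
#' crossovers that fell between two tracts of identical origin are invisible
#' and are never stored, so adjacent segments always carry different labels.
#'
#' @slot breakpoints numeric vector `0 = x_0 < x_1 < ... < x_m = l`; for the
#'   degenerate zero-length chromosome this is the single value 0.
#' @slot origins integer vector of length `m`, one founder-chromosome label
#'   per segment `[x_{j-1}, x_j)`; the last segment is closed at `l`.
#' @export
setClass("Mosaic", slots = c(breakpoints = "numeric", origins = "integer"))

setValidity("Mosaic", function(object) {
  bp <- object@breakpoints
  org <- object@origins
  if (length(org) == 0L) {
    if (length(bp) == 1L && bp == 0) return(TRUE)
    return("a mosaic without segments must be the zero-length chromosome (breakpoints = 0)")
  }
  if (length(bp) != length(org) + 1L)
    return("need exactly one origin per segment (length(breakpoints) == length(origins) + 1)")
  if (bp[1L] != 0)
    return("first breakpoint must be 0")
  if (any(diff(bp) <= 0))
    return("breakpoints must be strictly increasing")
  if (anyNA(bp) || anyNA(org))
    return("breakpoints and origins must not contain NA")
  if (length(org) > 1L && any(org[-1L] == org[-length(org)]))
    return("adjacent segments with equal origins must be merged (invisible crossover)")
  TRUE
})

#' Individual: an ordered pair of homologous chromosomes
#'
#' The diploid unit on which homozygosity by descent is measured. Homologue 0
#' is the maternally derived gamete, homologue 1 the paternally derived one.
#'
#' @slot maternal,paternal [Mosaic] objects of identical length.
#' @export
setClass("Individual", slots = c(maternal = "Mosaic", paternal = "Mosaic"))

setValidity("Individual", function(object) {
  lm <- .mosaicLength(object@maternal)
  lp <- .mosaicLength(object@paternal)
  if (!isTRUE(all.equal(lm, lp, tolerance = 0)) && lm != lp)
    return(sprintf("homologue length mismatch (%g vs %g Morgan)", lm, lp))
  TRUE
})

#' Population: N diploid individuals at one generation
#'
#' @slot members list of [Individual] objects, all with the same chromosome
#'   length.
#' @slot generation integer generation index; the founder population is
#'   generation 0.
#' @export
setClass("Population",
         slots = c(members = "list", generation = "integer"))

setValidity("Population", function(object) {
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    return("generation must be a single non-negative integer")
  if (!all(vapply(object@members, is, logical(1), class2 = "Individual")))
    return("members must all be Individual objects")
  if (length(object@members) > 0L) {
    ls <- vapply(object@members, function(i) .mosaicLength(i@maternal),
                 numeric(1))
    if (max(ls) - min(ls) != 0)
      return("all members must share one chromosome length")
  }
  TRUE
})

#' SimParams: configuration of a forward simulation
#'
#' @slot popSize integer N, the constant number of diploid individuals
#'   (at least 2: mating without selfing needs two distinct parents).
#' @slot chromLength numeric l, chromosome length in Morgan (> 0).
#' @slot nGenerations integer T, number of generations simulated after
#'   founding.
#' @slot nReplicates integer R, number of independent population trajectories.
#' @slot seed integer root seed; per-replicate child seeds are derived from it.
#' @slot recordGenerations integer vector of generations (subset of 0..T) at
#'   which per-individual summaries, and optionally full block records, are
#'   kept.
#' @slot recordBlocks logical, keep per-block records at recorded generations.
#' @slot pairing `"within-individual"` (homozygosity by descent, the model the
#'   theory targets) or `"random-pair"` (chromosomes re-paired at random each
#'   generation; exposed for exploration, untested against theory).
#' @export
setClass("SimParams",
         slots = c(popSize = "integer", chromLength = "numeric",
                   nGenerations = "integer", nReplicates = "integer",
                   seed = "integer", recordGenerations = "integer",
                   recordBlocks = "logical", pairing = "character"))

setValidity("SimParams", function(object) {
  if (object@popSize < 2L)
    return("popSize must be >= 2 (no selfing requires two distinct parents)")
  if (!(object@chromLength > 0))
    return("chromLength must be > 0 Morgan")
  if (object@nGenerations < 0L)
    return("nGenerations must be >= 0")
  if (object@nReplicates < 1L)
    return("nReplicates must be >= 1")
  if (anyNA(object@recordGenerations) ||
      any(object@recordGenerations < 0L) ||
      any(object@recordGenerations > object@nGenerations))
    return("recordGenerations must lie in 0..nGenerations")
  if (!object@pairing %in% c("within-individual", "random-pair"))
    return("pairing must be 'within-individual' or 'random-pair'")
  TRUE
})

#' ReplicateSet: the result of a replicated forward simulation
#'
#' Holds per-generation aggregates for every replicate (enough to compute all
#' three mean block-length measures and the empirical moments), plus full
#' per-individual summaries and per-block records at the recorded generations.
#'
#' @slot params the [SimParams] the run was made with.
#' @slot generationStats data.frame, one row per (replicate, generation):
#'   `sumD` (total relaxed-IBD length), `sumK` (block count), `sumZ`
#'   (external-junction count), `sumTips` (chromosome ends inside an IBD
#'   tract), `nIndWithBlocks`, `sumIndMean` (sum over individuals with blocks
#'   of their per-individual mean block length).
#' @slot individuals data.frame of per-individual summaries at recorded
#'   generations: `d`, `k`, `h`, `zCount`, `ibdTips`, `strictCount`,
#'   `strictLength`.
#' @slot blocks data.frame of relaxed-block records at recorded generations:
#'   `replicate`, `generation`, `individual`, `start`, `end`, `length`.
#' @slot childSeeds integer vector of per-replicate seeds.
#' @export
setClass("ReplicateSet",
         slots = c(params = "SimParams", generationStats = "data.frame",
                   individuals = "data.frame", blocks = "data.frame",
                   childSeeds = "integer"))

setValidity("ReplicateSet", function(object) {
  if (length(object@childSeeds) != object@params@nReplicates)
    return("need one child seed per replicate")
  TRUE
})

# total map length of a mosaic (0 for the degenerate zero-length chromosome)
.mosaicLength <- function(m) m@breakpoints[length(m@breakpoints)]
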