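#' @include AllClasses.R
NULL

#' Chromosome length in Morgan
#' @param x a [Mosaic], [Individual] or [Population].
#' @return numeric length in Morgan.
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))

#' @rdname chromLength
#' @export
setMethod("chromLength", "Mosaic", function(x) .mosaicLength(x))

#' @rdname chromLength
#' @export
setMethod("chromLength", "Individual", function(x) .mosaicLength(x@maternal))

#' @rdname chromLength
#' @export
setMethod("chromLength", "Population", function(x) {
  if (length(x@members) == 0L) return(NA_real_)
  chromLength(x@members[[1L]])
})

#' Segments of a mosaic as a table
#' @param x a [Mosaic].
#' @return data.frame with columns `start`, `end`, `origin`.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname segmentTable
#' @export
setMethod("segmentTable", "Mosaic", function(x) {
  m <- length(x@origins)
  data.frame(start = x@breakpoints[seq_len(m)],
             end = x@breakpoints[seq_len(m) + 1L],
             origin = x@origins)
})

#' Junction positions of a mosaic
#'
#' The internal breakpoints of the mosaic, i.e. its junctions: boundaries
#' between tracts of different ancestral origin. Chromosome tips are not
#' junctions.
#' @param x a [Mosaic].
#' @return numeric vector of positions in (0, l), possibly empty.
#' @export
setGeneric("junctionPositions", function(x) standardGeneric("junctionPositions"))

#' @rdname junctionPositions
#' @export
setMethod("junctionPositions", "Mosaic", function(x) {
  bp <- x@breakpoints
  if (length(bp) <= 2L) numeric(0) else bp[-c(1L, length(bp))]
})

#' Access one homologue of an individual
#' @param x an [Individual].
#' @param i homologue index, 0 (maternal) or 1 (paternal).
#' @return a [Mosaic].
#' @export
setGeneric("homologue", function(x, i) standardGeneric("homologue"))

#' @rdname homologue
#' @export
setMethod("homologue", "Individual", function(x, i) {
  stopifnot(i %in% c(0L, 1L))
  if (i == 0L) x@maternal else x@paternal
})

#' Members of a population
#' @param x a [Population].
#' @return list of [Individual] objects.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname members
#' @export
setMethod("members", "Population", function(x) x@members)

#' Generation index of a population
#' @param x a [Population].
#' @return integer (founders are generation 0).
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' @rdname generation
#' @export
setMethod("generation", "Population", function(x) x@generation)

#' Simulation parameters of a result object
#' @param x a [ReplicateSet].
#' @return the [SimParams] used for the run.
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' @rdname parameters
#' @export
setMethod("parameters", "ReplicateSet", function(x) x@params)

#' Per-(replicate, generation) aggregates of a simulation
#' @param x a [ReplicateSet].
#' @return data.frame, see [ReplicateSet-class].
#' @export
setGeneric("generationStats", function(x) standardGeneric("generationStats"))

#' @rdname generationStats
#' @export
setMethod("generationStats", "ReplicateSet", function(x) x@generationStats)

#' Per-individual IBD summaries at recorded generations
#' @param x a [ReplicateSet].
#' @return data.frame, see [ReplicateSet-class].
#' @export
setGeneric("individualSummaries",
           function(x) standardGeneric("individualSummaries"))

#' @rdname individualSummaries
#' @export
setMethod("individualSummaries", "ReplicateSet", function(x) x@individuals)

#' Relaxed-IBD block records at recorded generations
#' @param x a [ReplicateSet].
#' @return data.frame, see [ReplicateSet-class].
#' @export
setGeneric("blockRecords", function(x) standardGeneric("blockRecords"))

#' @rdname blockRecords
#' @export
setMethod("blockRecords", "ReplicateSet", function(x) x@blocks)

setMethod("show", "Mosaic", function(object) {
  m <- length(object@origins)
  cat(sprintf("Mosaic of length %g Morgan, %d segment%s, %d junction%s\n",
              .mosaicLength(object), m, if (m == 1L) "" else "s",
              max(m - 1L, 0L), if (m == 2L) "" else "s"))
  if (m > 0L && m <= 12L) {
    st <- segmentTable(object)
    cat(paste(sprintf("  [%.6g, %.6g) origin %d", st$start, st$end, st$origin),
              collapse = "\n"), "\n")
  }
})

setMethod("show", "Individual", function(object) {
  cat(sprintf("Individual (l = %g Morgan)\n", chromLength(object)))
  cat(sprintf("  homologue 0: %d segment(s); homologue 1: %d segment(s)\n",
              length(object@maternal@origins), length(object@paternal@origins)))
})

setMethod("show", "Population", function(object) {
  cat(sprintf("Population of %d individuals at generation %d (l = %g Morgan)\n",
              length(object@members), object@generation, chromLength(object)))
})

setMethod("show", "SimParams", function(object) {
  cat("Forward IBD simulation parameters\n")
  cat(sprintf("  N = %d diploid individuals, l = %g Morgan\n",
              object@popSize, object@chromLength))
  cat(sprintf("  %d generation(s), %d replicate(s), seed %d\n",
              object@nGenerations, object@nReplicates, object@seed))
  cat(sprintf("  recording %d generation(s)%s, pairing: %s\n",
              length(object@recordGenerations),
              if (object@recordBlocks) " with block records" else "",
              object@pairing))
})

setMethod("show", "ReplicateSet", function(object) {
  p <- object@params
  cat(sprintf(
    "ReplicateSet: %d replicate(s) of N = %d, l = %g Morgan, %d generation(s)\n",
    p@nReplicates, p@popSize, p@chromLength, p@nGenerations))
  cat(sprintf("  aggregates: %d rows; individual summaries: %d rows; blocks: %d rows\n",
              nrow(object@generationStats), nrow(object@individuals),
              nrow(object@blocks)))
})
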