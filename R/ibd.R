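#' @include AllClasses.R
NULL

#' Construct a diploid individual
#'
#' @param maternal,paternal [Mosaic] homologues of identical length;
#'   homologue 0 is maternal, homologue 1 paternal.
#' @return an [Individual].
#' @export
individual <- function(maternal, paternal) {
  new("Individual", maternal = maternal, paternal = paternal)
}

# Elementary decomposition of a homologous pair: the union of both
# breakpoint sets cuts [0, l] into intervals on which both origins are
# constant. Everything downstream (relaxed/strict blocks, junction
# classification, summaries) reads off this decomposition.
.elementary <- function(ind) {
  m0 <- ind@maternal; m1 <- ind@paternal
  u <- sort(unique(c(m0@breakpoints, m1@breakpoints)))
  if (length(u) < 2L)
    return(list(start = numeric(0), end = numeric(0),
                o0 = integer(0), o1 = integer(0), ibd = logical(0)))
  st <- u[-length(u)]
  i0 <- findInterval(st, m0@breakpoints)
  i1 <- findInterval(st, m1@breakpoints)
  o0 <- m0@origins[i0]; o1 <- m1@origins[i1]
  list(start = st, end = u[-1L], o0 = o0, o1 = o1, ibd = o0 == o1)
}

#' Relaxed IBD blocks of a homologous pair
#'
#' A relaxed IBD block is a maximal contiguous tract on which the two
#' homologues are IBD at every position, the shared ancestral origin being
#' allowed to change along the block. Blocks are delimited by external
#' junctions or chromosome tips.
#'
#' @param ind an [Individual] (or any homologous pair built as one).
#' @return data.frame with columns `start`, `end`, `length`, sorted and
#'   disjoint; zero rows when the pair shares no ancestry.
#' @examples
#' a <- mosaic(c(0, 0.5, 1), c(1L, 2L))
#' b <- mosaic(c(0, 0.5, 0.8, 1), c(1L, 2L, 3L))
#' relaxedSegments(individual(a, b))   # one block [0, 0.8)
#' @export
relaxedSegments <- function(ind) {
  e <- .elementary(ind)
  if (!any(e$ibd))
    return(data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0)))
  r <- rle(e$ibd)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- r$values
  st <- e$start[lo[keep]]; en <- e$end[hi[keep]]
  data.frame(start = st, end = en, length = en - st)
}

#' Strict IBD blocks of a homologous pair
#'
#' Strict blocks additionally require the same ancestral origin at every
#' position: relaxed blocks are subdivided at every internal junction lying
#' within an IBD tract, so a strict block contains no junction at all.
#' Strict blocks partition the relaxed blocks as point sets.
#'
#' @param ind an [Individual].
#' @return data.frame with columns `start`, `end`, `length`, `origin`.
#' @examples
#' a <- mosaic(c(0, 0.5, 1), c(1L, 2L))
#' b <- mosaic(c(0, 0.5, 0.8, 1), c(1L, 2L, 3L))
#' strictSegments(individual(a, b))   # [0, 0.5) origin 1 and [0.5, 0.8) origin 2
#' @export
strictSegments <- function(ind) {
  e <- .elementary(ind)
  if (!any(e$ibd))
    return(data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), origin = integer(0)))
  # a new run starts whenever IBD status or the shared origin changes
  n <- length(e$ibd)
  chg <- c(TRUE, e$ibd[-1L] != e$ibd[-n] |
             (e$ibd[-1L] & e$ibd[-n] & e$o0[-1L] != e$o0[-n]))
  lo <- which(chg)
  hi <- c(lo[-1L] - 1L, n)
  sel <- e$ibd[lo]
  st <- e$start[lo[sel]]; en <- e$end[hi[sel]]
  data.frame(start = st, end = en, length = en - st,
             origin = e$o0[lo[sel]])
}

#' Classify the junctions of a homologous pair
#'
#' Every internal breakpoint of either homologue is a junction. Projected on
#' the pair's IBD axis, a junction is external if it delimits an IBD tract
#' from a non-IBD tract (equivalently, it coincides with a relaxed-block
#' boundary), and internal otherwise, in which case its context records
#' whether it falls within an IBD or a non-IBD tract. A junction position
#' carried by both homologues (an inherited, shared junction) yields one
#' annotation per carrier.
#'
#' @param ind an [Individual].
#' @return data.frame with columns `position`, `carrier` (homologue index 0
#'   or 1), `kind` (`"external"` or `"internal"`) and `context`
#'   (`"within-IBD"` / `"within-non-IBD"`, `NA` for external junctions),
#'   sorted by position.
#' @export
classifyJunctions <- function(ind) {
  l <- chromLength(ind)
  pos <- c(junctionPositions(ind@maternal), junctionPositions(ind@paternal))
  carrier <- rep(c(0L, 1L), c(length(junctionPositions(ind@maternal)),
                              length(junctionPositions(ind@paternal))))
  if (length(pos) == 0L)
    return(data.frame(position = numeric(0), carrier = integer(0),
                      kind = character(0), context = character(0)))
  rel <- relaxedSegments(ind)
  bnd <- setdiff(c(rel$start, rel$end), c(0, l))
  ext <- pos %in% bnd
  insideIBD <- vapply(pos, function(p)
    any(rel$start < p & p < rel$end), logical(1))
  out <- data.frame(position = pos, carrier = carrier,
                    kind = ifelse(ext, "external", "internal"),
                    context = ifelse(ext, NA_character_,
                                     ifelse(insideIBD, "within-IBD",
                                            "within-non-IBD")))
  out[order(out$position, out$carrier), , drop = FALSE]
}

#' Per-individual IBD summary
#'
#' Computes the quantities the block-length estimators consume: the total
#' relaxed-IBD length d, the relaxed block count k, the non-IBD proportion
#' h = 1 - d/l, the external-junction count z and the number of chromosome
#' tips lying in an IBD tract. Every individual satisfies the block-edge
#' identity 2k = z + tips: each relaxed block has two edges, each of which
#' is either an external junction or an IBD chromosome tip.
#'
#' @param ind an [Individual].
#' @return one-row data.frame with columns `d`, `k`, `h`, `zCount`,
#'   `ibdTips`, `strictCount`, `strictLength`.
#' @examples
#' f <- individual(founderMosaic(1L, 1), founderMosaic(2L, 1))
#' summarizeIBD(f)   # founders: d = 0, k = 0, h = 1
#' @export
summarizeIBD <- function(ind) {
  l <- chromLength(ind)
  if (l == 0)
    stop("the non-IBD proportion is undefined on a zero-length chromosome")
  rel <- relaxedSegments(ind)
  str <- strictSegments(ind)
  jn <- classifyJunctions(ind)
  data.frame(d = sum(rel$length), k = nrow(rel),
             h = 1 - sum(rel$length) / l,
             zCount = sum(jn$kind == "external"),
             ibdTips = sum(rel$start == 0) + sum(rel$end == l),
             strictCount = nrow(str), strictLength = sum(str$length))
}
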