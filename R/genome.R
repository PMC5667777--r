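#' @include AllClasses.R
NULL

#' Construct a mosaic chromosome
#'
#' Low-level constructor; breakpoints must already be normalized (adjacent
#' origins differ). Use [normalizeMosaic()] to build a mosaic from a raw
#' segment table.
#'
#' @param breakpoints numeric vector `0, x_1, ..., l`.
#' @param origins integer vector of founder-copy labels, one per segment.
#' @return a [Mosaic].
#' @examples
#' mosaic(c(0, 0.5, 1), c(1L, 2L))
#' @export
mosaic <- function(breakpoints, origins) {
  new("Mosaic", breakpoints = as.numeric(breakpoints),
      origins = as.integer(origins))
}

#' Founder chromosome: a single-origin mosaic
#'
#' Founders are unrelated and non-inbred: each founder chromosome copy is a
#' single segment carrying its own globally unique origin label, so no two
#' founder chromosomes share ancestry.
#'
#' @param label integer origin label of this founder chromosome copy.
#' @param chromLength chromosome length l in Morgan (>= 0; a zero-length
#'   chromosome is a valid degenerate case).
#' @return a [Mosaic] with zero junctions.
#' @examples
#' founderMosaic(1L, 1.0)
#' @export
founderMosaic <- function(label, chromLength) {
  if (!is.numeric(chromLength) || length(chromLength) != 1L ||
      is.na(chromLength) || chromLength < 0)
    stop("chromLength must be a single non-negative number (Morgan)")
  if (chromLength == 0)
    return(new("Mosaic", breakpoints = 0, origins = integer(0)))
  mosaic(c(0, chromLength), as.integer(label))
}

#' Draw crossover positions under the Haldane model
#'
#' The crossover count per meiosis is Poisson with mean l (the chromosome
#' length in Morgan) and positions are i.i.d. uniform on (0, l) — the
#' no-interference model, i.e. a Poisson process of rate 1 per Morgan.
#' Exact floating-point collisions between two positions (a measure-zero
#' event) are re-drawn.
#'
#' @param chromLength chromosome length l in Morgan.
#' @return sorted numeric vector of crossover positions in (0, l).
#' @examples
#' set.seed(1)
#' drawCrossovers(1.0)
#' @export
drawCrossovers <- function(chromLength) {
  if (chromLength < 0) stop("chromLength must be non-negative")
  n <- stats::rpois(1L, chromLength)
  if (n == 0L) return(numeric(0))
  x <- sort(stats::runif(n, 0, chromLength))
  while (any(dup <- duplicated(x))) {
    x[dup] <- stats::runif(sum(dup), 0, chromLength)
    x <- sort(x)
  }
  x
}

#' Normalize a raw segment table into a mosaic
#'
#' Merges adjacent segments of equal origin (a breakpoint flanked by the same
#' origin on both sides is an invisible crossover, not a junction) and
#' validates that the segments tile `[0, l]` without gaps or overlaps.
#' Idempotent; total length is preserved.
#'
#' @param segments data.frame with columns `start`, `end`, `origin`, in
#'   genomic order.
#' @return a [Mosaic].
#' @examples
#' normalizeMosaic(data.frame(start = c(0, 0.2, 0.6), end = c(0.2, 0.6, 1),
#'                            origin = c(1L, 1L, 2L)))
#' @export
normalizeMosaic <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "origin") %in% names(segments)))
  if (nrow(segments) == 0L)
    return(new("Mosaic", breakpoints = 0, origins = integer(0)))
  st <- segments$start; en <- segments$end; org <- as.integer(segments$origin)
  if (st[1L] != 0)
    stop("segments must start at 0")
  if (any(en <= st))
    stop("each segment must have positive length")
  if (nrow(segments) > 1L && any(st[-1L] != en[-nrow(segments)]))
    stop("segments must tile [0, l] without gaps or overlaps")
  keep <- c(TRUE, org[-1L] != org[-length(org)])
  mosaic(c(0, en[c(keep[-1L], TRUE)]), org[keep])
}

#' One meiosis: form a gamete from a diploid parent
#'
#' Implements gamete formation under the Haldane model: a Poisson(l) number
#' of crossovers at uniform positions, a fair coin for the starting
#' homologue, switching homologue at every crossover. Crossovers falling
#' between tracts of identical origin on the two homologues are invisible:
#' the returned mosaic is normalized, so its junction count can be smaller
#' than the crossover count.
#'
#' @param parent an [Individual].
#' @param detailed if `TRUE`, also return the crossover positions and
#'   starting homologue used.
#' @return a [Mosaic] gamete, or (if `detailed`) a list with elements
#'   `gamete`, `crossovers`, `start`.
#' @examples
#' set.seed(42)
#' p <- individual(founderMosaic(1L, 1), founderMosaic(2L, 1))
#' meiosis(p)
#' @export
meiosis <- function(parent, detailed = FALSE) {
  stopifnot(is(parent, "Individual"))
  l <- chromLength(parent)
  xo <- drawCrossovers(l)
  start <- if (stats::runif(1L) < 0.5) 0L else 1L
  g <- .splice(parent@maternal, parent@paternal, l, xo, start)
  if (detailed) list(gamete = g, crossovers = xo, start = start) else g
}

# Copy alternating stretches of the two parental mosaics between the cut
# points, merging adjacent equal origins on the fly.
.splice <- function(m0, m1, l, xo, start) {
  if (l == 0) return(new("Mosaic", breakpoints = 0, origins = integer(0)))
  cuts <- c(0, xo, l)
  src <- list(m0, m1)
  outBp <- 0
  outOrg <- integer(0)
  cur <- start + 1L
  for (j in seq_len(length(cuts) - 1L)) {
    a <- cuts[j]; b <- cuts[j + 1L]
    M <- src[[cur]]
    bp <- M@breakpoints; org <- M@origins
    s <- findInterval(a, bp)              # segment containing a: bp[s] <= a
    if (s > length(org)) s <- length(org) # a == l can only be the last cut
    e <- findInterval(b, bp, left.open = TRUE)  # last segment with bp[e] < b
    ends <- c(if (e > s) bp[(s + 1L):e], b)
    orgs <- org[s:e]
    for (q in seq_along(orgs)) {
      no <- length(outOrg)
      if (no > 0L && outOrg[no] == orgs[q]) {
        outBp[no + 1L] <- ends[q]
      } else {
        outOrg[no + 1L] <- orgs[q]
        outBp[no + 2L] <- ends[q]
      }
    }
    cur <- 3L - cur
  }
  new("Mosaic", breakpoints = outBp, origins = outOrg)
}
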