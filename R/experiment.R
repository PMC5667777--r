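#' @include AllClasses.R
NULL

#' The reference drift experiment: measures vs prediction over time
#'
#' Runs the drift-only model at its reference configuration — N = 20 diploid
#' individuals on a 1 Morgan chromosome — and evaluates the three mean
#' block-length measures together with the finite-chromosome prediction at
#' every generation, producing a plot-ready table. The defaults (100
#' generations, 10,000 replicates) are a scaled-down version of the
#' full-scale experiment (500 generations, 1,000,000 replicates); the
#' qualitative relations between the measures stabilize well before full
#' scale, which remains available by overriding the arguments.
#'
#' @param popSize,chromLength,nGenerations,nReplicates,seed see [simParams()].
#' @param recordGenerations generations at which block records are kept
#'   (used by block-resampling diagnostics; aggregates are kept everywhere).
#' @param verbose log progress.
#' @return list with elements `curves` (the [estimateReport()] table),
#'   `data` (the [ReplicateSet]) and `params`.
#' @examples
#' \donttest{
#' ex <- meanLengthCurves(nReplicates = 200, seed = 1)
#' head(ex$curves)
#' }
#' @export
meanLengthCurves <- function(popSize = 20L, chromLength = 1.0,
                             nGenerations = 100L, nReplicates = 10000L,
                             seed = 1L,
                             recordGenerations = c(10L, 50L, 100L),
                             verbose = FALSE) {
  recordGenerations <- recordGenerations[recordGenerations <= nGenerations]
  p <- simParams(popSize = popSize, chromLength = chromLength,
                 nGenerations = nGenerations, nReplicates = nReplicates,
                 seed = seed, recordGenerations = recordGenerations,
                 recordBlocks = TRUE)
  rs <- runReplicates(p, verbose = verbose)
  list(curves = estimateReport(rs), data = rs, params = p)
}

#' Check the headline relations on an experiment table
#'
#' Evaluates the two qualitative claims the experiment illustrates:
#' (i) the across-replicate measure tracks the finite-chromosome prediction
#' (relative deviation below `tol` at the check generations), and (ii) it is
#' a lower bound of the population-wise and individual-wise measures at
#' every generation, within `nSE` between-replicate standard errors.
#'
#' @param curves an [estimateReport()] table.
#' @param checkGenerations generations at which the tracking claim is
#'   evaluated.
#' @param tol relative tolerance for the tracking claim.
#' @param nSE standard-error multiplier for the lower-bound claim.
#' @param minReplicates below this replicate count the assertions are not
#'   evaluated (Monte-Carlo noise dominates); a warning is issued.
#' @param nReplicates replicate count of the run the table came from.
#' @return data.frame with one row per assertion: `check`, `generation`,
#'   `value`, `bound`, `pass`; zero rows (with a warning) when skipped.
#' @export
checkHeadlineClaims <- function(curves, checkGenerations = c(10L, 50L, 100L),
                                tol = 0.02, nSE = 2,
                                minReplicates = 100L,
                                nReplicates = Inf) {
  if (nReplicates < minReplicates) {
    warning("fewer than ", minReplicates,
            " replicates: error bars too wide, assertions skipped")
    return(data.frame(check = character(0), generation = integer(0),
                      value = numeric(0), bound = numeric(0),
                      pass = logical(0)))
  }
  checkGenerations <- intersect(checkGenerations, curves$generation)
  track <- do.call(rbind, lapply(checkGenerations, function(t) {
    row <- curves[curves$generation == t, ]
    dev <- abs(row$L_AR - row$EL_pred) / row$EL_pred
    data.frame(check = "tracks-prediction", generation = t,
               value = dev, bound = tol, pass = is.finite(dev) && dev < tol)
  }))
  ok <- !is.na(curves$L_AR)
  lower <- rbind(
    data.frame(check = "lower-bound-PW", generation = curves$generation[ok],
               value = curves$L_AR[ok],
               bound = curves$L_PW[ok] + nSE * curves$se_PW[ok],
               pass = curves$L_AR[ok] <=
                 curves$L_PW[ok] + nSE * curves$se_PW[ok]),
    data.frame(check = "lower-bound-IW", generation = curves$generation[ok],
               value = curves$L_AR[ok],
               bound = curves$L_IW[ok] + nSE * curves$se_IW[ok],
               pass = curves$L_AR[ok] <=
                 curves$L_IW[ok] + nSE * curves$se_IW[ok]))
  rbind(track, lower)
}
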