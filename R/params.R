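#' Clustering parameters
#'
#' S4 container for all tunable parameters of the divisive clustering.
#' Construct with [weedParams()]; slots are validated on construction.
#'
#' @slot W Window width in bp. `NA` means "resolve at run time" to
#'   `floor(median sequence length / 3)`, the recommended wide-window
#'   default (much longer than a typical transcription-factor motif).
#' @slot pseudocount Dirichlet pseudocount `c` added to every nucleotide
#'   count in the marginal-likelihood scoring (default 0.5).
#' @slot splitT Interpolation parameter `T` of the split-significance
#'   threshold `L1 + T * (L2 - L1)` (default 0.4).
#' @slot ariThreshold Adjusted-Rand-index threshold `r` that pairwise
#'   replicate splits must exceed (default 0.2).
#' @slot maxClusters Maximum number of clusters reported; the final state is
#'   merged down to this by likelihood-loss joining (default 15).
#' @slot reassignFraction Fraction of poorest-scoring sequences re-examined
#'   in each reassignment step (default 0.20).
#' @slot initMoveFraction Fraction of members moved to seed the initial
#'   two-way split (default 0.25).
#' @slot nSplitReps Number of replicate splits for the reproducibility test
#'   (default 4).
#' @slot votesNeeded Number of pairwise replicate ARIs that must exceed
#'   `ariThreshold` (default 3).
#' @slot allowShifts Search all window offsets (default `TRUE`).
#' @slot allowRevcomp Search the reverse strand (default `TRUE`).
#' @slot seed Integer seed governing every random draw of a run.
#' @slot minSplitSize Clusters smaller than this are never split (default 8).
#' @slot maxPasses Cap on top-level passes (default 50).
#' @slot maxSweeps Cap on refinement sweeps within one replicate split
#'   (default 200; fixed points are typically reached far earlier).
#' @aliases ClusterParams-class
#' @export
setClass("ClusterParams", representation(
  W = "integer", pseudocount = "numeric", splitT = "numeric",
  ariThreshold = "numeric", maxClusters = "integer",
  reassignFraction = "numeric", initMoveFraction = "numeric",
  nSplitReps = "integer", votesNeeded = "integer",
  allowShifts = "logical", allowRevcomp = "logical",
  seed = "integer", minSplitSize = "integer",
  maxPasses = "integer", maxSweeps = "integer"))

setValidity("ClusterParams", function(object) {
  msg <- character(0)
  if (!is.na(object@W) && object@W < 2L) msg <- c(msg, "W must be >= 2")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be > 0")
  if (object@splitT <= 0 || object@splitT >= 1)
    msg <- c(msg, "splitT must lie in (0, 1)")
  if (object@ariThreshold <= -0.5 || object@ariThreshold >= 1)
    msg <- c(msg, "ariThreshold must lie in (-0.5, 1)")
  if (object@reassignFraction <= 0 || object@reassignFraction >= 1)
    msg <- c(msg, "reassignFraction must lie in (0, 1)")
  if (object@initMoveFraction <= 0 || object@initMoveFraction >= 1)
    msg <- c(msg, "initMoveFraction must lie in (0, 1)")
  if (object@nSplitReps < 2L) msg <- c(msg, "nSplitReps must be >= 2")
  if (object@votesNeeded < 1L) msg <- c(msg, "votesNeeded must be >= 1")
  if (object@maxClusters < 1L) msg <- c(msg, "maxClusters must be >= 1")
  if (object@minSplitSize < 2L) msg <- c(msg, "minSplitSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct clustering parameters
#'
#' @param W Window width in bp, or `NA` to use one third of the median
#'   sequence length at run time.
#' @param pseudocount Dirichlet pseudocount `c` (> 0).
#' @param splitT Split-threshold interpolation `T` in (0, 1).
#' @param ariThreshold Replicate-ARI threshold `r` in (-0.5, 1).
#' @param maxClusters Maximum number of reported clusters.
#' @param reassignFraction Poorest fraction re-examined per reassignment.
#' @param initMoveFraction Fraction moved by the initial split.
#' @param nSplitReps Replicate splits per reproducibility test.
#' @param votesNeeded Pairwise ARIs that must exceed `ariThreshold`.
#' @param allowShifts Search window offsets?
#' @param allowRevcomp Search the reverse strand?
#' @param seed Integer seed.
#' @param minSplitSize Minimum splittable cluster size.
#' @param maxPasses Pass budget of the top-level loop.
#' @param maxSweeps Sweep cap within one refinement.
#' @return A validated [ClusterParams-class] object.
#' @examples
#' weedParams(W = 33L, seed = 7L)
#' @export
weedParams <- function(W = NA_integer_, pseudocount = 0.5, splitT = 0.4,
                       ariThreshold = 0.2, maxClusters = 15L,
                       reassignFraction = 0.20, initMoveFraction = 0.25,
                       nSplitReps = 4L, votesNeeded = 3L,
                       allowShifts = TRUE, allowRevcomp = TRUE,
                       seed = 1L, minSplitSize = 8L,
                       maxPasses = 50L, maxSweeps = 200L) {
  new("ClusterParams", W = as.integer(W), pseudocount = pseudocount,
      splitT = splitT, ariThreshold = ariThreshold,
      maxClusters = as.integer(maxClusters),
      reassignFraction = reassignFraction,
      initMoveFraction = initMoveFraction,
      nSplitReps = as.integer(nSplitReps),
      votesNeeded = as.integer(votesNeeded),
      allowShifts = allowShifts, allowRevcomp = allowRevcomp,
      seed = as.integer(seed), minSplitSize = as.integer(minSplitSize),
      maxPasses = as.integer(maxPasses), maxSweeps = as.integer(maxSweeps))
}

setMethod("show", "ClusterParams", function(object) {
  cat("ClusterParams\n")
  cat("  W =", ifelse(is.na(object@W), "median(L)/3 at run time", object@W),
      " pseudocount =", object@pseudocount, "\n")
  cat("  splitT =", object@splitT, " ariThreshold =", object@ariThreshold,
      " maxClusters =", object@maxClusters, "\n")
  cat("  replicates =", object@nSplitReps, "(votes needed:",
      object@votesNeeded, ") shifts =", object@allowShifts,
      " revcomp =", object@allowRevcomp, "\n")
  cat("  seed =", object@seed, "\n")
  invisible(NULL)
})
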