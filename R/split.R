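# Split engine: one cluster -> two children (+ inconsistent pool), guarded
# by the LLR significance threshold and the replicate-ARI reproducibility
# test.
#
# Internal cluster representation (performance path): a plain list with
#   members : integer indices into the encoded sequence list
#   offsets : integer 0-based window starts, one per member
#   strands : integer, 1 = forward, 2 = reverse
#   counts  : 5 x W numeric count matrix (rows N,A,C,G,T)
# kept consistent by the helpers below.

.newCluster <- function(seqs, members, offsets, strands, W) {
  list(members = as.integer(members), offsets = as.integer(offsets),
       strands = as.integer(strands),
       counts = cpp_counts(seqs, as.integer(members), as.integer(offsets),
                           as.integer(strands), as.integer(W)))
}

.clusterSize <- function(cl) length(cl$members)

.looScores <- function(seqs, cl, pseudocount) {
  cpp_loo_scores(seqs, cl$members, cl$offsets, cl$strands, cl$counts,
                 pseudocount)
}

#' Split-significance threshold from idealized clean separations
#'
#' Anchors the log-likelihood-ratio scale for accepting a split of sizes
#' `M1` and `M2`.  The idealization pictures the parent's `M = M1 + M2`
#' random sequences split cleanly on `k` positions: half the sequences
#' carry only A or C there, the other half only G or T, while every other
#' column stays evenly distributed -- so the idealized children each have
#' `M/2` members (a clean split of random sequences is balanced by
#' construction) and the width-`W` idealized count matrices are uniform
#' (`M/8` per base per child) except in the `k` discriminating columns
#' (`M/4` per allowed base).  `L1` (`k = 1`) is the LLR of a split on a
#' single clean column -- always attainable by chance, hence not
#' significant; `L2` (`k = 2`) is the LLR of two clean columns, taken as
#' clearly significant.  A proposed split must reach
#' `L1 + T * (L2 - L1)`.  Fractional idealized counts enter the gamma
#' functions directly.
#'
#' @param M1,M2 Child sizes (>= 1); only their sum enters the idealization.
#' @param W Window width.
#' @param pseudocount Dirichlet pseudocount `c`.
#' @param splitT Interpolation parameter `T` in (0, 1).
#' @return A list with `L1`, `L2` and `threshold` (nats).
#' @examples
#' splitThreshold(100, 100, W = 20)
#' @export
splitThreshold <- function(M1, M2, W, pseudocount = 0.5, splitT = 0.4) {
  if (M1 < 1 || M2 < 1) stop("child sizes must be >= 1")
  c0 <- pseudocount
  colterm <- function(v)
    sum(lgamma(v + c0)) + lgamma(4 * c0) - lgamma(sum(v) + 4 * c0) -
      4 * lgamma(c0)
  M <- M1 + M2
  h <- M / 2                               # idealized child size
  uc <- colterm(rep(h / 4, 4))             # uniform column, one child
  up <- colterm(rep(M / 4, 4))             # uniform column, parent
  d1 <- colterm(c(h / 2, h / 2, 0, 0))     # discriminating column, child 1
  d2 <- colterm(c(0, 0, h / 2, h / 2))
  dp <- colterm(rep(M / 4, 4))             # parent: evenly distributed
  du <- 2 * uc - up                        # per-column LLR, uniform
  dd <- d1 + d2 - dp                       # per-column LLR, discriminating
  L1 <- (W - 1) * du + dd
  L2 <- (W - 2) * du + 2 * dd
  list(L1 = L1, L2 = L2, threshold = L1 + splitT * (L2 - L1))
}

# Initial two-way partition: members ranked by leave-one-out likelihood at
# their current windows; the top ceiling(f * M) ("best") are moved to a new
# cluster.  With random = TRUE a uniformly random subset of the same size is
# moved instead (used for replicate initializations beyond the first).
.initialPartition <- function(seqs, cl, pseudocount, fraction,
                              random = FALSE) {
  M <- .clusterSize(cl)
  if (M < 2L) stop("cluster too small to partition")
  nMove <- ceiling(fraction * M)
  if (nMove >= M) nMove <- M - 1L
  if (random) {
    moved <- sample.int(M, nMove)
  } else {
    loo <- .looScores(seqs, cl, pseudocount)
    moved <- order(loo, decreasing = TRUE)[seq_len(nMove)]
  }
  membership <- rep(1L, M)
  membership[moved] <- 2L
  membership
}

# One replicate: initial partition followed by iterative refinement to a
# fixed point.  Returns membership/offsets/strands plus failure flag when a
# child emptied.
.replicateSplit <- function(seqs, cl, params, random) {
  W <- ncol(cl$counts)
  membership <- .initialPartition(seqs, cl, params@pseudocount,
                                  params@initMoveFraction, random = random)
  r <- cpp_refine(seqs, cl$members, membership, cl$offsets, cl$strands,
                  W, params@pseudocount, params@allowShifts,
                  params@allowRevcomp, params@maxSweeps)
  list(membership = r$membership, offsets = r$offsets, strands = r$strands,
       sweeps = r$sweeps, failed = isTRUE(r$emptied))
}

#' Refine a two-way split to a fixed point
#'
#' Repeats full sweeps in fresh random order: each member is removed from
#' its cluster, its best window is scored against both clusters, and it is
#' inserted into the more likely one, until a sweep changes nothing (or the
#' sweep cap is hit).  Exposed mainly for testing; [attemptSplit()] drives
#' it internally.
#'
#' @param windows Character vector of member sequences.
#' @param membership Integer vector of 1/2 initial assignments.
#' @param params A [ClusterParams-class] object with a concrete `W`.
#' @return List with `membership`, `offsets`, `strands` (integer codes),
#'   `sweeps` and `emptied`.
#' @export
refineSplit <- function(windows, membership, params) {
  seqs <- lapply(windows, .encodeSeq)
  W <- params@W
  if (is.na(W)) stop("params@W must be concrete here")
  n <- length(seqs)
  offs <- vapply(seqs, function(s) (length(s) - W) %/% 2L, integer(1))
  r <- cpp_refine(seqs, seq_len(n), as.integer(membership), as.integer(offs),
                  rep(1L, n), W, params@pseudocount, params@allowShifts,
                  params@allowRevcomp, params@maxSweeps)
  r
}

# Majority-membership matching of a replicate's two-way labels to the base
# replicate's: identity or swap, whichever maximizes the agreement.
.matchTwoWay <- function(base, other) {
  agreeId <- sum(base == other)
  if (agreeId >= length(base) - agreeId) other else 3L - other
}

.pairARI <- function(a, b) adjustedRandIndex(a, b)

#' Attempt to split a cluster in two
#'
#' Runs up to `nSplitReps` replicate splits (ranked initial partition for
#' the first, random initializations for the rest, each refined to a fixed
#' point) and accepts the split only if (a) enough pairwise adjusted Rand
#' indices between replicate labelings exceed `ariThreshold` -- when the
#' first three already agree pairwise the fourth replicate is skipped --
#' and (b) the log-likelihood ratio of the consensus split clears
#' [splitThreshold()].  On acceptance, replicate labels are matched by
#' majority membership and members not clustered identically across the
#' three consensus replicates are routed to the `inconsistent` pool.
#' A replicate that empties a child counts as failing all its pairwise
#' comparisons.
#'
#' @param seqs List of encoded sequences (internal) -- see
#'   [runClustering()] for the user-level driver.
#' @param cl Internal cluster (list with members/offsets/strands/counts).
#' @param params A [ClusterParams-class] object.
#' @return A list (`SplitResult`): `accepted`, `child1`, `child2`,
#'   `inconsistent` (member indices), `llr`, `threshold`,
#'   `replicateARIs`, `reason`.
#' @keywords internal
.attemptSplit <- function(seqs, cl, params) {
  M <- .clusterSize(cl)
  W <- ncol(cl$counts)
  rej <- function(reason, aris = numeric(0))
    list(accepted = FALSE, child1 = NULL, child2 = NULL,
         inconsistent = integer(0), llr = NA_real_, threshold = NA_real_,
         replicateARIs = aris, reason = reason)
  if (M < params@minSplitSize) return(rej("below minimum splittable size"))

  nrep <- params@nSplitReps
  reps <- vector("list", nrep)
  for (k in 1:3) reps[[k]] <- .replicateSplit(seqs, cl, params, random = k > 1)

  ariOf <- function(i, j) {
    if (reps[[i]]$failed || reps[[j]]$failed) return(-1)
    .pairARI(reps[[i]]$membership, reps[[j]]$membership)
  }
  pairs3 <- combn(3L, 2L)
  ari3 <- apply(pairs3, 2L, function(p) ariOf(p[1], p[2]))

  if (all(ari3 > params@ariThreshold)) {
    triple <- 1:3
    aris <- ari3
  } else if (nrep >= 4L) {
    for (k in 4:nrep) reps[[k]] <- .replicateSplit(seqs, cl, params,
                                                   random = TRUE)
    pairsAll <- combn(nrep, 2L)
    ariAll <- apply(pairsAll, 2L, function(p) ariOf(p[1], p[2]))
    if (sum(ariAll > params@ariThreshold) < params@votesNeeded)
      return(rej("replicate splits not reproducible", ariAll))
    # consensus triple: highest summed pairwise ARI, deterministic tie-break
    triples <- combn(nrep, 3L)
    tripleScore <- apply(triples, 2L, function(tr) {
      sel <- apply(pairsAll, 2L, function(p) all(p %in% tr))
      sum(ariAll[sel])
    })
    triple <- triples[, which.max(tripleScore)]
    aris <- ariAll
  } else {
    return(rej("replicate splits not reproducible", ari3))
  }

  base <- reps[[triple[1]]]
  matched <- lapply(triple[-1], function(k)
    .matchTwoWay(base$membership, reps[[k]]$membership))
  consistent <- Reduce(`&`, lapply(matched, function(m) m == base$membership),
                       rep(TRUE, M))
  in1 <- which(consistent & base$membership == 1L)
  in2 <- which(consistent & base$membership == 2L)
  incon <- which(!consistent)
  if (length(in1) == 0L || length(in2) == 0L)
    return(rej("a consensus child is empty", aris))

  child1 <- .newCluster(seqs, cl$members[in1], base$offsets[in1],
                        base$strands[in1], W)
  child2 <- .newCluster(seqs, cl$members[in2], base$offsets[in2],
                        base$strands[in2], W)
  merged <- child1$counts + child2$counts
  c0 <- params@pseudocount
  llr <- clusterLogProb(child1$counts, c0) + clusterLogProb(child2$counts, c0) -
    clusterLogProb(merged, c0)
  thr <- splitThreshold(length(in1), length(in2), W, c0, params@splitT)
  if (llr < thr$threshold)
    return(list(accepted = FALSE, child1 = NULL, child2 = NULL,
                inconsistent = integer(0), llr = llr,
                threshold = thr$threshold, replicateARIs = aris,
                reason = "LLR below significance threshold"))
  list(accepted = TRUE, child1 = child1, child2 = child2,
       inconsistent = cl$members[incon],
       inconIdx = incon,
       inconOffsets = base$offsets[incon], inconStrands = base$strands[incon],
       llr = llr, threshold = thr$threshold, replicateARIs = aris,
       reason = "accepted")
}

#' Attempt a significance-tested two-way split of a set of sequences
#'
#' User-level wrapper around the internal split engine: places a centred
#' forward window on every sequence, then runs the replicate-split
#' procedure described in [attemptSplit] internals.
#'
#' @param sequences Character vector or `DNAStringSet` of sequences.
#' @param params A [ClusterParams-class] object; `W` of `NA` resolves to a
#'   third of the median sequence length.
#' @return A list with `accepted`, `membership` (1/2/NA for inconsistent,
#'   per input sequence), `llr`, `threshold`, `replicateARIs`, `reason`.
#' @examples
#' set.seed(1)
#' seqs <- vapply(1:40, function(i)
#'   paste(sample(c("A","C","G","T"), 60, TRUE), collapse = ""), "")
#' attemptSplit(seqs, weedParams(W = 20L, seed = 1L))$accepted
#' @export
attemptSplit <- function(sequences, params = weedParams()) {
  seqs <- .encodeSet(sequences)
  W <- params@W
  if (is.na(W))
    W <- max(2L, as.integer(median(lengths(seqs)) %/% 3L))
  set.seed(params@seed)
  n <- length(seqs)
  offs <- vapply(seqs, function(s) (length(s) - W) %/% 2L, integer(1))
  cl <- .newCluster(seqs, seq_len(n), offs, rep(1L, n), W)
  res <- .attemptSplit(seqs, cl, params)
  membership <- rep(NA_integer_, n)
  if (res$accepted) {
    membership[res$child1$members] <- 1L
    membership[res$child2$members] <- 2L
  }
  list(accepted = res$accepted, membership = membership, llr = res$llr,
       threshold = res$threshold, replicateARIs = res$replicateARIs,
       reason = res$reason)
}
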