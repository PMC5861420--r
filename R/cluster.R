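# Top-down driver: repeatedly attempt to split every current cluster,
# concatenate inconsistently clustered sequences into a pool cluster each
# pass, periodically reassign the poorest-scoring sequences, and finally
# merge down to maxClusters if needed.

# Reassignment of the poorest-scoring fraction.  Operates on the internal
# cluster list in place (functionally); returns the updated list plus the
# examined/moved bookkeeping.
.reassignPoorest <- function(seqs, clusters, params) {
  c0 <- params@pseudocount
  scores <- numeric(0)
  who <- integer(0)     # cluster index per entry
  pos <- integer(0)     # position within cluster
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (.clusterSize(cl) == 0L) next
    sc <- .looScores(seqs, cl, c0)
    scores <- c(scores, sc)
    who <- c(who, rep(k, length(sc)))
    pos <- c(pos, seq_along(sc))
  }
  total <- length(scores)
  nConsider <- ceiling(params@reassignFraction * total)
  ord <- order(scores)[seq_len(nConsider)]
  moved <- 0L
  for (e in ord) {
    k <- who[e]
    p <- pos[e]
    cl <- clusters[[k]]
    m <- cl$members[p]
    s <- seqs[[m]]
    wcode <- cpp_window(s, cl$offsets[p], cl$strands[p], ncol(cl$counts))
    cl$counts <- .updateCounts(cl$counts, wcode, -1)
    cl$members <- cl$members[-p]
    cl$offsets <- cl$offsets[-p]
    cl$strands <- cl$strands[-p]
    clusters[[k]] <- cl
    best <- lapply(clusters, function(cj) {
      sm <- cpp_score_matrix(cj$counts, c0)
      cpp_best_window(s, sm, params@allowShifts, params@allowRevcomp)
    })
    sc <- vapply(best, function(b) b$score, numeric(1))
    jstar <- which.max(sc)
    if (sc[jstar] <= sc[k] + 1e-12) jstar <- k   # ties: stay put
    b <- best[[jstar]]
    cj <- clusters[[jstar]]
    cj$members <- c(cj$members, m)
    cj$offsets <- c(cj$offsets, b$offset)
    cj$strands <- c(cj$strands, b$strand)
    cj$counts <- .updateCounts(cj$counts, cpp_window(s, b$offset, b$strand,
                                                    ncol(cj$counts)), +1)
    clusters[[jstar]] <- cj
    # positions shift after removal: rebuild the index for cluster k
    sel <- who == k & pos > p
    pos[sel] <- pos[sel] - 1L
    if (jstar != k) moved <- moved + 1L
  }
  clusters <- clusters[vapply(clusters, .clusterSize, integer(1)) > 0L]
  list(clusters = clusters, examined = nConsider, moved = moved)
}

# Significance closure: the split criterion, applied in reverse.  Two
# clusters whose division does not reach the split-LLR threshold are not
# significantly different, so they are joined again -- this dissolves
# duplicate clusters that arise when the pooled inconsistent sequences
# re-split into a motif that already has a cluster.  Pairs are merged
# worst-first until every remaining pair is significantly distinct.
.significanceMerge <- function(clusters, params) {
  c0 <- params@pseudocount
  merges <- 0L
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    lp <- vapply(clusters, function(cl) clusterLogProb(cl$counts, c0),
                 numeric(1))
    worst <- NULL
    worstGap <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      llr <- lp[i] + lp[j] -
        clusterLogProb(clusters[[i]]$counts + clusters[[j]]$counts, c0)
      thr <- splitThreshold(.clusterSize(clusters[[i]]),
                            .clusterSize(clusters[[j]]),
                            ncol(clusters[[i]]$counts), c0,
                            params@splitT)$threshold
      if (llr - thr < worstGap) {
        worstGap <- llr - thr
        worst <- c(i, j)
      }
    }
    if (is.null(worst)) break
    ci <- clusters[[worst[1]]]
    cj <- clusters[[worst[2]]]
    clusters[[worst[1]]] <- list(members = c(ci$members, cj$members),
                                 offsets = c(ci$offsets, cj$offsets),
                                 strands = c(ci$strands, cj$strands),
                                 counts = ci$counts + cj$counts)
    clusters <- clusters[-worst[2]]
    merges <- merges + 1L
  }
  list(clusters = clusters, merges = merges)
}

# Merge clusters down to maxClusters by least likelihood loss:
# repeatedly join the pair maximizing logP(Ci u Cj) - logP(Ci) - logP(Cj).
# Members keep their window configurations.  Returns clusters plus Newick
# strings of the join trees (leaves named C<original index>).
.mergeToMax <- function(clusters, maxClusters, pseudocount) {
  labels <- paste0("C", seq_along(clusters))
  lp <- vapply(clusters, function(cl) clusterLogProb(cl$counts, pseudocount),
               numeric(1))
  while (length(clusters) > maxClusters) {
    k <- length(clusters)
    bestScore <- -Inf
    bi <- bj <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sc <- clusterLogProb(clusters[[i]]$counts + clusters[[j]]$counts,
                           pseudocount) - lp[i] - lp[j]
      if (sc > bestScore) {
        bestScore <- sc
        bi <- i
        bj <- j
      }
    }
    ci <- clusters[[bi]]
    cj <- clusters[[bj]]
    merged <- list(members = c(ci$members, cj$members),
                   offsets = c(ci$offsets, cj$offsets),
                   strands = c(ci$strands, cj$strands),
                   counts = ci$counts + cj$counts)
    newLabel <- paste0("(", labels[bi], ",", labels[bj], ")")
    clusters[[bi]] <- merged
    lp[bi] <- clusterLogProb(merged$counts, pseudocount)
    labels[bi] <- newLabel
    clusters <- clusters[-bj]
    lp <- lp[-bj]
    labels <- labels[-bj]
  }
  trees <- labels[grepl("\\(", labels)]
  list(clusters = clusters,
       dendrogram = if (length(trees)) paste0(trees, ";") else character(0))
}

#' Run the divisive hierarchical clustering
#'
#' Starts from a single cluster holding every sequence (centred forward
#' windows) and repeatedly attempts a significance-tested two-way split of
#' every current cluster.  Sequences that do not cluster consistently
#' across replicate splits are concatenated into one pool cluster per pass,
#' itself a split candidate in later passes.  After every two passes (when
#' more than two clusters exist) the poorest-scoring
#' `reassignFraction` of sequences are re-examined and moved to their best
#' cluster.  The run terminates when a full pass produces no accepted
#' splits and no reassignments; if more than `maxClusters` clusters remain
#' they are merged by least likelihood loss.  Fully deterministic for a
#' fixed `params@seed`.
#'
#' @param sequences A named `DNAStringSet` or named character vector of
#'   sequences over `{A,C,G,T,N}` (lowercase accepted).
#' @param params A [ClusterParams-class] object; `W = NA` resolves to
#'   `floor(median(length) / 3)`.
#' @return A [MotifClustering-class] object.
#' @examples
#' ds <- generateDataset(150, nMotifs = 2, dirichletC = 0.05, seed = 5)
#' res <- runClustering(ds$sequences, weedParams(W = 20L, seed = 5L))
#' nClusters(res)
#' @export
runClustering <- function(sequences, params = weedParams()) {
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- sprintf("seq_%05d", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  seqs <- .encodeSet(sequences)
  W <- params@W
  if (is.na(W)) W <- max(2L, as.integer(median(lengths(seqs)) %/% 3L))
  params@W <- W
  if (any(lengths(seqs) < ceiling(W / 2)))
    stop("every sequence must be at least ceiling(W/2) bp long")
  set.seed(params@seed)

  n <- length(seqs)
  offs <- vapply(seqs, function(s) (length(s) - W) %/% 2L, integer(1))
  clusters <- list(.newCluster(seqs, seq_len(n), offs, rep(1L, n), W))
  log <- list()
  passes <- 0L
  repeat {
    passes <- passes + 1L
    nsplits <- 0L
    nxt <- list()
    poolM <- integer(0)
    poolO <- integer(0)
    poolS <- integer(0)
    for (cl in clusters) {
      res <- if (.clusterSize(cl) >= params@minSplitSize)
        .attemptSplit(seqs, cl, params) else list(accepted = FALSE)
      if (isTRUE(res$accepted)) {
        nsplits <- nsplits + 1L
        nxt <- c(nxt, list(res$child1, res$child2))
        poolM <- c(poolM, res$inconsistent)
        poolO <- c(poolO, res$inconOffsets)
        poolS <- c(poolS, res$inconStrands)
      } else {
        nxt <- c(nxt, list(cl))
      }
    }
    if (length(poolM)) {
      pool <- .newCluster(seqs, poolM, poolO, poolS, W)
      # the fresh pool gets an immediate split attempt so that mixed pools
      # are usually dissolved before the next reassignment step sees them
      rp <- if (.clusterSize(pool) >= params@minSplitSize)
        .attemptSplit(seqs, pool, params) else list(accepted = FALSE)
      if (isTRUE(rp$accepted)) {
        nsplits <- nsplits + 1L
        nxt <- c(nxt, list(rp$child1, rp$child2))
        if (length(rp$inconsistent))
          nxt <- c(nxt, list(.newCluster(seqs, rp$inconsistent,
                                         rp$inconOffsets, rp$inconStrands,
                                         W)))
      } else {
        nxt <- c(nxt, list(pool))
      }
    }
    clusters <- nxt
    if (length(clusters) > 1L) {
      sm <- .significanceMerge(clusters, params)
      clusters <- sm$clusters
    }
    examined <- 0L
    moved <- 0L
    if (passes %% 2L == 0L && length(clusters) > 2L) {
      rr <- .reassignPoorest(seqs, clusters, params)
      clusters <- rr$clusters
      examined <- rr$examined
      moved <- rr$moved
    }
    log[[passes]] <- data.frame(pass = passes, splits = nsplits,
                                examined = examined, moved = moved)
    if ((nsplits == 0L && moved == 0L) || passes >= params@maxPasses) break
  }

  dendro <- character(0)
  if (length(clusters) > params@maxClusters) {
    mg <- .mergeToMax(clusters, params@maxClusters, params@pseudocount)
    clusters <- mg$clusters
    dendro <- mg$dendrogram
  }

  ord <- order(-vapply(clusters, .clusterSize, integer(1)),
               vapply(clusters, function(cl) min(cl$members), integer(1)))
  clusters <- clusters[ord]
  ids <- names(sequences)
  asn <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(id = ids[cl$members], cluster = k, offset = cl$offsets,
               strand = c("+", "-")[cl$strands],
               logLik = as.numeric(.looScores(seqs, cl, params@pseudocount)),
               stringsAsFactors = FALSE)
  }))
  asn <- asn[order(match(asn$id, ids)), , drop = FALSE]
  rownames(asn) <- NULL
  new("MotifClustering",
      sequences = sequences, assignments = asn, params = params,
      passes = passes, passLog = do.call(rbind, log),
      clusterLogProb = vapply(clusters, function(cl)
        clusterLogProb(cl$counts, params@pseudocount), numeric(1)),
      dendrogram = dendro)
}
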