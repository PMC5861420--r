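#' Result of a divisive clustering run
#'
#' S4 container for the final partition of a [runClustering()] run.
#' The `assignments` table has one row per input sequence: `id`,
#' `cluster` (1-based, ordered by decreasing size), `offset` (0-based
#' window start, forward-strand coordinates of the input sequence),
#' `strand` (`"+"`/`"-"`) and `logLik` (leave-one-out window
#' log-likelihood in its cluster, nats).
#'
#' @slot sequences The input `DNAStringSet`.
#' @slot assignments Per-sequence assignment `data.frame` (see above).
#' @slot params The [ClusterParams-class] used (with `W` resolved).
#' @slot passes Number of top-level passes executed.
#' @slot passLog Per-pass `data.frame`: `pass`, `splits`, `examined`,
#'   `moved` (reassignment bookkeeping; `examined = 0` on passes where no
#'   reassignment step ran).
#' @slot clusterLogProb Numeric vector of per-cluster marginal
#'   log-probabilities (nats).
#' @slot dendrogram Character: Newick serializations of the merge trees
#'   produced when reducing to `maxClusters` (empty if no merging
#'   happened).  Leaf names refer to pre-merge cluster indices.
#' @aliases MotifClustering-class
#' @export
setClass("MotifClustering", representation(
  sequences = "DNAStringSet", assignments = "data.frame",
  params = "ClusterParams", passes = "integer", passLog = "data.frame",
  clusterLogProb = "numeric", dendrogram = "character"))

setValidity("MotifClustering", function(object) {
  asn <- object@assignments
  msg <- character(0)
  need <- c("id", "cluster", "offset", "strand", "logLik")
  if (!all(need %in% names(asn)))
    msg <- c(msg, "assignments must have columns id/cluster/offset/strand/logLik")
  else {
    if (anyDuplicated(asn$id))
      msg <- c(msg, "each sequence must be assigned exactly once")
    if (!setequal(asn$id, names(object@sequences)))
      msg <- c(msg, "assignments must cover exactly the input sequences")
    k <- length(object@clusterLogProb)
    if (length(unique(asn$cluster)) != k ||
        !all(sort(unique(asn$cluster)) == seq_len(k)))
      msg <- c(msg, "cluster ids must be 1..k with k = length(clusterLogProb)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifClustering-class Per-sequence assignment table.
#' @param x A `MotifClustering` object.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname MotifClustering-class
#' @export
setMethod("assignments", "MotifClustering", function(x) x@assignments)

#' @describeIn MotifClustering-class Number of clusters in the final state.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname MotifClustering-class
#' @export
setMethod("nClusters", "MotifClustering",
          function(x) length(x@clusterLogProb))

#' @describeIn MotifClustering-class Cluster sizes, largest first.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname MotifClustering-class
#' @export
setMethod("clusterSizes", "MotifClustering", function(x) {
  tab <- table(factor(x@assignments$cluster,
                      levels = seq_len(nClusters(x))))
  as.integer(tab)
})

#' @describeIn MotifClustering-class Per-pass split/reassignment log.
#' @export
setGeneric("passLog", function(x) standardGeneric("passLog"))

#' @rdname MotifClustering-class
#' @export
setMethod("passLog", "MotifClustering", function(x) x@passLog)

#' Aligned window strings of one cluster
#'
#' Rebuilds the N-padded, strand-resolved window strings of a cluster's
#' members from the stored assignments.
#'
#' @param x A [MotifClustering-class] object.
#' @param k Cluster index.
#' @return Named character vector of width-`W` window strings.
#' @export
clusterWindows <- function(x, k) {
  asn <- x@assignments[x@assignments$cluster == k, , drop = FALSE]
  if (nrow(asn) == 0L) stop("no such cluster: ", k)
  W <- x@params@W
  ch <- as.character(x@sequences[asn$id])
  out <- mapply(function(s, off, st) extractWindow(s, off, st, W),
                ch, asn$offset, asn$strand)
  names(out) <- asn$id
  out
}

#' Count or frequency matrix of one cluster
#'
#' @param x A [MotifClustering-class] object.
#' @param k Cluster index.
#' @param type `"counts"` for the raw 5 x W count matrix, `"prob"` for the
#'   4 x W posterior-mean frequencies `(n + c) / (N_i + 4c)`.
#' @return A numeric matrix.
#' @export
clusterMotif <- function(x, k, type = c("prob", "counts")) {
  type <- match.arg(type)
  counts <- countMatrix(clusterWindows(x, k))
  if (type == "counts") return(counts)
  c0 <- x@params@pseudocount
  base <- counts[2:5, , drop = FALSE]
  sweep(base + c0, 2, colSums(base) + 4 * c0, "/")
}

setMethod("show", "MotifClustering", function(object) {
  sz <- clusterSizes(object)
  cat("MotifClustering:", length(object@sequences), "sequences in",
      nClusters(object), "clusters (W =", object@params@W, "bp)\n")
  cat("  sizes:", paste(sz, collapse = ", "), "\n")
  cat("  passes:", object@passes, "\n")
  invisible(NULL)
})
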