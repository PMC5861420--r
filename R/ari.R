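# Adjusted Rand index and label matching for comparing partitions:
# used both inside the split reproducibility test and for benchmark
# evaluation against known labels.

.alignLabelings <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)) || anyDuplicated(names(a)) ||
        anyDuplicated(names(b)))
      stop("labelings must cover the same item universe exactly once")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("labelings must cover the same item universe")
  }
  list(a = as.vector(a), b = as.vector(b))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table: `(Index - ExpectedIndex) / (MaxIndex - ExpectedIndex)`.  1.0 for
#' identical partitions (up to label permutation); approximately 0 for
#' independent random labelings.  In the degenerate case where the
#' correction denominator vanishes (e.g. both partitions are a single
#' cluster) the value is 1.0 if the partitions are identical and 0.0
#' otherwise.
#'
#' @param a,b Label vectors over the same items; if both are named the
#'   names define the item universe and order is irrelevant.
#' @return The adjusted Rand index (a number `<= 1`).
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))          # -0.5
#' @export
adjustedRandIndex <- function(a, b) {
  al <- .alignLabelings(a, b)
  tab <- table(al$a, al$b)
  n <- length(al$a)
  sumnij <- sum(choose(tab, 2))
  suma <- sum(choose(rowSums(tab), 2))
  sumb <- sum(choose(colSums(tab), 2))
  expix <- suma * sumb / choose(n, 2)
  maxix <- (suma + sumb) / 2
  if (abs(maxix - expix) < .Machine$double.eps * max(1, maxix)) {
    identicalPartition <- all(rowSums(tab > 0) == 1) &&
      all(colSums(tab > 0) == 1)
    return(if (identicalPartition) 1.0 else 0.0)
  }
  (sumnij - expix) / (maxix - expix)
}

#' Match cluster labels of one partition to another
#'
#' Maximum-overlap matching of `b`'s labels onto `a`'s.  For up to six
#' labels on each side the optimum assignment is found exhaustively (the
#' relevant regime for replicate-split matching and benchmark reporting);
#' larger label sets fall back to greedy maximum-overlap pairing.  Both
#' routes break ties deterministically by label order.  Surplus `b` labels
#' (when `b` has more clusters than `a`) map to `NA`.
#'
#' @param a,b Label vectors over the same items (see
#'   [adjustedRandIndex()] for universe rules).
#' @return Named vector: names are `b`'s labels, values the matched `a`
#'   labels.
#' @examples
#' matchLabels(c(1, 1, 2, 2), c(2, 2, 1, 1))  # swap map
#' @export
matchLabels <- function(a, b) {
  al <- .alignLabelings(a, b)
  tab <- table(al$a, al$b)
  aLabs <- rownames(tab)
  bLabs <- colnames(tab)
  map <- rep(NA_character_, length(bLabs))
  names(map) <- bLabs
  ka <- length(aLabs)
  kb <- length(bLabs)
  m <- min(ka, kb)
  if (max(ka, kb) <= 6L) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(perms(v[-i]), function(r) c(v[i], r)))
      out
    }
    best <- -1
    if (ka >= kb) {
      for (p in perms(seq_len(ka))) {
        sc <- sum(tab[cbind(p[seq_len(m)], seq_len(m))])
        if (sc > best) {
          best <- sc
          map[seq_len(m)] <- aLabs[p[seq_len(m)]]
        }
      }
    } else {
      for (q in perms(seq_len(kb))) {
        sc <- sum(tab[cbind(seq_len(m), q[seq_len(m)])])
        if (sc > best) {
          best <- sc
          map[] <- NA_character_
          map[q[seq_len(m)]] <- aLabs[seq_len(m)]
        }
      }
    }
    return(map)
  }
  free_a <- rep(TRUE, ka)
  free_b <- rep(TRUE, kb)
  for (k in seq_len(m)) {
    sub <- tab
    sub[!free_a, ] <- -1
    sub[, !free_b] <- -1
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    map[bLabs[best[2]]] <- aLabs[best[1]]
    free_a[best[1]] <- FALSE
    free_b[best[2]] <- FALSE
  }
  map
}

#' Evaluate a clustering result against known labels
#'
#' Converts a [MotifClustering-class] result to a labeling (every cluster,
#' including any pool cluster, is its own label) and returns the adjusted
#' Rand index against the ground-truth labels.
#'
#' @param predicted A [MotifClustering-class] object.
#' @param truth Data frame with columns `id` and `label` (as written by
#'   [writeDataset()]), or a named label vector.
#' @return The adjusted Rand index.
#' @export
evaluateVsTruth <- function(predicted, truth) {
  if (!is(predicted, "MotifClustering"))
    stop("predicted must be a MotifClustering object")
  asn <- assignments(predicted)
  pred <- asn$cluster
  names(pred) <- asn$id
  if (is.data.frame(truth)) {
    if (!all(c("id", "label") %in% names(truth)))
      stop("truth data frame needs columns 'id' and 'label'")
    tr <- truth$label
    names(tr) <- truth$id
  } else {
    tr <- truth
  }
  if (!setequal(names(pred), names(tr)))
    stop("truth does not cover the same sequences as the prediction")
  adjustedRandIndex(pred, tr)
}
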