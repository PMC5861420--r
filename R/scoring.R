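# Dirichlet-multinomial scoring of clusters of aligned windows.
#
# A cluster of M fixed-width windows is summarized by a 5 x W count matrix
# (rows N, A, C, G, T).  The probability of the cluster under a single-PWM
# model, marginalized over the PWM with a symmetric Dirichlet(c) prior, is
# computed column-wise with log-gamma arithmetic.  N's (padding of windows
# overhanging the sequence, or masked bases) are uninformative: each
# contributes a flat factor 1/4 and is excluded from the informative counts
# and from the column totals, which keeps the identity
# logP(C + S) - logP(C) = per-window log-likelihood exact.

.ROWNAMES <- c("N", "A", "C", "G", "T")

.checkCounts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (nrow(counts) == 4L)          # no-N convenience form
    counts <- rbind(N = 0, counts)
  if (nrow(counts) != 5L)
    stop("counts must have 4 (A,C,G,T) or 5 (N,A,C,G,T) rows")
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts) <- .ROWNAMES
  counts
}

#' Build a count matrix from aligned window strings
#'
#' @param windows Character vector of equal-length windows over
#'   `{A,C,G,T,N}`.
#' @return A 5 x W numeric matrix with rows `N, A, C, G, T`; column sums of
#'   the `A..T` rows are the informative totals `N_i`.
#' @examples
#' countMatrix(c("ACGT", "ACGA"))
#' @export
countMatrix <- function(windows) {
  if (length(windows) == 0L) stop("no windows given")
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("windows must all have the same width")
  counts <- matrix(0, 5L, W, dimnames = list(.ROWNAMES, NULL))
  for (w in windows) {
    code <- .encodeSeq(w)
    idx <- cbind(code + 1L, seq_len(W))
    counts[idx] <- counts[idx] + 1
  }
  counts
}

#' Marginal log-probability of a cluster of windows
#'
#' Log-probability that all windows in the cluster were drawn from one
#' (unknown) position weight matrix, marginalized over the PWM with a
#' symmetric Dirichlet prior of pseudocount `c`:
#' `sum_i [ sum_a lgamma(n_ia + c) + lgamma(4c) - lgamma(N_i + 4c)
#' - 4 lgamma(c) ]`, plus `log(1/4)` for every `N` in the cluster.  A
#' single-window cluster scores `W * log(1/4)` regardless of composition;
#' an empty matrix scores 0.
#'
#' @param counts Count matrix (4 or 5 rows, see [countMatrix()]).
#' @param pseudocount Dirichlet pseudocount `c` (> 0).
#' @return Log-probability in nats.
#' @examples
#' clusterLogProb(countMatrix("ACGT"))  # 4 * log(1/4)
#' @export
clusterLogProb <- function(counts, pseudocount = 0.5) {
  counts <- .checkCounts(counts)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  c0 <- pseudocount
  W <- ncol(counts)
  base <- counts[2:5, , drop = FALSE]
  tot <- colSums(base)
  sum(lgamma(base + c0)) + W * lgamma(4 * c0) - sum(lgamma(tot + 4 * c0)) -
    4 * W * lgamma(c0) + sum(counts[1L, ]) * log(0.25)
}

#' Log-likelihood of one window under a cluster's predictive distribution
#'
#' Posterior-predictive probability that window `S` was sampled from the
#' same PWM as the cluster: `sum_i log((n_i,S_i + c) / (N_i + 4c))`.
#' Positions where `S_i = N` contribute `log(1/4)`.  The counts must not
#' include the window being scored (remove it first).
#'
#' @param window A single window string, same width as `counts`.
#' @param counts Count matrix (4 or 5 rows).
#' @param pseudocount Dirichlet pseudocount `c`.
#' @return Log-likelihood in nats.
#' @examples
#' seqLogLikelihood("A", countMatrix(c("A", "A", "A")))  # log(3.5/5)
#' @export
seqLogLikelihood <- function(window, counts, pseudocount = 0.5) {
  counts <- .checkCounts(counts)
  code <- .encodeSeq(window)
  if (length(code) != ncol(counts))
    stop("window width does not match counts")
  c0 <- pseudocount
  tot <- colSums(counts[2:5, , drop = FALSE])
  sc <- ifelse(code == 0L, log(0.25),
               log(counts[cbind(code + 1L, seq_along(code))] + c0) -
                 log(tot + 4 * c0))
  sum(sc)
}

#' Extract a window from a sequence
#'
#' Returns the `W` residues starting at 0-based `offset` on the chosen
#' strand; positions falling outside the sequence are filled with `N`.
#' The reverse-strand window is the reverse complement of the forward
#' extraction at the mirrored offset `L - W - offset`.  A configuration is
#' admissible only if at least `ceiling(W/2)` window positions overlap the
#' sequence.
#'
#' @param seq A nucleotide string.
#' @param offset 0-based window start (may be negative).
#' @param strand `"+"` or `"-"`.
#' @param W Window width.
#' @return A window string of width `W`.
#' @examples
#' extractWindow("ACGTACGT", 2, "+", 4)   # "GTAC"
#' extractWindow("ACGT", -2, "+", 4)      # "NNAC"
#' @export
extractWindow <- function(seq, offset, strand = "+", W) {
  code <- .encodeSeq(seq)
  L <- length(code)
  ov <- min(L, offset + W) - max(0L, offset)
  if (ov < ceiling(W / 2))
    stop("inadmissible window: fewer than ceiling(W/2) positions overlap")
  st <- match(strand, c("+", "-"))
  if (is.na(st)) stop("strand must be '+' or '-'")
  .decodeSeq(cpp_window(code, as.integer(offset), st, as.integer(W)))
}

#' Admissible window offsets for a sequence length
#'
#' The 0-based window starts considered by the search:
#' `-floor(W/2) .. L - ceiling(W/2) - 1`, so that at least half the window
#' overlaps the sequence; with both strands this yields about `2 L`
#' configurations.  When `shifts = FALSE` only the single centred offset is
#' returned.
#'
#' @param L Sequence length (bp).
#' @param W Window width (bp).
#' @param shifts Allow shifted windows?
#' @return Integer vector of admissible offsets.
#' @export
windowOffsets <- function(L, W, shifts = TRUE) {
  cpp_offsets(as.integer(L), as.integer(W), isTRUE(shifts))
}

#' Best window placement of a sequence against a cluster
#'
#' Scans all admissible offsets and (optionally) both strands and returns
#' the configuration maximizing [seqLogLikelihood()] against the cluster
#' counts (which must exclude the sequence's own window).  Ties are broken
#' deterministically: smallest offset, forward before reverse.
#'
#' @param seq Nucleotide string.
#' @param counts Cluster count matrix (4 or 5 rows).
#' @param pseudocount Dirichlet pseudocount `c`.
#' @param allowShifts Search all offsets?
#' @param allowRevcomp Search the reverse strand?
#' @return A list with elements `offset`, `strand` (`"+"`/`"-"`) and
#'   `score` (nats).
#' @export
bestWindow <- function(seq, counts, pseudocount = 0.5, allowShifts = TRUE,
                       allowRevcomp = TRUE) {
  counts <- .checkCounts(counts)
  code <- .encodeSeq(seq)
  sm <- cpp_score_matrix(counts, pseudocount)
  b <- cpp_best_window(code, sm, isTRUE(allowShifts), isTRUE(allowRevcomp))
  list(offset = b$offset, strand = c("+", "-")[b$strand], score = b$score)
}

# Internal: add or remove one encoded window from a 5 x W count matrix.
.updateCounts <- function(counts, wcode, delta) {
  idx <- cbind(wcode + 1L, seq_along(wcode))
  counts[idx] <- counts[idx] + delta
  counts
}
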