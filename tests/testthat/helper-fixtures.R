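# Shared fixtures and independent oracles.  The oracles below deliberately
# avoid the package's compiled path: they work on character strings with
# base R only, so agreement with the package is a genuine cross-check.

BASES <- c("A", "C", "G", "T")

randSeq <- function(L, alphabet = BASES) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

randSeqs <- function(n, L) vapply(seq_len(n), function(i) randSeq(L), "")

# Independent reverse complement (lookup table, no package code).
oracleRevComp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Independent window extraction: explicit N padding, mirrored-offset
# reverse strand.
oracleExtract <- function(s, off, strand, W) {
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  grab <- function(o) {
    idx <- (o + 1):(o + W)
    out <- ifelse(idx >= 1 & idx <= L, chars[pmax(1, pmin(L, idx))], "N")
    paste(out, collapse = "")
  }
  if (strand == "+") grab(off) else oracleRevComp(grab(L - W - off))
}

# Independent Eq-2 scoring of a window string against a list of window
# strings (the cluster), via a from-scratch tally.
oracleSeqLL <- function(window, clusterWindows, c0 = 0.5) {
  W <- nchar(window)
  wc <- strsplit(window, "")[[1]]
  total <- 0
  for (i in seq_len(W)) {
    col <- vapply(clusterWindows, function(x) substr(x, i, i), "")
    if (wc[i] == "N") {
      total <- total + log(0.25)
    } else {
      n <- sum(col == wc[i])
      Ni <- sum(col %in% BASES)
      total <- total + log((n + c0) / (Ni + 4 * c0))
    }
  }
  total
}

# Brute-force window search: enumerate every admissible configuration on
# both strands and score with the oracle above.
oracleBestWindow <- function(s, clusterWindows, W, c0 = 0.5) {
  L <- nchar(s)
  offs <- seq(-floor(W / 2), L - ceiling(W / 2) - 1)
  best <- list(score = -Inf)
  for (off in offs) for (strand in c("+", "-")) {
    sc <- oracleSeqLL(oracleExtract(s, off, strand, W), clusterWindows, c0)
    if (sc > best$score)
      best <- list(offset = off, strand = strand, score = sc)
  }
  best
}

# Sequences with a fixed planted motif string at a fixed offset.
plantedSeqs <- function(n, L, motif, offset) {
  vapply(seq_len(n), function(i) {
    bg <- sample(BASES, L, replace = TRUE)
    bg[(offset + 1):(offset + nchar(motif))] <- strsplit(motif, "")[[1]]
    paste(bg, collapse = "")
  }, "")
}
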