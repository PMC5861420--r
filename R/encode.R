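# Internal integer encoding of sequences: 0 = N, 1 = A, 2 = C, 3 = G, 4 = T.
# All compiled kernels work on this encoding; conversion happens once per
# run at the API boundary.

.CODE2CHAR <- c("N", "A", "C", "G", "T")

.encodeSeq <- function(x) {
  v <- utf8ToInt(x)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  bad <- !(v %in% c(65L, 67L, 71L, 78L, 84L))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(intToUtf8(v[bad], multiple = TRUE)), collapse = ","))
  out
}

.decodeSeq <- function(code) {
  paste(.CODE2CHAR[code + 1L], collapse = "")
}

# DNAStringSet (or character) -> list of integer vectors, preserving names.
.encodeSet <- function(seqs) {
  ch <- if (is(seqs, "XStringSet")) as.character(seqs) else as.character(seqs)
  lapply(ch, .encodeSeq)
}

#' Reverse complement of nucleotide strings
#'
#' Watson-Crick complement, reversed; `N` is its own complement.  Vectorized
#' over a character vector of sequences over the alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revComp(c("ACGT", "AAC", "ANT"))
#' @export
revComp <- function(x) {
  if (!is.character(x)) stop("x must be a character vector")
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    if (!all(v %in% c(65L, 67L, 71L, 78L, 84L)))
      stop("sequence contains characters outside {A,C,G,T,N}")
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}
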