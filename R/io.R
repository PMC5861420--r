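#' Read peak-region sequences from a FASTA file
#'
#' Standard multi-record FASTA (wrapped or unwrapped lines).  Record ids
#' are the header tokens up to the first whitespace; residues are
#' uppercased.  Characters outside `{A,C,G,T,N}` either abort the read
#' (`ambiguous = "error"`) or are mapped to `N` (`ambiguous = "mask"`).
#' Optionally, sequences whose masked (`N`) fraction exceeds
#' `dropMaskedOver` are removed (repeat-masked regions are typically
#' filtered upstream of motif analysis).
#'
#' @param path Path to a FASTA file.
#' @param ambiguous `"error"` or `"mask"`.
#' @param dropMaskedOver Optional fraction in (0, 1]; sequences with a
#'   larger `N` fraction are dropped (with a message).
#' @return A named `DNAStringSet`.
#' @export
readPeakFasta <- function(path, ambiguous = c("error", "mask"),
                          dropMaskedOver = NULL) {
  ambiguous <- match.arg(ambiguous)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(raw), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path)
  ch <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", ch)
  if (any(bad)) {
    if (ambiguous == "error")
      stop(sum(bad), " sequence(s) contain characters outside {A,C,G,T,N}")
    ch <- gsub("[^ACGTN]", "N", ch)
  }
  if (any(nchar(ch) == 0L)) stop("empty sequence record in ", path)
  if (!is.null(dropMaskedOver)) {
    nfrac <- vapply(ch, function(s)
      mean(strsplit(s, "")[[1]] == "N"), numeric(1), USE.NAMES = FALSE)
    keep <- nfrac <= dropMaskedOver
    if (!all(keep))
      message("dropping ", sum(!keep), " sequence(s) with masked fraction > ",
              dropMaskedOver)
    ch <- ch[keep]
    ids <- ids[keep]
    if (length(ch) == 0L) stop("all sequences dropped by the mask filter")
  }
  out <- Biostrings::DNAStringSet(ch)
  names(out) <- ids
  out
}

.writeMeme <- function(x, path) {
  c0 <- x@params@pseudocount
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", "",
               paste0("# frequencies are posterior means with pseudocount ",
                      c0)), con)
  for (k in seq_len(nClusters(x))) {
    pf <- clusterMotif(x, k, type = "prob")
    nsites <- sum(x@assignments$cluster == k)
    writeLines(c("", paste0("MOTIF cluster_", k),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(pf), nsites)), con)
    writeLines(apply(pf, 2, function(col) {
      r <- round(col, 6)
      i <- which.max(r)
      r[i] <- 1 - sum(r[-i])   # printed row sums to exactly 1
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
  }
  invisible(path)
}

#' Write the results of a clustering run
#'
#' Writes into `outdir`:
#' \describe{
#'   \item{assignments.tsv}{sequence id, cluster, window offset (0-based,
#'     forward-strand coordinates), strand, window log-likelihood.}
#'   \item{motifs.meme}{per-cluster position-frequency matrices in MEME
#'     minimal motif format (posterior-mean frequencies with the model's
#'     pseudocount; one motif per cluster, `nsites` = cluster size).}
#'   \item{cluster_<k>.fasta}{the aligned (N-padded, strand-resolved)
#'     window strings of each cluster.}
#'   \item{summary.json}{parameters, seed, pass log, per-cluster sizes and
#'     log-probabilities, merge dendrogram in Newick.}
#'   \item{run.log}{a short plain-text run log.}
#' }
#'
#' @param x A [MotifClustering-class] object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
writeResults <- function(x, outdir) {
  if (!is(x, "MotifClustering")) stop("x must be a MotifClustering object")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)

  asn <- x@assignments
  asn$logLik <- sprintf("%.6f", asn$logLik)
  write.table(asn, file.path(outdir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  .writeMeme(x, file.path(outdir, "motifs.meme"))

  for (k in seq_len(nClusters(x))) {
    w <- clusterWindows(x, k)
    ws <- Biostrings::DNAStringSet(w)
    Biostrings::writeXStringSet(ws, file.path(outdir,
                                              sprintf("cluster_%d.fasta", k)))
  }

  p <- x@params
  summary <- list(
    params = list(W = p@W, pseudocount = p@pseudocount, splitT = p@splitT,
                  ariThreshold = p@ariThreshold, maxClusters = p@maxClusters,
                  reassignFraction = p@reassignFraction,
                  initMoveFraction = p@initMoveFraction,
                  nSplitReps = p@nSplitReps, votesNeeded = p@votesNeeded,
                  allowShifts = p@allowShifts, allowRevcomp = p@allowRevcomp,
                  minSplitSize = p@minSplitSize, seed = p@seed),
    passes = x@passes,
    passLog = x@passLog,
    clusterSizes = clusterSizes(x),
    clusterLogProb = x@clusterLogProb,
    dendrogramNewick = as.list(x@dendrogram))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  writeLines(c(sprintf("divMotif run: %d sequences, W = %d bp, seed = %d",
                       length(x@sequences), p@W, p@seed),
               sprintf("passes: %d", x@passes),
               sprintf("clusters: %d (sizes %s)", nClusters(x),
                       paste(clusterSizes(x), collapse = ", "))),
             file.path(outdir, "run.log"))
  invisible(outdir)
}
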