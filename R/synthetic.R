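#' Synthetic position weight matrix with a sharp core and tapering flanks
#'
#' @slot prob 4 x `fullWidth` column-stochastic matrix (rows A, C, G, T).
#' @slot coreWidth Width of the sharply constrained core (bp).
#' @slot fullWidth Total motif width including flanks (bp).
#' @slot dirichletC Dirichlet hyperparameter of the core columns.
#' @slot hyper Per-column hyperparameters actually used (taper included).
#' @aliases SyntheticPWM-class
#' @export
setClass("SyntheticPWM", representation(
  prob = "matrix", coreWidth = "integer", fullWidth = "integer",
  dirichletC = "numeric", hyper = "numeric"))

setValidity("SyntheticPWM", function(object) {
  msg <- character(0)
  if (nrow(object@prob) != 4L || ncol(object@prob) != object@fullWidth)
    msg <- c(msg, "prob must be 4 x fullWidth")
  if (any(abs(colSums(object@prob) - 1) > 1e-8))
    msg <- c(msg, "columns must sum to 1")
  if (object@fullWidth < object@coreWidth)
    msg <- c(msg, "fullWidth must be >= coreWidth")
  if (any(object@hyper < object@dirichletC - 1e-12))
    msg <- c(msg, "flank hyperparameters must be >= the core hyperparameter")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticPWM", function(object) {
  cons <- c("A", "C", "G", "T")[apply(object@prob, 2, which.max)]
  cat("SyntheticPWM: core", object@coreWidth, "bp / full",
      object@fullWidth, "bp, Dirichlet c =", object@dirichletC, "\n")
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(NULL)
})

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Sample a synthetic core/flank PWM
#'
#' Core columns are drawn independently from a symmetric
#' Dirichlet(`dirichletC`); a low hyperparameter yields highly skewed
#' (sharp) columns, while 20 is nearly indistinguishable from uniform.
#' Flank columns taper geometrically from the core hyperparameter to
#' `flankHyper` = 20: the column at flank distance `j` of `f` flank columns
#' on its side uses hyperparameter `dirichletC * (20 / dirichletC)^(j/f)`,
#' so the outermost columns are essentially background.
#'
#' @param coreWidth Core width in bp (5-10).
#' @param fullWidth Full width in bp (10-20, `>= coreWidth`).
#' @param dirichletC Core Dirichlet hyperparameter (> 0).
#' @param flankHyper Hyperparameter reached at the outermost flank column.
#' @param seed Optional seed (restores the RNG state afterwards).
#' @return A [SyntheticPWM-class] object.
#' @examples
#' samplePWM(6, 20, 0.1, seed = 1)
#' @export
samplePWM <- function(coreWidth, fullWidth, dirichletC, flankHyper = 20,
                      seed = NULL) {
  coreWidth <- as.integer(coreWidth)
  fullWidth <- as.integer(fullWidth)
  if (coreWidth < 5L || coreWidth > 10L)
    stop("coreWidth must be in 5..10")
  if (fullWidth < 10L || fullWidth > 20L || fullWidth < coreWidth)
    stop("fullWidth must be in 10..20 and >= coreWidth")
  if (dirichletC <= 0) stop("dirichletC must be > 0")
  .withSeed(seed, {
    fl <- fullWidth - coreWidth
    left <- fl %/% 2L
    right <- fl - left
    taper <- function(f)
      if (f == 0L) numeric(0)
      else dirichletC * (flankHyper / dirichletC)^(seq_len(f) / f)
    hyper <- c(rev(taper(left)), rep(dirichletC, coreWidth), taper(right))
    prob <- vapply(hyper, function(a) {
      g <- rgamma(4, shape = a)
      while (sum(g) == 0) g <- rgamma(4, shape = a)  # guard tiny shapes
      g / sum(g)
    }, numeric(4))
    rownames(prob) <- c("A", "C", "G", "T")
    new("SyntheticPWM", prob = prob, coreWidth = coreWidth,
        fullWidth = fullWidth, dirichletC = dirichletC, hyper = hyper)
  })
}

.sampleInstance <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(pwm@fullWidth), function(i)
    sample(bases, 1L, prob = pwm@prob[, i]), character(1)), collapse = "")
}

#' Generate a synthetic mixed-motif benchmark dataset
#'
#' Emulates the benchmark construction: uniform-background sequences
#' (each base probability 0.25) of `seqLen` bp, each containing exactly one
#' motif instance sampled column-wise from one of `nMotifs` PWMs (chosen
#' according to `proportions`), placed uniformly at random so that it lies
#' wholly within the central `centralZone` bp, on a uniformly random
#' strand.  Ground truth records the motif label, planted 0-based offset
#' (forward coordinates) and strand of every sequence.
#'
#' @param nSeqs Number of sequences.
#' @param seqLen Sequence length in bp (default 100).
#' @param nMotifs Number of distinct motifs (2-5 in the benchmark design).
#' @param dirichletC Core Dirichlet hyperparameter shared by all motifs.
#' @param proportions Mixing proportions (recycled/normalized); default
#'   equal.
#' @param coreWidths,fullWidths Per-motif widths (scalars recycled);
#'   default: core drawn uniformly from 5-10, full from 10-20 (>= core).
#' @param centralZone Width of the central placement zone (default 40 bp).
#' @param seed Optional seed (restores the RNG state afterwards).
#' @return A list: `sequences` (named `DNAStringSet`), `truth`
#'   (`data.frame` with `id`, `label`, `offset`, `strand`), `pwms`
#'   (list of [SyntheticPWM-class]), `params`.
#' @examples
#' ds <- generateDataset(50, nMotifs = 2, dirichletC = 0.1, seed = 1)
#' head(ds$truth)
#' @export
generateDataset <- function(nSeqs, seqLen = 100L, nMotifs = 3L,
                            dirichletC = 0.1, proportions = NULL,
                            coreWidths = NULL, fullWidths = NULL,
                            centralZone = 40L, seed = NULL) {
  nSeqs <- as.integer(nSeqs)
  seqLen <- as.integer(seqLen)
  nMotifs <- as.integer(nMotifs)
  centralZone <- as.integer(centralZone)
  if (nSeqs < 1L) stop("nSeqs must be >= 1")
  if (centralZone > seqLen) stop("central zone wider than the sequence")
  if (is.null(proportions)) proportions <- rep(1, nMotifs)
  proportions <- rep_len(proportions, nMotifs)
  proportions <- proportions / sum(proportions)
  .withSeed(seed, {
    if (is.null(coreWidths)) coreWidths <- sample(5:10, nMotifs, TRUE)
    coreWidths <- rep_len(as.integer(coreWidths), nMotifs)
    if (is.null(fullWidths))
      fullWidths <- vapply(coreWidths, function(cw)
        sample(max(cw, 10L):20L, 1L), integer(1))
    fullWidths <- rep_len(as.integer(fullWidths), nMotifs)
    if (any(fullWidths > centralZone))
      stop("motif wider than the central placement zone")
    pwms <- lapply(seq_len(nMotifs), function(k)
      samplePWM(coreWidths[k], fullWidths[k], dirichletC))
    zoneStart <- (seqLen - centralZone) %/% 2L
    bases <- c("A", "C", "G", "T")
    labels <- sample.int(nMotifs, nSeqs, replace = TRUE, prob = proportions)
    strands <- sample(c("+", "-"), nSeqs, replace = TRUE)
    offsets <- integer(nSeqs)
    out <- character(nSeqs)
    for (s in seq_len(nSeqs)) {
      k <- labels[s]
      fw <- fullWidths[k]
      off <- zoneStart + sample.int(centralZone - fw + 1L, 1L) - 1L
      offsets[s] <- off
      bg <- sample(bases, seqLen, replace = TRUE)
      inst <- .sampleInstance(pwms[[k]])
      if (strands[s] == "-") inst <- revComp(inst)
      bg[(off + 1L):(off + fw)] <- strsplit(inst, "")[[1]]
      out[s] <- paste(bg, collapse = "")
    }
    ids <- sprintf("seq_%05d", seq_len(nSeqs))
    seqsSet <- Biostrings::DNAStringSet(out)
    names(seqsSet) <- ids
    list(sequences = seqsSet,
         truth = data.frame(id = ids, label = paste0("motif_", labels),
                            offset = offsets, strand = strands,
                            stringsAsFactors = FALSE),
         pwms = pwms,
         params = list(nSeqs = nSeqs, seqLen = seqLen, nMotifs = nMotifs,
                       dirichletC = dirichletC, proportions = proportions,
                       coreWidths = coreWidths, fullWidths = fullWidths,
                       centralZone = centralZone, seed = seed))
  })
}

#' Generate the timing-benchmark dataset
#'
#' 1000-bp uniform-background sequences, each carrying one length-10 motif
#' (core = full = 10 bp, Dirichlet hyperparameter 0.2), two motifs mixed in
#' 60:40 proportion.
#'
#' @param nSeqs Number of sequences (>= 2).
#' @param seed Optional seed.
#' @return Same structure as [generateDataset()].
#' @export
generateRuntimeSet <- function(nSeqs, seed = NULL) {
  if (nSeqs < 2L) stop("nSeqs must be >= 2")
  generateDataset(nSeqs, seqLen = 1000L, nMotifs = 2L, dirichletC = 0.2,
                  proportions = c(0.6, 0.4), coreWidths = 10L,
                  fullWidths = 10L, centralZone = 40L, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Writes `sequences.fasta`, `truth.tsv` (`id`, `label`, `offset`,
#' `strand`) and `manifest.json` (generator parameters) into `dir`.
#'
#' @param ds A dataset list from [generateDataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "truth.tsv")
  mj <- file.path(dir, "manifest.json")
  Biostrings::writeXStringSet(ds$sequences, fa)
  write.table(ds$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$params, mj, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(fasta = fa, truth = tsv, manifest = mj))
}

#' Read ground-truth labels
#'
#' @param path A TSV with at least columns `id` and `label` (as written by
#'   [writeDataset()]).
#' @return A `data.frame`.
#' @export
readTruth <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tr)))
    stop("truth file needs columns 'id' and 'label'")
  tr
}
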