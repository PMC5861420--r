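test_that("initial partition moves the ceiling of the best quarter", {
  set.seed(23)
  mkCluster <- function(M, L = 40, W = 12) {
    seqs <- lapply(randSeqs(M, L), divMotif:::.encodeSeq)
    offs <- rep((L - W) %/% 2L, M)
    list(seqs = seqs,
         cl = divMotif:::.newCluster(seqs, seq_len(M), offs, rep(1L, M), W))
  }
  for (M in c(100, 4, 37)) {
    f <- mkCluster(M)
    mem <- divMotif:::.initialPartition(f$seqs, f$cl, 0.5, 0.25)
    expect_equal(sum(mem == 2L), ceiling(0.25 * M))
    expect_equal(sum(mem == 1L), M - ceiling(0.25 * M))
  }
  # the moved set is exactly the top leave-one-out scorers
  f <- mkCluster(30)
  loo <- divMotif:::.looScores(f$seqs, f$cl, 0.5)
  mem <- divMotif:::.initialPartition(f$seqs, f$cl, 0.5, 0.25)
  expect_setequal(which(mem == 2L), order(loo, decreasing = TRUE)[1:8])
})

test_that("leave-one-out scores equal brute-force recomputation", {
  set.seed(29)
  W <- 8
  M <- 15
  wins <- randSeqs(M, W)
  seqs <- lapply(wins, divMotif:::.encodeSeq)
  cl <- divMotif:::.newCluster(seqs, seq_len(M), rep(0L, M), rep(1L, M), W)
  loo <- divMotif:::.looScores(seqs, cl, 0.5)
  for (m in seq_len(M))
    expect_equal(loo[m], oracleSeqLL(wins[m], wins[-m]), tolerance = 1e-9)
})

test_that("split threshold interpolates between clean one- and two-column anchors", {
  grid <- expand.grid(M1 = c(2, 10, 50, 300), M2 = c(2, 25, 400))
  for (i in seq_len(nrow(grid))) {
    a <- splitThreshold(grid$M1[i], grid$M2[i], W = 33)
    expect_gt(a$L2, a$L1)   # two clean columns always beat one
  }
  a0 <- splitThreshold(100, 100, 20, splitT = 1e-9)
  a1 <- splitThreshold(100, 100, 20, splitT = 1 - 1e-9)
  expect_equal(a0$threshold, a0$L1, tolerance = 1e-6)
  expect_equal(a1$threshold, a1$L2, tolerance = 1e-6)
  # strictly increasing in T
  ts <- seq(0.1, 0.9, by = 0.2)
  thr <- vapply(ts, function(tt)
    splitThreshold(60, 40, 33, splitT = tt)$threshold, numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("split threshold matches an independent column-wise evaluation", {
  # independent route: assemble the full idealized W-column matrices and
  # score them with the Dirichlet-multinomial marginal likelihood directly
  c0 <- 0.5
  W <- 12
  M <- 80
  h <- M / 2
  lpMat <- function(cols) {
    sum(lgamma(cols + c0)) + ncol(cols) * lgamma(4 * c0) -
      sum(lgamma(colSums(cols) + 4 * c0)) - 4 * ncol(cols) * lgamma(c0)
  }
  for (k in 1:2) {
    child1 <- cbind(matrix(rep(c(h / 2, h / 2, 0, 0), k), 4),
                    matrix(h / 4, 4, W - k))
    child2 <- cbind(matrix(rep(c(0, 0, h / 2, h / 2), k), 4),
                    matrix(h / 4, 4, W - k))
    parent <- child1 + child2
    Lk <- lpMat(child1) + lpMat(child2) - lpMat(parent)
    a <- splitThreshold(h, h, W, c0)
    expect_equal(if (k == 1) a$L1 else a$L2, Lk, tolerance = 1e-9)
  }
})

test_that("refinement separates two sharp planted motifs and is deterministic", {
  ds <- generateDataset(400, nMotifs = 2, dirichletC = 0.05,
                        coreWidths = 8, fullWidths = 16, seed = 31)
  p <- weedParams(W = 33L, seed = 31L)
  seqs <- divMotif:::.encodeSet(ds$sequences)
  init <- rep(1:2, length.out = 400)
  set.seed(31)
  r1 <- divMotif:::cpp_refine(seqs, seq_len(400), init,
                              rep(33L, 400), rep(1L, 400), 33L, 0.5,
                              TRUE, TRUE, 200L)
  set.seed(31)
  r2 <- divMotif:::cpp_refine(seqs, seq_len(400), init,
                              rep(33L, 400), rep(1L, 400), 33L, 0.5,
                              TRUE, TRUE, 200L)
  expect_identical(r1, r2)   # same seed, same fixed point
  truthLab <- ds$truth$label
  expect_gt(adjustedRandIndex(r1$membership, truthLab), 0.9)
})

test_that("identical sequences give no reproducible split", {
  seqs <- rep(paste(rep("ACGT", 10), collapse = ""), 40)
  r <- attemptSplit(seqs, weedParams(W = 16L, seed = 3L))
  expect_false(r$accepted)
})

test_that("a split on a single discriminating column is rejected as insignificant", {
  set.seed(37)
  L <- 33
  M <- 200
  seqs <- randSeqs(M, L)
  # force one clean column: half A/C, half G/T at position 17
  forced <- c(sample(c("A", "C"), M / 2, TRUE), sample(c("G", "T"), M / 2, TRUE))
  seqs <- vapply(seq_len(M), function(i) {
    s <- strsplit(seqs[i], "")[[1]]
    s[17] <- forced[i]
    paste(s, collapse = "")
  }, "")
  p <- weedParams(W = 33L, seed = 37L, allowShifts = FALSE,
                  allowRevcomp = FALSE)
  r <- attemptSplit(seqs, p)
  expect_false(r$accepted)
  if (!is.na(r$llr)) expect_lt(r$llr, r$threshold)
})

test_that("accepted splits on motif mixtures partition the parent", {
  ds <- generateDataset(300, nMotifs = 2, dirichletC = 0.05,
                        coreWidths = 8, fullWidths = 16, seed = 41)
  r <- attemptSplit(as.character(ds$sequences), weedParams(W = 33L, seed = 41L))
  expect_true(r$accepted)
  expect_true(all(r$replicateARIs > 0.2))
  expect_gte(r$llr, r$threshold)
  # every sequence is in child 1, child 2, or the inconsistent set (NA)
  expect_equal(length(r$membership), 300)
  expect_true(all(r$membership %in% c(1L, 2L, NA)))
  # children line up with the planted labels
  ok <- !is.na(r$membership)
  expect_gt(adjustedRandIndex(r$membership[ok], ds$truth$label[ok]), 0.9)
})

test_that("clusters below the minimum splittable size are never split", {
  seqs <- randSeqs(6, 40)
  r <- attemptSplit(seqs, weedParams(W = 12L, seed = 1L))
  expect_false(r$accepted)
  expect_match(r$reason, "minimum")
})

test_that("split acceptance increases with motif sharpness", {
  trials <- 6
  acc <- function(dc) {
    n <- 0
    for (i in seq_len(trials)) {
      ds <- generateDataset(400, nMotifs = 2, dirichletC = dc,
                            coreWidths = 8, fullWidths = 16, seed = 500 + i)
      r <- attemptSplit(as.character(ds$sequences),
                        weedParams(W = 33L, seed = 500L + i))
      n <- n + r$accepted
    }
    n
  }
  sharp <- acc(0.1)
  dull <- acc(0.5)
  expect_gte(sharp, dull)
  expect_gte(sharp, trials - 1)   # sharp mixtures nearly always split
})
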