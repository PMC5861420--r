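test_that("pure uniform-random input terminates with a single cluster", {
  set.seed(107)
  seqs <- randSeqs(300, 100)
  names(seqs) <- sprintf("r%03d", seq_along(seqs))
  res <- runClustering(seqs, weedParams(W = 33L, seed = 107L))
  expect_equal(nClusters(res), 1)
  expect_equal(clusterSizes(res), 300L)
})

test_that("the final state is a partition and is reproducible by seed", {
  ds <- generateDataset(250, nMotifs = 2, dirichletC = 0.05,
                        coreWidths = 8, fullWidths = 16, seed = 109)
  p <- weedParams(W = 25L, seed = 109L)
  r1 <- runClustering(ds$sequences, p)
  r2 <- runClustering(ds$sequences, p)
  expect_identical(assignments(r1), assignments(r2))
  asn <- assignments(r1)
  expect_setequal(asn$id, names(ds$sequences))       # no loss, no duplication
  expect_false(anyDuplicated(asn$id) > 0)
  expect_equal(sum(clusterSizes(r1)), 250L)
  expect_lte(r1@passes, 50L)
})

test_that("window width defaults to a third of the median sequence length", {
  ds <- generateDataset(60, nMotifs = 2, dirichletC = 0.3, seed = 113)
  res <- runClustering(ds$sequences, weedParams(seed = 113L))
  expect_equal(res@params@W, 33L)   # 100-bp input
})

test_that("reassignment moves a sequence planted in the wrong cluster", {
  set.seed(127)
  # two sharply distinct fixed motifs, no shifts: clusters are unambiguous
  m1 <- "AAAAAAAAAA"
  m2 <- "CCCCCCCCCC"
  s1 <- plantedSeqs(30, 20, m1, 5)
  s2 <- plantedSeqs(30, 20, m2, 5)
  seqs <- lapply(c(s1, s2), divMotif:::.encodeSeq)
  W <- 20L
  p <- weedParams(W = W, seed = 127L, allowShifts = FALSE,
                  allowRevcomp = FALSE, reassignFraction = 0.2)
  # cluster 1 holds one misplaced member of motif 2
  wrong <- 31L
  g1 <- c(1:30, wrong)
  g2 <- setdiff(31:60, wrong)
  cl1 <- divMotif:::.newCluster(seqs, g1, rep(0L, 31), rep(1L, 31), W)
  cl2 <- divMotif:::.newCluster(seqs, g2, rep(0L, 29), rep(1L, 29), W)
  rr <- divMotif:::.reassignPoorest(seqs, list(cl1, cl2), p)
  expect_gte(rr$moved, 1)
  homes <- vapply(rr$clusters, function(cl) wrong %in% cl$members, logical(1))
  expect_true(homes[2])   # the misplaced sequence went home
})

test_that("merging joins matching count profiles first and conserves membership", {
  set.seed(131)
  W <- 10L
  mk <- function(wins) {
    seqs <- lapply(wins, divMotif:::.encodeSeq)
    divMotif:::.newCluster(seqs, seq_along(seqs), rep(0L, length(seqs)),
                           rep(1L, length(seqs)), W)
  }
  polyA <- replicate(20, paste(rep("A", W), collapse = ""))
  polyC <- replicate(20, paste(rep("C", W), collapse = ""))
  clA1 <- mk(polyA)
  clA2 <- mk(polyA)
  clC <- mk(polyC)
  # identical profiles merge before disjoint ones
  mg <- divMotif:::.mergeToMax(list(clA1, clC, clA2), 2L, 0.5)
  expect_length(mg$clusters, 2)
  sizes <- sort(vapply(mg$clusters, divMotif:::.clusterSize, integer(1)))
  expect_equal(sizes, c(20L, 40L))
  expect_match(mg$dendrogram, "C1,C3|C3,C1")
  # total membership conserved
  expect_equal(sum(sizes), 60L)
  # no-op when already at or below the maximum
  mg2 <- divMotif:::.mergeToMax(list(clA1, clC), 5L, 0.5)
  expect_length(mg2$clusters, 2)
  expect_length(mg2$dendrogram, 0)
})

test_that("three planted motifs are recovered with high agreement", {
  ds <- generateDataset(900, nMotifs = 3, dirichletC = 0.05,
                        coreWidths = 8, fullWidths = 16, seed = 137)
  res <- runClustering(ds$sequences, weedParams(W = 33L, seed = 137L))
  expect_gte(nClusters(res), 3)
  ari <- evaluateVsTruth(res, ds$truth)
  expect_gt(ari, 0.8)
  # consensus of each major cluster matches a planted consensus
  tr <- ds$truth
  asn <- assignments(res)
  major <- which(clusterSizes(res) >= 100)
  for (k in major) {
    lab <- names(which.max(table(tr$label[match(
      asn$id[asn$cluster == k], tr$id)])))
    expect_gt(max(table(tr$label[match(asn$id[asn$cluster == k], tr$id)])) /
                sum(asn$cluster == k), 0.8)
  }
})
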