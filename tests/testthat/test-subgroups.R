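test_that("median split uses the strictly-greater rule", {
  s <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5), paste0("s", 1:5))
  sp <- splitByMedian(s)
  expect_identical(as.character(sp), c("low", "low", "low", "high", "high"))
  # exact tie with the median goes low; just above goes high
  expect_identical(as.character(splitByMedian(
    c(a = 0.55, b = 0.55, c = 0.56))), c("low", "low", "high"))
  expect_error(splitByMedian(c(a = 1, b = 1)), "degenerate")
})

test_that("Welch DE matches t.test and flags the planted shift", {
  set.seed(17)
  n <- 20
  X <- matrix(rnorm(6 * 2 * n), 6, 2 * n,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:(2 * n))))
  labels <- rep(c("high", "low"), each = n)
  X["g1", labels == "high"] <- X["g1", labels == "high"] * 0.01 + 3
  X["g1", labels == "low"] <- X["g1", labels == "low"] * 0.01
  de <- differentialExpression(X, labels)
  # per-gene agreement with the reference two-sample Welch test
  for (g in rownames(X)) {
    tt <- t.test(X[g, labels == "high"], X[g, labels == "low"])
    expect_equal(de$p[de$gene == g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[de$gene == g],
                 unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  expect_true(de$is_deg[de$gene == "g1"])
  expect_equal(sum(de$is_deg), 1L)
  expect_true(all(de$adj_p >= de$p))
})

test_that("label permutation on null data yields no DEGs", {
  bad <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 24), 50, 24,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:24)))
    de <- differentialExpression(X, rep(c("a", "b"), 12))
    if (sum(de$is_deg) > 0) bad <- bad + 1L
  }
  expect_lte(bad, 1L)
})

test_that("DEG count is monotone non-increasing in both thresholds", {
  set.seed(23)
  X <- matrix(rnorm(100 * 30, sd = 2), 100, 30,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  X[1:30, 1:15] <- X[1:30, 1:15] + rep(seq(0.5, 3.4, 0.1), 15)
  labels <- rep(c("high", "low"), each = 15)
  counts <- sapply(c(0.5, 1, 1.5, 2), function(l)
    sum(differentialExpression(X, labels, lfcThreshold = l)$is_deg))
  expect_true(all(diff(counts) <= 0))
  counts2 <- sapply(c(0.05, 0.01, 0.001), function(p)
    sum(differentialExpression(X, labels, pThreshold = p)$is_deg))
  expect_true(all(diff(counts2) <= 0))
})

test_that("consensus clustering recovers planted blobs with k = 2", {
  blob <- makeBlobMatrix()
  cc <- consensusCluster(blob$X, kRange = 2:5, reps = 200, seed = 13)
  expect_equal(chosenK(cc), 2L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(cc), blob$truth), 1)
  cm <- consensusMatrix(cc, 2)
  within <- c(cm[1:10, 1:10][upper.tri(diag(10))],
              cm[11:20, 11:20][upper.tri(diag(10))])
  expect_gte(min(within), 0.95)
  expect_lte(max(cm[1:10, 11:20]), 0.05)

  # a three-program fixture selects k = 3 under the same rule
  set.seed(5)
  pat <- matrix(0, 60, 3)
  pat[1:20, 1] <- 5; pat[21:40, 2] <- 5; pat[41:60, 3] <- 5
  X3 <- sapply(rep(1:3, each = 8), function(cl) pat[, cl] + rnorm(60))
  dimnames(X3) <- list(paste0("g", 1:60), paste0("s", 1:24))
  c3 <- consensusCluster(X3, kRange = 2:6, reps = 300, seed = 2)
  expect_equal(chosenK(c3), 3L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(c3),
                                         rep(1:3, each = 8)), 1)
})

test_that("consensus matrices are reproducible and respect duplicates", {
  blob <- makeBlobMatrix(nPerBlob = 6L)
  c1 <- consensusCluster(blob$X, kRange = 2:3, reps = 100, seed = 5)
  c2 <- consensusCluster(blob$X, kRange = 2:3, reps = 100, seed = 5)
  expect_identical(c1, c2)

  # a duplicated sample always co-clusters with its twin
  Xd <- cbind(blob$X, dup = blob$X[, 1])
  cd <- consensusCluster(Xd, kRange = 2:3, reps = 100, seed = 5)
  cm <- consensusMatrix(cd, 2)
  expect_equal(cm["s1", "dup"], 1)

  # doubling reps barely moves the consensus entries
  c4 <- consensusCluster(blob$X, kRange = 2:3, reps = 200, seed = 5)
  expect_lt(max(abs(consensusMatrix(c4, 2) - consensusMatrix(c1, 2))),
            0.05)
  expect_error(consensusCluster(blob$X, kRange = 2:50), "domain error")
})

test_that("association tests reproduce hand-computed chi-square values", {
  lab <- rep(c("high", "low"), c(20, 19))
  resp <- c(rep(c("responder", "non_responder"), c(10, 10)),
            rep(c("responder", "non_responder"), c(17, 2)))
  a <- associationTest(lab, resp)
  expect_equal(unname(a$perSubgroupP["high"]), 1)
  expect_equal(unname(a$perSubgroupP["low"]),
               pchisq((17 - 9.5)^2 / 9.5 * 2, 1, lower.tail = FALSE))
  expect_error(associationTest(lab, rep("x", 39)), "two levels")
})

test_that("Wilcoxon comparisons use Hommel adjustment faithfully", {
  set.seed(29)
  n <- 30
  X <- matrix(rnorm(5 * 2 * n), 5, 2 * n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:(2 * n))))
  resp <- rep(c("responder", "non_responder"), each = n)
  X["g1", resp == "non_responder"] <- X["g1", resp == "non_responder"] + 2
  res <- compareExpressionWilcoxon(X, rownames(X), resp)
  expect_lt(res$adj_p[res$gene == "g1"], 0.01)
  expect_equal(res$adj_p, closedTestingHommel(res$p), tolerance = 1e-12)

  # identical groups: maximal p
  Xi <- rbind(gSame = rep(c(1, 2, 3), 4))
  colnames(Xi) <- paste0("s", 1:12)
  ri <- compareExpressionWilcoxon(Xi, "gSame", rep(c("a", "b"), 6))
  expect_equal(ri$p, 1)
})
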