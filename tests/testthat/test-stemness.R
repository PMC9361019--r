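test_that("compendium centering removes per-gene reference means", {
  X <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  ctr <- centerByCompendium(X)
  expect_equal(unname(ctr$centered["g1", ]), c(-1, 0, 1))
  expect_equal(unname(ctr$centered["g2", ]), c(0, 0, 0))
  expect_lt(max(abs(rowMeans(ctr$centered))), 1e-12)
  expect_error(centerByCompendium(X[, 1, drop = FALSE]), "domain error")
})

test_that("OCLR returns exactly zero on training-subset-centered data", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  X <- X - rowMeans(X)       # centered on the training subset itself
  model <- trainOclr(X, l1 = 0.1, l2 = 1)
  expect_identical(stemnessWeights(model),
                   setNames(rep(0, 30), paste0("g", 1:30)))
})

test_that("one-gene OCLR solution matches the bisection root", {
  cval <- 1.7; l2 <- 0.8; n <- 5
  X <- matrix(rep(cval, n), nrow = 1,
              dimnames = list("g1", paste0("s", 1:n)))
  # stationarity: sigma(-w c) c = l2 w, root found by bisection
  f <- function(w) (1 / (1 + exp(w * cval))) * cval - l2 * w
  lo <- 0; hi <- cval / l2
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  model <- trainOclr(X, l1 = 0, l2 = l2, tol = 1e-10)
  expect_equal(unname(stemnessWeights(model)), (lo + hi) / 2,
               tolerance = 1e-8)
})

test_that("OCLR matches a slow proximal-gradient oracle on small problems", {
  for (l1 in c(0, 0.05)) {
    set.seed(21 + l1 * 100)
    X <- matrix(rnorm(20 * 12, mean = 0.3), 20, 12,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
    model <- trainOclr(X, l1 = l1, l2 = 1, tol = 1e-9)
    w <- unname(stemnessWeights(model))
    wOracle <- proxGradOclr(X, l1 = l1, l2 = 1)
    expect_lt(max(abs(w - wOracle)), 1e-4)
    expect_lt(oclrObjective(X, w, l1, 1) -
                oclrObjective(X, wOracle, l1, 1), 1e-8)
  }
})

test_that("OCLR learns positive weights for the planted program", {
  cfg <- simConfig(seed = 7)
  ref <- generateReferenceCompendium(cfg)
  ctr <- centerByCompendium(ref$expression)
  model <- trainOclr(ctr$centered[, ref$isStem], centeringMeans = ctr$means)
  w <- stemnessWeights(model)[ref$truth$stemnessGeneIds]
  expect_gte(mean(w > 0), 0.95)
})

test_that("Spearman scoring follows the closed form and the rank rules", {
  # weights ranked 1..4 against a sample ranked (1,2,4,3): rho = 0.8
  w <- c(0.1, 0.2, 0.3, 0.4)
  X <- cbind(sample1 = c(1, 2, 4, 3), sample2 = c(1, 2, 3, 4))
  rownames(X) <- paste0("g", 1:4)
  model <- new("StemnessModel", geneIds = rownames(X), weights = w,
               l1 = 0, l2 = 1, nTrain = 5L,
               centeringMeans = rep(0, 4), converged = TRUE,
               objective = 0)
  sc <- scoreMrnasi(model, X)
  expect_equal(unname(rawRho(sc)), c(0.8, 1))
  # the perfectly concordant sample is the cohort max: mrnasi = 1
  expect_equal(unname(mrnasi(sc)), c(0, 1))
})

test_that("mRNAsi is invariant under increasing per-sample transforms", {
  cfg <- simConfig(nGenes = 60, nStemnessGenes = 10, nCohort = 15, seed = 9)
  ref <- generateReferenceCompendium(cfg)
  coh <- generateTumorCohort(cfg, ref$truth)
  ctr <- centerByCompendium(ref$expression)
  model <- trainOclr(ctr$centered[, ref$isStem], centeringMeans = ctr$means)
  s1 <- scoreMrnasi(model, coh$expression)
  s2 <- scoreMrnasi(model, exp(coh$expression / 4) + 2)
  expect_equal(mrnasi(s1), mrnasi(s2), tolerance = 1e-12)
})

test_that("scoring requires gene overlap and a non-degenerate cohort", {
  model <- new("StemnessModel", geneIds = paste0("g", 1:10),
               weights = 1:10 / 10, l1 = 0, l2 = 1, nTrain = 3L,
               centeringMeans = rep(0, 10), converged = TRUE,
               objective = 0)
  X <- matrix(rnorm(8), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_error(scoreMrnasi(model, X), "compatibility error")
  Xc <- matrix(rep(1:10, 2), 10,
               dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_error(scoreMrnasi(model, Xc), "degenerate-cohort")
})

test_that("stronger planted effects widen the mRNAsi gap monotonically", {
  gaps <- vapply(c(0.5, 1.5, 3), function(eff) {
    cfg <- simConfig(nGenes = 100, nStemnessGenes = 20, nCohort = 60,
                     stemEffect = eff, seed = 31)
    ref <- generateReferenceCompendium(cfg)
    coh <- generateTumorCohort(cfg, ref$truth)
    ctr <- centerByCompendium(ref$expression)
    model <- trainOclr(ctr$centered[, ref$isStem],
                       centeringMeans = ctr$means)
    m <- mrnasi(scoreMrnasi(model, coh$expression))
    s <- coh$truth$latentStemness[names(m)]
    mean(m[s > median(s)]) - mean(m[s <= median(s)])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("gene-stemness correlations hit the exact extremes", {
  set.seed(5)
  n <- 20
  m <- runif(n)
  X <- rbind(gUp = m, gDown = -m, gConst = rep(1, n),
             gNoise = rnorm(n))
  colnames(X) <- paste0("s", 1:n)
  sc <- new("StemnessScores", sampleIds = colnames(X),
            rho = 2 * m - 1, mrnasi = (m - min(m)) / diff(range(m)))
  expect_warning(
    res <- correlateGenesWithStemness(X, sc,
                                      c("gUp", "gDown", "gConst")),
    "constant")
  expect_equal(res$rho[1:2], c(1, -1))
  expect_true(is.na(res$rho[3]))
})
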