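test_that("a perfectly correlated two-gene panel collapses to one component", {
  set.seed(61)
  v <- rnorm(20)
  X <- rbind(gA = v, gB = 2 * v + 5)
  colnames(X) <- paste0("s", 1:20)
  panel <- fitSignature(X, c("gA", "gB"))
  expect_equal(abs(signatureLoadings(panel)[, 1]),
               c(gA = 1, gB = 1) / sqrt(2), tolerance = 1e-10)
  ev <- panel@explainedVariance
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-10)
})

test_that("loadings match a direct eigendecomposition of the correlation", {
  set.seed(67)
  X <- matrix(rnorm(4 * 30), 4, 30,
              dimnames = list(defaultPanelGenes(), paste0("s", 1:30)))
  panel <- fitSignature(X)
  Z <- t((X - rowMeans(X)) / apply(X, 1, sd))
  eig <- eigen(cov(Z) * (29 / 30) * (30 / 29))   # sample covariance
  for (a in 1:2) {
    v <- eig$vectors[, a]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(signatureLoadings(panel)[, a]), v,
                 tolerance = 1e-8)
  }
  # determinism and the sign convention
  expect_identical(signatureLoadings(fitSignature(X)),
                   signatureLoadings(panel))
  expect_true(all(apply(signatureLoadings(panel), 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("projection centers the fitting cohort and its centroid", {
  set.seed(71)
  X <- matrix(rnorm(4 * 25, mean = 5), 4, 25,
              dimnames = list(defaultPanelGenes(), paste0("s", 1:25)))
  panel <- fitSignature(X)
  sc <- scoreSignature(panel, X)
  expect_lt(abs(mean(sc@dim1)), 1e-10)
  expect_lt(abs(mean(sc@dim2)), 1e-10)
  expect_equal(pparScore(sc), setNames(sc@dim1 + sc@dim2, sampleIds(sc)))

  centroid <- matrix(rowMeans(X), 4, 1,
                     dimnames = list(defaultPanelGenes(), "c1"))
  scC <- scoreSignature(panel, centroid)
  expect_equal(unname(pparScore(scC)), 0, tolerance = 1e-10)
  expect_error(scoreSignature(panel, X[1:3, ]), "compatibility error")
})

test_that("ROC fixtures match brute-force pair counting", {
  pos <- c(0.9, 0.8, 0.4); neg <- c(0.7, 0.3, 0.2)
  roc <- rocCurve(c(pos, neg),
                  rep(c("non_responder", "responder"), each = 3))
  expect_equal(roc$auc, 8 / 9)
  expect_equal(roc$auc, bruteForceAuc(pos, neg))

  # perfect separation
  rocP <- rocCurve(c(5, 6, 1, 2), c("non_responder", "non_responder",
                                    "responder", "responder"))
  expect_equal(rocP$auc, 1)
  expect_gt(rocP$optimalCutoff, 2)
  expect_lt(rocP$optimalCutoff, 5)
  expect_error(rocCurve(1:3, rep("responder", 3)), "domain error")
})

test_that("the chosen cutoff equals exhaustive threshold search", {
  set.seed(73)
  for (i in 1:5) {
    sc <- round(rnorm(40), 1)          # force ties
    lab <- ifelse(rbinom(40, 1, plogis(sc)) == 1, "non_responder",
                  "responder")
    if (length(unique(lab)) < 2) next
    roc <- rocCurve(sc, lab)
    pos <- sc[lab == "non_responder"]; neg <- sc[lab != "non_responder"]
    u <- sort(unique(sc))
    cand <- c(Inf, rev((u[-1] + u[-length(u)]) / 2), -Inf)
    d2 <- vapply(cand, function(t)
      (1 - mean(pos > t))^2 + mean(neg > t)^2, numeric(1))
    sens <- vapply(cand, function(t) mean(pos > t), numeric(1))
    best <- order(d2, -sens, cand)[1]
    expect_equal(roc$optimalCutoff, cand[best])
    # complement identity and agreement with the pROC reference
    expect_equal(roc$auc + rocCurve(-sc, lab)$auc, 1)
    refAuc <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(lab, sc, levels = c("responder", "non_responder"),
                direction = "<"))))
    expect_equal(roc$auc, refAuc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(79)
  sc <- rnorm(50)
  lab <- ifelse(rbinom(50, 1, plogis(2 * sc)) == 1, "non_responder",
                "responder")
  r1 <- rocCurve(sc, lab)$auc
  r2 <- rocCurve(exp(sc) + 3, lab)$auc
  expect_equal(r1, r2)
})

test_that("classification uses a strict cutoff and the published default", {
  sc <- new("SignatureScores", sampleIds = c("a", "b", "c"),
            dim1 = c(-0.56, -1, 1), dim2 = c(0, 0, 0),
            pparscore = c(-0.56, -1, 1), predicted = character())
  cls <- classifyResponse(sc)
  expect_identical(unname(predictedResponse(cls)),
                   c("responder", "responder", "non_responder"))
  expect_identical(classifyResponse(c(-2, -1)),
                   c("responder", "responder"))
  expect_identical(eval(formals(classifyResponse)$cutoff), -0.56)
})

test_that("the signature separates simulated response groups", {
  cfg <- simConfig(nGenes = 40, nStemnessGenes = 8, nCohort = 150, seed = 7)
  ref <- generateReferenceCompendium(cfg)
  coh <- generateTumorCohort(cfg, ref$truth)
  panel <- fitSignature(coh$expression)
  sc <- scoreSignature(panel, coh$expression)
  roc <- rocCurve(sc, coh$clinical$response)
  expect_gt(roc$auc, 0.8)

  # sign stability of the summed score under resampling
  set.seed(83)
  agree <- replicate(40, {
    idx <- sample(ncol(coh$expression), replace = TRUE)
    Xb <- coh$expression[, idx]
    colnames(Xb) <- paste0("b", seq_len(ncol(Xb)))
    pb <- fitSignature(Xb)
    sum(sign(signatureLoadings(pb)[, 1]) ==
          sign(signatureLoadings(panel)[, 1])) == 4
  })
  expect_gte(mean(agree), 0.95)
})
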