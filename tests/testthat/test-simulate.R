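test_that("identical config and seed give bit-identical outputs", {
  cfg <- simConfig(nGenes = 60, nStemnessGenes = 10, nStem = 8, nDiff = 10,
                   nCohort = 20, seed = 1)
  r1 <- generateReferenceCompendium(cfg)
  r2 <- generateReferenceCompendium(cfg)
  expect_identical(r1, r2)
  c1 <- generateTumorCohort(cfg, r1$truth)
  c2 <- generateTumorCohort(cfg, r2$truth)
  expect_identical(c1, c2)
  s1 <- generateGeneSets(cfg, c1$truth)
  s2 <- generateGeneSets(cfg, c2$truth)
  expect_identical(s1, s2)
})

test_that("reference compendium has the configured shape and labels", {
  cfg <- simConfig(nGenes = 80, nStemnessGenes = 15, nStem = 6, nDiff = 9,
                   seed = 3)
  ref <- generateReferenceCompendium(cfg)
  expect_equal(dim(ref$expression), c(80L, 15L))
  expect_equal(sum(ref$isStem), 6L)
  expect_setequal(ref$truth$stemnessGeneIds,
                  rownames(ref$expression)[1:15])
  expect_true(all(c("RXRB", "NR1H3", "CYP8B1", "SCD") %in%
                    rownames(ref$expression)))
})

test_that("zero stem effect leaves program genes at the null", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    cfg <- simConfig(nGenes = 80, nStemnessGenes = 30, nStem = 20,
                     nDiff = 20, stemEffect = 0, seed = seed)
    ref <- generateReferenceCompendium(cfg)
    for (g in ref$truth$stemnessGeneIds) {
      p <- t.test(ref$expression[g, ref$isStem],
                  ref$expression[g, !ref$isStem])$p.value
      total <- total + 1L
      if (p >= 0.01) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("planted program shift matches its configured mean", {
  cfg <- simConfig(nGenes = 500, nStemnessGenes = 50, stemEffect = 2,
                   noiseSd = 1, seed = 7)
  ref <- generateReferenceCompendium(cfg)
  d <- rowMeans(ref$expression[ref$truth$stemnessGeneIds, ref$isStem]) -
    rowMeans(ref$expression[ref$truth$stemnessGeneIds, !ref$isStem])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 2), 2 * se)
})

test_that("null response and survival links are calibrated", {
  # no response slope, no panel shift: latent stemness has no
  # discrimination for the response label
  cfg <- simConfig(nGenes = 30, nStemnessGenes = 5, nCohort = 500,
                   responseSlope = 0, responseIntercept = 0.8,
                   panelShift = 0, seed = 5)
  ref <- generateReferenceCompendium(cfg)
  coh <- generateTumorCohort(cfg, ref$truth)
  s <- coh$truth$latentStemness
  pos <- coh$truth$trueResponse == "non_responder"
  auc <- bruteForceAuc(s[pos], s[!pos])
  expect_gt(auc, 0.42)
  expect_lt(auc, 0.58)

  # no hazard effect: log-rank between latent-median halves rejects at
  # about the nominal rate
  rej <- 0L
  for (seed in 1:100) {
    cfg0 <- simConfig(nGenes = 10, nStemnessGenes = 3, nCohort = 60,
                      hazardCoef = 0, seed = seed)
    ref0 <- generateReferenceCompendium(cfg0)
    coh0 <- generateTumorCohort(cfg0, ref0$truth)
    grp <- coh0$truth$latentStemness >
      median(coh0$truth$latentStemness)
    lr <- logrankTest(coh0$clinical, ifelse(grp, "hi", "lo"))
    if (lr$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 10L)
})

test_that("the panel chain is Markov: G1 independent of G4 given G2, G3", {
  cfg <- simConfig(nGenes = 30, nStemnessGenes = 5, nCohort = 500,
                   chainCoefs = c(0.9, 0.9, 0.9), noiseSd = 0.3, seed = 2)
  ref <- generateReferenceCompendium(cfg)
  coh <- generateTumorCohort(cfg, ref$truth)
  p <- coh$expression[c("RXRB", "NR1H3", "CYP8B1", "SCD"), ]
  r1 <- residuals(lm(p[1, ] ~ p[2, ] + p[3, ]))
  r4 <- residuals(lm(p[4, ] ~ p[2, ] + p[3, ]))
  expect_lt(abs(cor(r1, r4)), 0.1)
})

test_that("gene sets contain the planted structure and round-trip as GMT", {
  cfg <- simConfig(nGenes = 100, nStemnessGenes = 10, seed = 4)
  ref <- generateReferenceCompendium(cfg)
  coh <- generateTumorCohort(cfg, ref$truth)
  sets <- generateGeneSets(cfg, coh$truth)
  expect_gte(length(sets), 10L)
  expect_true(all(lengths(sets) >= 5L))
  expect_setequal(sets$PPAR_LIKE,
                  c(coh$truth$panelGenes, coh$truth$stemnessGeneIds))
  expect_length(intersect(sets$NOISE_ONLY,
                          c(coh$truth$stemnessGeneIds,
                            coh$truth$panelGenes)), 0L)
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, f)
  back <- readGmt(f)
  expect_identical(unname(lapply(names(sets), function(n) back[[n]])),
                   unname(sets))
  # a set larger than the universe is rejected
  expect_error(generateGeneSets(cfg, coh$truth, randomSetSize = 1000),
               "configuration error")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nGenes = 1), "count >= 2")
  expect_error(simConfig(nGenes = 20, nStemnessGenes = 19), "nGenes - 4")
  expect_error(simConfig(noiseSd = 0), "noiseSd")
  expect_error(simConfig(chainCoefs = c(1, 2)), "chainCoefs")
  expect_error(
    generateTumorCohort(simConfig(), list(stemnessGeneIds = "g1")),
    "sequencing error")
})
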