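#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generators.
#' The defaults emulate, at desk scale, the statistical structure the
#' analysis assumes: a stem vs differentiated reference compendium with a
#' planted stemness gene program, a tumor cohort whose latent stemness drives
#' both a binary drug-response label and survival hazard, and a four-gene
#' linear-Gaussian regulatory chain (RXRB -> NR1H3 -> CYP8B1 -> SCD analogs)
#' whose root is shifted in non-responders.
#'
#' @param nGenes total number of genes (the last four are the chain panel).
#' @param nStem number of stem-labeled reference samples.
#' @param nDiff number of differentiated reference samples.
#' @param nStemnessGenes number of planted stemness-program genes.
#' @param stemEffect mean log2 shift of program genes in stem samples; in the
#'   cohort, program genes shift by `latent * stemEffect`.
#' @param nCohort tumor cohort size.
#' @param responseSlope logistic slope linking latent stemness to the
#'   probability of non-response.
#' @param responseIntercept logistic intercept; with the default slope it
#'   fixes the marginal non-response rate near 0.69, the rate observed in
#'   published sorafenib cohorts.
#' @param hazardCoef log-hazard coefficient of latent stemness.
#' @param baseHazard baseline exponential hazard per month.
#' @param censorRate fraction of cohort samples administratively censored.
#' @param chainCoefs three linear coefficients of the planted 4-gene chain.
#' @param panelShift mean shift applied to the chain root gene in
#'   non-responders (propagates down the chain).
#' @param noiseSd residual standard deviation on the log2 scale.
#' @param seed integer RNG seed; each generator operation derives its own
#'   stream from it, so identical configs are bit-reproducible.
#'
#' @return A validated list of class `"SimConfig"`.
#' @export
#'
#' @examples
#' cfg <- simConfig(nGenes = 200, nStemnessGenes = 20, seed = 1)
#' ref <- generateReferenceCompendium(cfg)
#' dim(ref$expression)
simConfig <- function(nGenes = 500L, nStem = 40L, nDiff = 60L,
                      nStemnessGenes = 50L, stemEffect = 2,
                      nCohort = 150L, responseSlope = 8,
                      responseIntercept = -2.4,
                      hazardCoef = 1.5, baseHazard = 0.02,
                      censorRate = 0.3,
                      chainCoefs = c(0.9, 0.9, 0.9),
                      panelShift = 1.5, noiseSd = 1, seed = 1L) {
  cfg <- list(
    nGenes = as.integer(nGenes), nStem = as.integer(nStem),
    nDiff = as.integer(nDiff), nStemnessGenes = as.integer(nStemnessGenes),
    stemEffect = stemEffect, nCohort = as.integer(nCohort),
    responseSlope = responseSlope, responseIntercept = responseIntercept,
    hazardCoef = hazardCoef, baseHazard = baseHazard,
    censorRate = censorRate, chainCoefs = as.numeric(chainCoefs),
    panelShift = panelShift, noiseSd = noiseSd, seed = as.integer(seed)
  )
  counts <- c("nGenes", "nStem", "nDiff", "nStemnessGenes", "nCohort")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 2L)
      stop("configuration error: ", nm, " must be a count >= 2")
  }
  # four gene slots are reserved for the regulatory-chain panel
  if (cfg$nStemnessGenes >= cfg$nGenes - 4L)
    stop("configuration error: nStemnessGenes must be < nGenes - 4")
  if (!is.finite(cfg$noiseSd) || cfg$noiseSd <= 0)
    stop("configuration error: noiseSd must be > 0")
  if (length(cfg$chainCoefs) != 3L || anyNA(cfg$chainCoefs))
    stop("configuration error: chainCoefs must be three finite values")
  if (cfg$censorRate < 0 || cfg$censorRate >= 1)
    stop("configuration error: censorRate must lie in [0, 1)")
  if (cfg$baseHazard <= 0)
    stop("configuration error: baseHazard must be > 0")
  class(cfg) <- "SimConfig"
  cfg
}

.panelGenes <- c("RXRB", "NR1H3", "CYP8B1", "SCD")

.simGeneIds <- function(cfg) {
  ids <- sprintf("g%04d", seq_len(cfg$nGenes))
  ids[(cfg$nGenes - 3L):cfg$nGenes] <- .panelGenes
  ids
}

#' Generate the stem-cell reference compendium
#'
#' Simulates a genes x (stem + differentiated) log2 expression matrix.
#' Per-gene baseline means are drawn once; the planted program genes are
#' shifted by `stemEffect` in stem-labeled samples; residuals are
#' i.i.d. Gaussian with sd `noiseSd`.
#'
#' @param config a [simConfig()] object.
#' @return A list with `expression` (matrix), `isStem` (named logical per
#'   sample) and `truth` (ground-truth list: `stemnessGeneIds`,
#'   `baselineMeans`, `panelGenes`, `trueChainEdges`).
#' @export
generateReferenceCompendium <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  geneIds <- .simGeneIds(cfg)
  programGenes <- geneIds[seq_len(cfg$nStemnessGenes)]
  n <- cfg$nStem + cfg$nDiff
  .withSeed(.opSeed(cfg$seed, "reference_compendium"), {
    mu <- stats::rnorm(cfg$nGenes, mean = 6, sd = 1.5)
    # program genes respond to the stemness program with one of two
    # magnitudes (strong/weak members, mean multiplier 1); without this
    # heterogeneity the program would be a uniform per-sample offset,
    # invisible to correlation-based sample distances
    effects <- sample(c(0.5, 1.5), cfg$nStemnessGenes, replace = TRUE)
    X <- mu + matrix(stats::rnorm(cfg$nGenes * n, sd = cfg$noiseSd),
                     nrow = cfg$nGenes, ncol = n)
    isStem <- rep(c(TRUE, FALSE), c(cfg$nStem, cfg$nDiff))
    X[seq_len(cfg$nStemnessGenes), isStem] <-
      X[seq_len(cfg$nStemnessGenes), isStem] + cfg$stemEffect * effects
    dimnames(X) <- list(geneIds,
                        sprintf("ref%03d", seq_len(n)))
    names(isStem) <- colnames(X)
    list(
      expression = X,
      isStem = isStem,
      truth = list(
        stemnessGeneIds = programGenes,
        programEffects = stats::setNames(effects, programGenes),
        baselineMeans = stats::setNames(mu, geneIds),
        panelGenes = .panelGenes,
        trueChainEdges = data.frame(
          from = .panelGenes[1:3], to = .panelGenes[2:4],
          stringsAsFactors = FALSE
        )
      )
    )
  })
}

#' Generate the tumor cohort
#'
#' Simulates a tumor cohort sharing the reference's gene universe. Each
#' sample carries a latent stemness value `s ~ Uniform(0,1)` that (i) shifts
#' the program genes by `s * stemEffect`, (ii) drives the probability of
#' sorafenib non-response through a logistic link, and (iii) scales the
#' exponential survival hazard as `baseHazard * exp(hazardCoef * s)`. The
#' four panel genes follow a linear-Gaussian chain whose root is mean-shifted
#' in non-responders, so the shift propagates along the chain and the
#' chain's Markov structure is preserved.
#'
#' @param config a [simConfig()] object.
#' @param truth ground truth from [generateReferenceCompendium()] (supplies
#'   the shared gene baselines).
#' @return A list with `expression` (genes x samples matrix), `clinical`
#'   (data.frame: sample_id, time_months, event, response) and `truth`
#'   (input truth extended with `latentStemness`, `trueResponse`,
#'   `trueCluster`).
#' @export
generateTumorCohort <- function(config, truth) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(truth$baselineMeans))
    stop("sequencing error: generate the reference compendium first")
  cfg <- config
  geneIds <- names(truth$baselineMeans)
  mu <- truth$baselineMeans
  nProg <- length(truth$stemnessGeneIds)
  n <- cfg$nCohort
  .withSeed(.opSeed(cfg$seed, "tumor_cohort"), {
    s <- stats::runif(n)
    X <- mu + matrix(stats::rnorm(cfg$nGenes * n, sd = cfg$noiseSd),
                     nrow = cfg$nGenes, ncol = n)
    eff <- truth$programEffects[truth$stemnessGeneIds]
    X[seq_len(nProg), ] <- X[seq_len(nProg), ] +
      outer(cfg$stemEffect * eff, s)
    nonResp <- stats::rbinom(
      n, 1L, .sigmoid(cfg$responseIntercept + cfg$responseSlope * s)
    ) == 1L
    # linear-Gaussian chain on the panel genes; root shifted in non-responders
    z <- matrix(0, nrow = 4L, ncol = n)
    z[1L, ] <- cfg$panelShift * nonResp + stats::rnorm(n, sd = cfg$noiseSd)
    for (k in 2:4) {
      z[k, ] <- cfg$chainCoefs[k - 1L] * z[k - 1L, ] +
        stats::rnorm(n, sd = cfg$noiseSd)
    }
    panelIdx <- match(truth$panelGenes, geneIds)
    X[panelIdx, ] <- mu[panelIdx] + z
    dimnames(X) <- list(geneIds, sprintf("tum%03d", seq_len(n)))

    eventTime <- stats::rexp(n, rate = cfg$baseHazard *
                               exp(cfg$hazardCoef * s))
    censored <- stats::rbinom(n, 1L, cfg$censorRate) == 1L
    obsTime <- eventTime
    obsTime[censored] <- stats::runif(sum(censored)) * eventTime[censored]
    clinical <- data.frame(
      sample_id = colnames(X),
      time_months = obsTime,
      event = as.integer(!censored),
      response = ifelse(nonResp, "non_responder", "responder"),
      stringsAsFactors = FALSE
    )
    truth$latentStemness <- stats::setNames(s, colnames(X))
    truth$trueResponse <- stats::setNames(clinical$response, colnames(X))
    truth$trueCluster <- stats::setNames(
      1L + as.integer(s > stats::median(s)), colnames(X)
    )
    list(expression = X, clinical = clinical, truth = truth)
  })
}

#' Generate gene-set collections
#'
#' Builds a GMT-writable gene-set collection: one "PPAR-like" set holding
#' the four panel genes plus the planted program genes, one set of pure
#' noise genes, and `nRandomSets` random sets.
#'
#' @param config a [simConfig()] object.
#' @param truth ground truth from the generators above.
#' @param nRandomSets number of random background sets (>= 8).
#' @param randomSetSize size of the noise and random sets (>= 5).
#' @return A named list of character vectors (gene sets); the planted set is
#'   named `"PPAR_LIKE"`, the noise set `"NOISE_ONLY"`.
#' @export
generateGeneSets <- function(config, truth, nRandomSets = 10L,
                             randomSetSize = 20L) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(truth$stemnessGeneIds)) stop("truth must be generated first")
  geneIds <- names(truth$baselineMeans)
  if (randomSetSize > length(geneIds))
    stop("configuration error: set size exceeds the gene universe")
  if (randomSetSize < 5L || nRandomSets < 8L)
    stop("configuration error: need >= 8 random sets of size >= 5")
  background <- setdiff(geneIds, c(truth$stemnessGeneIds, truth$panelGenes))
  .withSeed(.opSeed(config$seed, "gene_sets"), {
    sets <- list(
      PPAR_LIKE = c(truth$panelGenes, truth$stemnessGeneIds),
      NOISE_ONLY = sample(background, randomSetSize)
    )
    for (i in seq_len(nRandomSets)) {
      sets[[sprintf("RANDOM_%02d", i)]] <- sample(geneIds, randomSetSize)
    }
    sets
  })
}
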