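#' Run the full stemness analysis pipeline
#'
#' Orchestrates every stage end-to-end on simulated inputs: data generation,
#' OCLR training and mRNAsi scoring, median split, differential expression,
#' consensus clustering, subgroup-response association, ORA and preranked
#' GSEA, pathway- and gene-level bootstrap Bayesian networks, the PCA
#' response signature with its ROC cutoff, and mRNAsi-stratified survival.
#' Every output table is written to `outDir` together with a JSON manifest
#' recording parameters, the seed, and an md5 per file; re-running with the
#' same config reproduces byte-identical outputs.
#'
#' If fewer than `minClusterGenes` genes pass the DEG thresholds, the
#' clustering/enrichment gene list falls back to the `minClusterGenes`
#' smallest-p genes (logged in the manifest) so the downstream stages stay
#' exercised on weak-effect data.
#'
#' @param config a [simConfig()]; its seed drives every stage.
#' @param outDir output directory (created if needed).
#' @param l1,l2 OCLR penalties (defaults 0 and 1).
#' @param lfcThreshold,pThreshold DEG thresholds (defaults 1.5, 0.01).
#' @param consensusReps consensus-clustering repetitions (default 1000).
#' @param kRange candidate cluster counts (default 2:4).
#' @param gseaPerm GSEA permutations (default 1000).
#' @param bnGeneR bootstraps for the panel-gene network (default 200).
#' @param bnPathwayR bootstraps for the pathway network (default 50).
#' @param survivalCutoff mRNAsi threshold for survival strata (default 0.55).
#' @param horizon follow-up truncation in months (default 60).
#' @param minClusterGenes fallback gene-list size (default 50).
#' @return The manifest, invisibly (a named list).
#' @export
runFullPipeline <- function(config = simConfig(), outDir,
                            l1 = 0, l2 = 1,
                            lfcThreshold = 1.5, pThreshold = 0.01,
                            consensusReps = 1000L, kRange = 2:4,
                            gseaPerm = 1000L,
                            bnGeneR = 200L, bnPathwayR = 50L,
                            survivalCutoff = 0.55, horizon = 60,
                            minClusterGenes = 50L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "StemSig",
    version = as.character(utils::packageVersion("StemSig")),
    seed = config$seed,
    parameters = list(
      config = unclass(config), l1 = l1, l2 = l2,
      lfcThreshold = lfcThreshold, pThreshold = pThreshold,
      consensusReps = consensusReps, kRange = kRange,
      gseaPerm = gseaPerm, bnGeneR = bnGeneR, bnPathwayR = bnPathwayR,
      survivalCutoff = survivalCutoff, horizon = horizon,
      minClusterGenes = minClusterGenes
    ),
    log = list(), outputs = list()
  )
  out <- function(name, file) {
    manifest$outputs[[name]] <<- list(
      file = basename(file),
      md5 = unname(tools::md5sum(file)))
  }
  persist <- function() {
    jsonlite::write_json(
      manifest, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      manifest$log$failed_stage <<- name
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fp <- function(f) file.path(outDir, f)

  stage("simulate", {
    ref <- generateReferenceCompendium(config)
    cohort <- generateTumorCohort(config, ref$truth)
    sets <- generateGeneSets(config, cohort$truth)
    writeExpression(ref$expression, fp("reference_expression.tsv"))
    writeExpression(cohort$expression, fp("cohort_expression.tsv"))
    writeClinical(cohort$clinical, fp("clinical.tsv"))
    writeGmt(sets, fp("gene_sets.gmt"))
    jsonlite::write_json(
      cohort$truth[c("stemnessGeneIds", "panelGenes", "latentStemness",
                     "trueResponse", "trueCluster")],
      fp("ground_truth.json"), auto_unbox = FALSE, digits = NA)
    out("reference_expression", fp("reference_expression.tsv"))
    out("cohort_expression", fp("cohort_expression.tsv"))
    out("clinical", fp("clinical.tsv"))
    out("gene_sets", fp("gene_sets.gmt"))
    out("ground_truth", fp("ground_truth.json"))
  })

  stage("stemness", {
    ctr <- centerByCompendium(ref$expression)
    model <- trainOclr(ctr$centered[, ref$isStem, drop = FALSE],
                       l1 = l1, l2 = l2, centeringMeans = ctr$means)
    scores <- scoreMrnasi(model, cohort$expression)
    utils::write.table(
      data.frame(gene_id = model@geneIds, weight = model@weights,
                 centering_mean = ctr$means[model@geneIds]),
      fp("stemness_model.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sampleIds(scores), rho = scores@rho,
                 mrnasi = scores@mrnasi),
      fp("mrnasi_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out("stemness_model", fp("stemness_model.tsv"))
    out("mrnasi_scores", fp("mrnasi_scores.tsv"))
    manifest$log$n_train <- model@nTrain
  })

  stage("median_split", {
    split <- splitByMedian(scores)
    utils::write.table(
      data.frame(sample_id = names(mrnasi(scores)), split = as.character(split)),
      fp("median_split.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    out("median_split", fp("median_split.tsv"))
  })

  stage("differential_expression", {
    de <- differentialExpression(cohort$expression, split,
                                 lfcThreshold, pThreshold)
    utils::write.table(de, fp("differential_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out("differential_expression", fp("differential_expression.tsv"))
    degs <- de$gene[de$is_deg]
    manifest$log$n_degs <- length(degs)
    if (length(degs) < minClusterGenes) {
      degs <- de$gene[order(de$p)][seq_len(minClusterGenes)]
      manifest$log$deg_fallback <- TRUE
    }
  })

  stage("consensus_cluster", {
    cons <- consensusCluster(
      cohort$expression[degs, , drop = FALSE],
      kRange = kRange, reps = consensusReps, seed = config$seed)
    utils::write.table(
      data.frame(sample_id = names(clusterLabels(cons)),
                 cluster = clusterLabels(cons)),
      fp("consensus_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out("consensus_labels", fp("consensus_labels.tsv"))
    manifest$log$chosen_k <- chosenK(cons)
  })

  stage("association", {
    # collapse clusters to the two mRNAsi segments: a cluster is "high"
    # when its mean mRNAsi exceeds the cohort median (falls back to the
    # single most stem-like cluster if every mean lands on one side)
    mr <- mrnasi(scores)
    meanByCl <- tapply(mr[names(clusterLabels(cons))],
                       clusterLabels(cons), mean)
    hiCls <- as.integer(names(meanByCl)[meanByCl > stats::median(mr)])
    if (length(hiCls) == 0L || length(hiCls) == length(meanByCl))
      hiCls <- as.integer(names(which.max(meanByCl)))
    sub <- ifelse(clusterLabels(cons) %in% hiCls,
                  "mRNAsi_high", "mRNAsi_low")
    assoc <- associationTest(
      sub, cohort$clinical$response[
        match(names(clusterLabels(cons)), cohort$clinical$sample_id)])
    jsonlite::write_json(
      list(contingency = as.data.frame(assoc$contingency),
           per_subgroup_p = as.list(assoc$perSubgroupP),
           overall_p = assoc$overallP),
      fp("association.json"), auto_unbox = TRUE, digits = NA)
    out("association", fp("association.json"))
  })

  stage("enrichment", {
    ora <- oraHypergeometric(degs, rownames(cohort$expression), sets)
    utils::write.table(ora, fp("ora_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ranks <- stats::setNames(de$log2fc, de$gene)
    gsea <- gseaPreranked(ranks, sets, nPerm = gseaPerm,
                          seed = config$seed)
    utils::write.table(gsea, fp("gsea_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out("ora_results", fp("ora_results.tsv"))
    out("gsea_results", fp("gsea_results.tsv"))
  })

  stage("bayes_networks", {
    act <- suppressWarnings(pathwayActivity(cohort$expression, sets))
    utils::write.table(
      data.frame(pathway = rownames(act), act, check.names = FALSE),
      fp("pathway_activity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pathNet <- bootstrapNetwork(act, R = bnPathwayR,
                                seed = config$seed)
    utils::write.table(networkEdges(pathNet), fp("pathway_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    panel <- cohort$truth$panelGenes
    geneNet <- bootstrapNetwork(
      cohort$expression[panel, , drop = FALSE], R = bnGeneR,
      seed = config$seed)
    utils::write.table(networkEdges(geneNet), fp("gene_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out("pathway_activity", fp("pathway_activity.tsv"))
    out("pathway_network", fp("pathway_network.tsv"))
    out("gene_network", fp("gene_network.tsv"))
  })

  stage("signature", {
    panel <- fitSignature(cohort$expression,
                          cohort$truth$panelGenes)
    sig <- scoreSignature(panel, cohort$expression)
    roc <- rocCurve(sig, cohort$clinical$response[
      match(sampleIds(sig), cohort$clinical$sample_id)])
    sig <- classifyResponse(sig, cutoff = roc$optimalCutoff)
    jsonlite::write_json(
      list(genes = panel@geneIds, means = panel@means, sds = panel@sds,
           loadings = panel@loadings,
           explained_variance = panel@explainedVariance),
      fp("signature_panel.json"), digits = NA, matrix = "rowmajor")
    utils::write.table(
      data.frame(sample_id = sampleIds(sig), dim1 = sig@dim1,
                 dim2 = sig@dim2, pparscore = sig@pparscore,
                 predicted = sig@predicted),
      fp("signature_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
      fp("roc_curve.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    out("signature_panel", fp("signature_panel.json"))
    out("signature_scores", fp("signature_scores.tsv"))
    out("roc_curve", fp("roc_curve.tsv"))
    manifest$log$signature_auc <- roc$auc
    manifest$log$signature_cutoff <- roc$optimalCutoff
  })

  stage("survival", {
    clin <- cohort$clinical
    mr <- mrnasi(scores)[clin$sample_id]
    clin$mrnasi_group <- ifelse(mr > survivalCutoff, "high", "low")
    clin <- truncateFollowup(clin, horizon = horizon)
    km <- lapply(split(clin, clin$mrnasi_group), kmEstimate)
    for (g in names(km)) {
      f <- fp(sprintf("km_%s.tsv", g))
      utils::write.table(km[[g]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out(paste0("km_", g), f)
    }
    lr <- logrankTest(clin, clin$mrnasi_group)
    clin$mrnasi_high <- as.integer(clin$mrnasi_group == "high")
    clin$non_responder <- as.integer(clin$response == "non_responder")
    cox <- coxFit(clin, c("mrnasi_high", "non_responder"))
    utils::write.table(cox, fp("cox_fit.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out("cox_fit", fp("cox_fit.tsv"))
    manifest$log$logrank_p <- lr$p
  })

  persist()
  out("manifest", fp("manifest.json"))   # recorded for callers, post-write
  invisible(manifest)
}
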