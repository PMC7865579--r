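# End-to-end orchestration on synthetic data: simulate -> write/read RCC ->
# QC -> normalize -> integrate -> partition -> dictionary -> classify ->
# survival comparison, with a manifest recording seeds, parameters, and the
# per-stage attrition accounting.

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in order and returns all artifacts plus a manifest.
#' When `outputDir` is given, lanes are round-tripped through RCC files on
#' disk and every artifact is serialized (QC report, normalized matrix,
#' integrated matrix, dictionary, calls, survival comparison, manifest).
#' Any stage error halts the run with the stage name and cause.
#'
#' @param config A [SimulationConfig-class]; its defaults are the simulated
#'   study's conditions.
#' @param outputDir optional output directory.
#' @param nModels ensemble size for the dictionary.
#' @param threshold dictionary CV-accuracy filter.
#' @param withOutOfFold also compute out-of-fold calls on the reference
#'   (costly; off by default).
#' @return a bundle: list with `panel`, `truth`, `lanes`, `qc`,
#'   `normalized`, `integration`, `partition`, `dictionary`, `calls`,
#'   `survivalTable`, `comparison`, `manifest`.
#' @export
runPipeline <- function(config = SimulationConfig(), outputDir = NULL,
                        nModels = 1000L, threshold = 0.95,
                        withOutOfFold = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- defaultPanel(config)
  ref <- stage("simulate-reference", generateReference(config))
  tl <- stage("simulate-lanes", generateTestLanes(config, ref$truth))
  truth <- tl$truth
  lanes <- tl$lanes

  if (!is.null(outputDir)) {
    lane_dir <- file.path(outputDir, "lanes")
    stage("write-rcc", writeRccSet(lanes, lane_dir))
    lanes <- stage("read-rcc", readRccSet(lane_dir, panel = panel))
    lanes <- lanes[names(tl$lanes)] # restore generation order
  }

  qc <- stage("qc", qcLanes(lanes))
  passed <- qcPassed(qc)
  failed <- setdiff(vapply(lanes, laneSampleId, character(1)), passed)
  if (length(passed) < 2L)
    stop("pipeline stage 'qc' failed: fewer than 2 lanes passed QC")
  normalized <- stage("normalize",
                      normalizeLanes(lanes[passed], panel, qc = qc))

  integration <- stage("integrate",
                       projectTest(normalized, ref$reference))
  ref_std <- integration$combined[, integration$referenceIds, drop = FALSE]
  labels <- integration$labels[integration$referenceIds]

  set.seed(config@seed)
  partition <- stage("partition", partitionGenes(ref_std, labels))
  dictionary <- stage("train",
                      buildDictionary(ref_std, labels, partition,
                                      nModels = nModels,
                                      threshold = threshold,
                                      seed = config@seed))
  test_mat <- integration$combined[, integration$testIds, drop = FALSE]
  calls <- stage("classify", classifySamples(dictionary, test_mat))

  oof <- if (withOutOfFold)
    stage("out-of-fold",
          outOfFoldCalls(ref_std, labels, partition, nModels = nModels,
                         threshold = threshold, seed = config@seed))
  else NULL

  survivalTable <- stage("simulate-survival",
                         generateSurvival(truth, config,
                                          samples = integration$testIds))
  comparison <- stage("survive", compareTP1(calls, survivalTable))

  label_tab <- table(factor(callTable(calls)$label,
                            levels = c(TP_LEVELS, "Ambiguous")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gliomaTP")),
    seed = config@seed,
    parameters = list(
      n_ref_per_subtype = config@nRefPerSubtype,
      n_test_samples = config@nTestSamples,
      n_endogenous_genes = config@nEndogenousGenes,
      subtype_effect_sd = config@subtypeEffectSd,
      batch_shift = config@batchShift,
      nb_dispersion = config@nbDispersion,
      corrupt_fraction = config@corruptFraction,
      n_models = nModels, threshold = threshold),
    attrition = list(
      lanes_in = length(lanes),
      lanes_passed_qc = length(passed),
      lanes_failed_qc = length(failed),
      failed_lane_ids = failed),
    models_retained = nModels(dictionary),
    call_counts = as.list(label_tab))

  bundle <- list(panel = panel, truth = truth, lanes = lanes, qc = qc,
                 normalized = normalized, integration = integration,
                 partition = partition, dictionary = dictionary,
                 calls = calls, outOfFold = oof,
                 survivalTable = survivalTable, comparison = comparison,
                 manifest = manifest)

  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    writePanel(panel, file.path(outputDir, "panel.csv"))
    write.csv(qcFlags(qc), file.path(outputDir, "qc_report.csv"),
              row.names = FALSE)
    write.table(SummarizedExperiment::assay(normalized),
                file.path(outputDir, "normalized_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(normFactors(normalized),
                         file.path(outputDir, "normalization_factors.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(integration$combined,
                file.path(outputDir, "integrated_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    writeBatchModel(integration$model,
                    file.path(outputDir, "batch_model.json"))
    writeDictionary(dictionary, file.path(outputDir, "dictionary.json"))
    writeCalls(calls, file.path(outputDir, "calls.csv"))
    writeSurvivalTable(survivalTable,
                       file.path(outputDir, "survival_table.csv"))
    writeGroundTruth(truth, file.path(outputDir, "ground_truth.json"))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Human-readable summary of a pipeline bundle
#'
#' Per-class call counts and median classification confidence (an
#' infinite, unanimous-vote confidence is rendered with a `>cap`
#' sentinel), QC attrition, and the survival contrast. A partial bundle
#' yields a partial report with warnings rather than an error.
#'
#' @param bundle output of [runPipeline()].
#' @param confCap sentinel cap used to render infinite confidences.
#' @return list with `classCounts` (data.frame), `attrition`, `survival`,
#'   and `lines` (printable text), invisibly printed.
#' @export
pipelineReport <- function(bundle, confCap = 1000) {
  lines <- character()
  classCounts <- NULL
  if (!is.null(bundle$calls)) {
    ct <- callTable(bundle$calls)
    levs <- c(bundle$calls@classes, "Ambiguous")
    counts <- table(factor(ct$label, levels = levs))
    med_conf <- vapply(levs, function(l) {
      v <- ct$confidence[ct$label == l]
      if (!length(v)) NA_real_ else stats::median(v)
    }, numeric(1))
    render <- ifelse(is.na(med_conf), "-",
                     ifelse(is.infinite(med_conf),
                            paste0(">", confCap),
                            sprintf("%.2f", pmin(med_conf, confCap))))
    classCounts <- data.frame(class = levs, n = as.integer(counts),
                              median_confidence = render,
                              stringsAsFactors = FALSE)
    lines <- c(lines, "Classification calls:",
               sprintf("  %-10s %4d  median confidence %s",
                       classCounts$class, classCounts$n,
                       classCounts$median_confidence))
  } else warning("bundle has no calls; reporting without classification")
  if (!is.null(bundle$manifest)) {
    at <- bundle$manifest$attrition
    lines <- c(lines, sprintf(
      "QC attrition: %d lanes in, %d passed, %d failed",
      at$lanes_in, at$lanes_passed_qc, at$lanes_failed_qc))
  } else warning("bundle has no manifest")
  surv <- NULL
  if (!is.null(bundle$comparison)) {
    cx <- bundle$comparison@cox
    m <- bundle$comparison@km$medians
    fmt <- function(v) if (is.na(v)) "not reached" else sprintf("%.1f", v)
    surv <- list(HR = cx$HR, ci = cx$ci, p_lr = cx$p_lr,
                 medians = m,
                 logrank_p = bundle$comparison@logrank$p)
    lines <- c(lines, sprintf(
      "Survival TP1 vs non-TP1: HR %.2f (95%% CI %.2f-%.2f), LR p = %.4g; median %s vs %s months",
      cx$HR, cx$ci[1], cx$ci[2], cx$p_lr, fmt(m[["TP1"]]),
      fmt(m[["non-TP1"]])))
  } else warning("bundle has no survival comparison")
  out <- list(classCounts = classCounts,
              attrition = bundle$manifest$attrition, survival = surv,
              lines = lines)
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(out)
}
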