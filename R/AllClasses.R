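#' @import methods
#' @importFrom stats kmeans median predict quantile rbinom rexp rnbinom residuals
#'   rnorm runif sd var setNames aggregate coef cor lm pchisq
#' @importFrom utils read.csv write.csv write.table head
NULL

#' Transcriptome profile labels
#'
#' The four glioma transcriptome profiles, in the fixed order used for
#' vote tallies and deterministic tie-breaking.
#' @export
TP_LEVELS <- c("TP1", "TP2a", "TP2b", "TP3")

#' Probe code classes recognized in a panel
#' @export
CODE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

# ---------------------------------------------------------------------------
# PanelDefinition
# ---------------------------------------------------------------------------

#' PanelDefinition: the probe catalogue of a code set
#'
#' Describes every probe of an nCounter-style code set: its name, its code
#' class (Endogenous, Housekeeping, Positive or Negative control) and, for
#' endogenous probes, the expression-pattern group (1..6) it belongs to.
#'
#' @slot probes data.frame with columns `name`, `code_class`, `pattern_group`
#'   (NA for non-endogenous probes).
#' @export
setClass("PanelDefinition", representation(probes = "data.frame"))

setValidity("PanelDefinition", function(object) {
  pr <- object@probes
  msg <- character()
  if (!all(c("name", "code_class", "pattern_group") %in% names(pr)))
    msg <- c(msg, "probes must have columns name, code_class, pattern_group")
  else {
    if (anyDuplicated(pr$name)) msg <- c(msg, "probe names must be unique")
    if (!all(pr$code_class %in% CODE_CLASSES))
      msg <- c(msg, "unknown code class")
    pg <- pr$pattern_group[pr$code_class == "Endogenous"]
    if (anyNA(pg)) msg <- c(msg, "endogenous probes need a pattern group")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelDefinition
#'
#' @param name character vector of probe names.
#' @param code_class character vector, one of [CODE_CLASSES].
#' @param pattern_group integer pattern group for endogenous probes, NA
#'   otherwise.
#' @return A [PanelDefinition-class] object.
#' @export
PanelDefinition <- function(name, code_class, pattern_group = NA_integer_) {
  pr <- data.frame(name = as.character(name),
                   code_class = as.character(code_class),
                   pattern_group = as.integer(pattern_group),
                   stringsAsFactors = FALSE)
  new("PanelDefinition", probes = pr)
}

#' @describeIn PanelDefinition Probe names of a code class (all if NULL).
#' @param panel,object A `PanelDefinition`.
#' @param codeClass optional code class filter.
#' @export
panelProbes <- function(panel, codeClass = NULL) {
  pr <- panel@probes
  if (!is.null(codeClass)) pr <- pr[pr$code_class %in% codeClass, , drop = FALSE]
  pr$name
}

#' @describeIn PanelDefinition Named integer vector of endogenous pattern
#'   groups.
#' @export
patternGroups <- function(panel) {
  pr <- panel@probes[panel@probes$code_class == "Endogenous", , drop = FALSE]
  setNames(pr$pattern_group, pr$name)
}

setMethod("show", "PanelDefinition", function(object) {
  tab <- table(factor(object@probes$code_class, levels = CODE_CLASSES))
  cat("PanelDefinition with", nrow(object@probes), "probes\n")
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# RccLane
# ---------------------------------------------------------------------------

#' RccLane: one sample's raw single-molecule counts
#'
#' Holds a single lane of raw reporter counts plus the lane attributes used
#' for imaging/binding QC. This is the unit on which quality control and
#' normalization factors operate.
#'
#' @slot sampleId character scalar.
#' @slot attributes named list of lane attributes (`ID`, `CartridgeID`,
#'   `Date`, `FovCount`, `FovCounted`, `BindingDensity`, ...).
#' @slot counts data.frame with columns `CodeClass`, `Name`, `Accession`,
#'   `Count` (non-negative integer).
#' @export
setClass("RccLane", representation(sampleId = "character",
                                   attributes = "list",
                                   counts = "data.frame"))

setValidity("RccLane", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be scalar")
  cs <- object@counts
  if (!all(c("CodeClass", "Name", "Accession", "Count") %in% names(cs)))
    msg <- c(msg, "counts must have CodeClass, Name, Accession, Count")
  else if (any(cs$Count < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an RccLane
#' @param sampleId sample identifier.
#' @param attributes named list of lane attributes.
#' @param counts data.frame `CodeClass`, `Name`, `Accession`, `Count`.
#' @return An [RccLane-class] object.
#' @export
RccLane <- function(sampleId, attributes, counts) {
  counts$Count <- as.integer(counts$Count)
  new("RccLane", sampleId = as.character(sampleId),
      attributes = attributes, counts = counts)
}

#' @describeIn RccLane Counts of the lane, optionally one code class, as a
#'   named vector.
#' @param lane An `RccLane`.
#' @param codeClass optional code class filter.
#' @export
laneCounts <- function(lane, codeClass = NULL) {
  cs <- lane@counts
  if (!is.null(codeClass)) cs <- cs[cs$CodeClass %in% codeClass, , drop = FALSE]
  setNames(as.numeric(cs$Count), cs$Name)
}

#' @describeIn RccLane Sample identifier.
#' @export
laneSampleId <- function(lane) lane@sampleId

#' @describeIn RccLane Named list of lane attributes.
#' @export
laneAttributes <- function(lane) lane@attributes

setMethod("show", "RccLane", function(object) {
  cat("RccLane", object@sampleId, "with", nrow(object@counts), "probes;",
      "cartridge", object@attributes$CartridgeID %||% "<none>", "\n")
})

# ---------------------------------------------------------------------------
# QCReport
# ---------------------------------------------------------------------------

#' QCReport: per-lane quality-control flags
#'
#' One row per lane with the individual pass flags (imaging field-of-view
#' ratio, binding density, positive-control linearity, positive and
#' housekeeping normalization factor ranges) and the overall verdict, which
#' is the conjunction of all flags.
#'
#' @slot flags data.frame, one row per lane.
#' @slot thresholds named list of thresholds applied.
#' @export
setClass("QCReport", representation(flags = "data.frame", thresholds = "list"))

setValidity("QCReport", function(object) {
  fl <- object@flags
  need <- c("sample_id", "imaging", "binding", "pos_linearity", "pos_factor",
            "hk_factor", "pass")
  if (!all(need %in% names(fl)))
    return("flags must contain sample_id, the five checks, and pass")
  flag_cols <- c("imaging", "binding", "pos_linearity", "pos_factor",
                 "hk_factor")
  ok <- apply(fl[flag_cols], 1L, all)
  if (!identical(unname(ok), unname(fl$pass)))
    return("overall pass must equal the conjunction of all flags")
  TRUE
})

#' @describeIn QCReport The flag table.
#' @param report A `QCReport`.
#' @export
qcFlags <- function(report) report@flags

#' @describeIn QCReport Sample ids passing all checks.
#' @export
qcPassed <- function(report) report@flags$sample_id[report@flags$pass]

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", sum(object@flags$pass), "of", nrow(object@flags),
      "lanes pass\n")
})

# ---------------------------------------------------------------------------
# NormalizedMatrix (SummarizedExperiment subclass)
# ---------------------------------------------------------------------------

#' NormalizedMatrix: log2-scale normalized expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `log2norm` holds fully normalized, log2(x+1)-transformed endogenous
#' counts (genes in rows, lanes in columns). The positive-control and
#' housekeeping normalization factors applied to each lane are kept in
#' `metadata(x)$factors` for provenance.
#'
#' @export
#' @import SummarizedExperiment
setClass("NormalizedMatrix", contains = "SummarizedExperiment")

setValidity("NormalizedMatrix", function(object) {
  if (!"log2norm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2norm' required")
  TRUE
})

#' @describeIn NormalizedMatrix Per-lane normalization factors applied.
#' @param x A `NormalizedMatrix`.
#' @export
normFactors <- function(x) S4Vectors::metadata(x)$factors

# ---------------------------------------------------------------------------
# ReferenceSet (SummarizedExperiment subclass)
# ---------------------------------------------------------------------------

#' ReferenceSet: labelled reference expression compendium
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the reference
#' genes-by-samples expression matrix (assay `exprs`) with subtype labels in
#' `colData(x)$subtype` and, when known, the generating pattern group of each
#' gene in `rowData(x)$pattern_group`.
#'
#' @export
setClass("ReferenceSet", contains = "SummarizedExperiment")

setValidity("ReferenceSet", function(object) {
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' required")
  if (!"subtype" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain 'subtype'")
  TRUE
})

#' @describeIn ReferenceSet Subtype label per sample.
#' @param x A `ReferenceSet`.
#' @export
refSubtypes <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$subtype),
           colnames(x))
}

# ---------------------------------------------------------------------------
# BatchModel
# ---------------------------------------------------------------------------

#' BatchModel: empirical-Bayes batch-adjustment parameters
#'
#' Per-gene, per-batch location (gamma) and scale (delta^2) estimates, their
#' empirical-Bayes shrunken versions, and the estimated prior
#' hyperparameters, as fitted by [ebBatchAdjust()].
#'
#' @slot batches character vector of batch names.
#' @slot refBatch name of the batch left unchanged.
#' @slot gammaHat,deltaHat batches x genes matrices of raw estimates.
#' @slot gammaStar,deltaStar batches x genes matrices of shrunken estimates.
#' @slot hyper per-batch list of prior hyperparameters
#'   (`gamma_bar`, `tau2`, `lambda`, `theta`).
#' @slot pooledMean,pooledVar per-gene pooled standardization parameters.
#' @export
setClass("BatchModel", representation(
  batches = "character", refBatch = "character",
  gammaHat = "matrix", deltaHat = "matrix",
  gammaStar = "matrix", deltaStar = "matrix",
  hyper = "list", pooledMean = "numeric", pooledVar = "numeric"))

setValidity("BatchModel", function(object) {
  if (any(object@deltaStar <= 0)) return("shrunken variances must be > 0")
  TRUE
})

setMethod("show", "BatchModel", function(object) {
  cat("BatchModel over", length(object@batches), "batches,",
      ncol(object@gammaHat), "genes; reference batch:", object@refBatch, "\n")
})

# ---------------------------------------------------------------------------
# ModelSpec / ModelDictionary
# ---------------------------------------------------------------------------

#' ModelSpec: one entry of the ensemble dictionary
#'
#' A gene subset selected by recursive feature elimination together with the
#' fitted one-vs-rest linear classifier on that subset and its
#' cross-validation record.
#'
#' @slot genes character vector of selected genes.
#' @slot weights classes x (genes+1) matrix; last column is the intercept.
#' @slot classes class labels, in decision-function row order.
#' @slot cvAccuracy mean 3-fold CV accuracy of the selected subset.
#' @slot trajectory data.frame `size`, `accuracy` over the elimination path.
#' @export
setClass("ModelSpec", representation(
  genes = "character", weights = "matrix", classes = "character",
  cvAccuracy = "numeric", trajectory = "data.frame"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (ncol(object@weights) != length(object@genes) + 1L)
    msg <- c(msg, "weights must have one column per gene plus intercept")
  if (nrow(object@weights) != length(object@classes))
    msg <- c(msg, "weights must have one row per class")
  if (object@cvAccuracy < 0 || object@cvAccuracy > 1)
    msg <- c(msg, "cvAccuracy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ModelDictionary: the ensemble of retained classifiers
#'
#' The ordered collection of [ModelSpec-class] entries retained after the
#' accuracy filter, plus construction metadata.
#'
#' @slot models list of `ModelSpec`.
#' @slot seed construction seed.
#' @slot threshold CV-accuracy filter threshold.
#' @slot nRequested number of base models built before filtering.
#' @slot discardedAccuracies CV accuracies of filtered-out models.
#' @export
setClass("ModelDictionary", representation(
  models = "list", seed = "numeric", threshold = "numeric",
  nRequested = "integer", discardedAccuracies = "numeric"))

setValidity("ModelDictionary", function(object) {
  accs <- vapply(object@models, function(m) m@cvAccuracy, numeric(1))
  if (length(accs) && any(accs < object@threshold))
    return("every retained model must meet the accuracy threshold")
  TRUE
})

#' @describeIn ModelDictionary Number of retained models.
#' @param dict A `ModelDictionary`.
#' @export
nModels <- function(dict) length(dict@models)

#' @describeIn ModelDictionary CV accuracies of retained models.
#' @export
cvAccuracies <- function(dict)
  vapply(dict@models, function(m) m@cvAccuracy, numeric(1))

#' @describeIn ModelDictionary Gene-subset sizes of retained models.
#' @export
modelSizes <- function(dict)
  vapply(dict@models, function(m) length(m@genes), integer(1))

setMethod("show", "ModelDictionary", function(object) {
  accs <- cvAccuracies(object)
  cat("ModelDictionary:", length(object@models), "of", object@nRequested,
      "models retained (threshold", object@threshold, ")\n")
  if (length(accs))
    cat("  CV accuracy: min", round(min(accs), 4), "mean",
        round(mean(accs), 4), "| subset sizes",
        paste(range(modelSizes(object)), collapse = "-"), "\n")
})

# ---------------------------------------------------------------------------
# EnsembleCalls
# ---------------------------------------------------------------------------

#' EnsembleCalls: per-sample vote tallies and final labels
#'
#' For each sample: the vote count per transcriptome profile, the top and
#' second vote fractions (p1, p2), the confidence score c = p1/p2, and the
#' final label (a profile when c > 3, otherwise "Ambiguous").
#'
#' @slot calls data.frame with columns `sample_id`, one vote column per
#'   class, `p1`, `p2`, `confidence`, `label`.
#' @slot classes class labels voted over.
#' @export
setClass("EnsembleCalls", representation(calls = "data.frame",
                                         classes = "character"))

setValidity("EnsembleCalls", function(object) {
  cl <- object@calls
  need <- c("sample_id", object@classes, "p1", "p2", "confidence", "label")
  if (!all(need %in% names(cl))) return("calls missing required columns")
  if (nrow(cl) && any(cl$confidence < 1 - 1e-12, na.rm = TRUE))
    return("confidence must be >= 1")
  TRUE
})

#' @describeIn EnsembleCalls The call table.
#' @param calls An `EnsembleCalls`.
#' @export
callTable <- function(calls) calls@calls

#' @describeIn EnsembleCalls Final label per sample (named character).
#' @export
callLabels <- function(calls)
  setNames(calls@calls$label, calls@calls$sample_id)

setMethod("show", "EnsembleCalls", function(object) {
  tab <- table(factor(object@calls$label,
                      levels = c(object@classes, "Ambiguous")))
  cat("EnsembleCalls for", nrow(object@calls), "samples:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# SurvivalComparison
# ---------------------------------------------------------------------------

#' SurvivalComparison: TP1 vs non-TP1 survival contrast
#'
#' Kaplan-Meier estimates and medians per group, the two-group log-rank
#' test, and the single-binary-covariate Cox proportional-hazards fit with
#' Wald confidence interval and likelihood-ratio p-value.
#'
#' @slot km list with per-group step functions and medians.
#' @slot logrank list `statistic`, `p`.
#' @slot cox list `logHR`, `HR`, `ci`, `se`, `p_lr`, `diverged`.
#' @slot data the joined records used.
#' @export
setClass("SurvivalComparison", representation(
  km = "list", logrank = "list", cox = "list", data = "data.frame"))

setMethod("show", "SurvivalComparison", function(object) {
  m <- object@km$medians
  fmt <- function(v) ifelse(is.na(v), "not reached", sprintf("%.1f", v))
  cat("SurvivalComparison (TP1 vs non-TP1)\n")
  cat(sprintf("  median survival: TP1 %s vs non-TP1 %s months\n",
              fmt(m[["TP1"]]), fmt(m[["non-TP1"]])))
  cat(sprintf("  HR %.2f (95%% CI %.2f-%.2f), likelihood-ratio p = %.4g\n",
              object@cox$HR, object@cox$ci[1], object@cox$ci[2],
              object@cox$p_lr))
  cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
              object@logrank$statistic, object@logrank$p))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
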