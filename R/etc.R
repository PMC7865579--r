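# The ensemble transcriptomic classifier: genes are partitioned into six
# expression-pattern groups; each of 1000 base models draws half of every
# group, runs recursive feature elimination (dropping five genes per step,
# mean 3-fold CV accuracy as the criterion), and is kept only if its CV
# accuracy clears the filter; samples are labelled by plurality voting with
# a confidence-ratio abstention rule (c = p1/p2 <= 3 -> "Ambiguous").

#' LinearSVM: a fitted one-vs-rest linear classifier
#'
#' L2-regularized hinge-loss linear decision functions, one per class,
#' fitted by dual coordinate descent (regularization constant C fixed at 1
#' by default). Prediction is the argmax of the decision values.
#'
#' @slot weights classes x (features+1) matrix, intercept last.
#' @slot classes class labels in row order.
#' @slot genes feature names, in the column order of `weights`.
#' @export
setClass("LinearSVM", representation(weights = "matrix",
                                     classes = "character",
                                     genes = "character"))

.class_levels <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% TP_LEVELS)) TP_LEVELS[TP_LEVELS %in% u] else sort(u)
}

.encode_labels <- function(labels, classes) {
  y <- match(as.character(labels), classes) - 1L
  if (anyNA(y)) stop("labels outside the class set")
  y
}

#' Fit a one-vs-rest linear support-vector classifier
#'
#' @param x genes x samples numeric matrix (features in rows, standardized).
#' @param labels class label per sample (column).
#' @param C regularization constant.
#' @param eps dual optimality tolerance.
#' @param maxEpochs epoch cap of the coordinate-descent solver.
#' @return A [LinearSVM-class].
#' @export
fitLinearClassifier <- function(x, labels, C = 1, eps = 0.1,
                                maxEpochs = 200L) {
  stopifnot(ncol(x) == length(labels))
  classes <- .class_levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  y <- .encode_labels(labels, classes)
  W <- .cpp_svm_ovr(x, y, length(classes), C, eps, as.integer(maxEpochs))
  rownames(W) <- classes
  new("LinearSVM", weights = W, classes = classes,
      genes = rownames(x) %||% sprintf("f%d", seq_len(nrow(x))))
}

#' @describeIn fitLinearClassifier Predict class labels for new samples.
#' @param object A `LinearSVM`.
#' @param newdata genes x samples matrix containing the model's genes.
#' @export
setMethod("predict", "LinearSVM", function(object, newdata) {
  x <- if (!is.null(rownames(newdata)) &&
           all(object@genes %in% rownames(newdata)))
    newdata[object@genes, , drop = FALSE]
  else if (nrow(newdata) == length(object@genes)) newdata
  else stop("newdata does not carry the model's features")
  idx <- .cpp_svm_predict(object@weights, x) + 1L
  setNames(object@classes[idx], colnames(newdata))
})

# ---------------------------------------------------------------------------
# gene-group partition
# ---------------------------------------------------------------------------

#' Partition genes into expression-pattern groups
#'
#' Computes each gene's per-subtype mean vector and clusters the vectors by
#' k-means (10 restarts) into `k` groups. Groups are indexed by descending
#' size so the numbering is deterministic. Uses R's RNG; seed before the
#' call for reproducibility.
#'
#' @param reference standardized genes x samples matrix.
#' @param labels subtype label per sample.
#' @param k number of groups.
#' @param nstart k-means restarts.
#' @return named integer vector, gene -> group in 1..k.
#' @export
partitionGenes <- function(reference, labels, k = 6L, nstart = 10L) {
  if (methods::is(reference, "SummarizedExperiment"))
    reference <- SummarizedExperiment::assay(reference)
  stopifnot(ncol(reference) == length(labels))
  classes <- .class_levels(labels)
  means <- vapply(classes, function(cl)
    rowMeans(reference[, labels == cl, drop = FALSE]),
    numeric(nrow(reference)))
  ndistinct <- nrow(unique(round(means, 10)))
  if (ndistinct < k)
    stop("cannot partition: only ", ndistinct,
         " distinct subtype-mean vectors for k = ", k)
  km <- stats::kmeans(means, centers = k, nstart = nstart)
  sizes <- table(km$cluster)
  # rank clusters by descending size; ties resolved by original index
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- integer(k)
  remap[as.integer(names(sizes))[ord]] <- seq_len(k)
  setNames(remap[km$cluster], rownames(reference))
}

#' Draw a stratified half-subset of genes
#'
#' For each pattern group of size m, draws exactly ceiling(m/2) genes
#' without replacement and returns the union. Uses R's RNG.
#'
#' @param partition named integer vector, gene -> group.
#' @return character vector of gene names.
#' @export
sampleGeneSubset <- function(partition) {
  groups <- sort(unique(partition))
  if (any(!tabulate(partition))) stop("empty pattern group")
  unlist(lapply(groups, function(g) {
    members <- names(partition)[partition == g]
    take <- ceiling(length(members) / 2)
    if (length(members) == 1L) members else sample(members, take)
  }), use.names = FALSE)
}

# stratified fold assignment; every fold must contain every class
.stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    j <- which(labels == cl)
    if (length(j) < k)
      stop("class '", cl, "' has fewer samples (", length(j),
           ") than folds (", k, ")")
    fold[j[sample.int(length(j))]] <- rep_len(seq_len(k), length(j))
  }
  fold
}

# ---------------------------------------------------------------------------
# recursive feature elimination
# ---------------------------------------------------------------------------

#' Recursive feature elimination for one base model
#'
#' Starting from `initialGenes`, repeatedly: record the mean stratified
#' 3-fold CV accuracy of the current subset, fit on all samples, rank genes
#' by the sum of squared one-vs-rest weights, and drop the `step`
#' lowest-ranked (never crossing `minGenes`). Returns the smallest recorded
#' subset attaining the maximum accuracy, refit on all samples.
#'
#' @param x genes x samples standardized matrix.
#' @param labels subtype per sample.
#' @param initialGenes starting gene subset (must be rows of `x`).
#' @param step genes removed per iteration.
#' @param cvFolds number of CV folds.
#' @param minGenes smallest subset considered.
#' @param C,eps,maxEpochs solver parameters, see [fitLinearClassifier()].
#' @return A [ModelSpec-class].
#' @export
rfeSelect <- function(x, labels, initialGenes, step = 5L, cvFolds = 3L,
                      minGenes = 5L, C = 1, eps = 0.1, maxEpochs = 200L) {
  miss <- setdiff(initialGenes, rownames(x))
  if (length(miss)) stop("initial genes not in matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  if (length(initialGenes) < minGenes)
    stop("initial subset smaller than minGenes")
  classes <- .class_levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  y <- .encode_labels(labels, classes)
  folds <- .stratified_folds(labels, cvFolds) - 1L
  xs <- x[initialGenes, , drop = FALSE]
  res <- .cpp_rfe(xs, y, length(classes), folds, cvFolds,
                  as.integer(step), as.integer(minGenes), C, eps,
                  as.integer(maxEpochs))
  genes <- initialGenes[res$genes + 1L]
  W <- res$weights
  rownames(W) <- classes
  new("ModelSpec", genes = genes, weights = W, classes = classes,
      cvAccuracy = res$best_accuracy,
      trajectory = data.frame(size = res$sizes, accuracy = res$accuracies))
}

# ---------------------------------------------------------------------------
# dictionary construction
# ---------------------------------------------------------------------------

#' Build the model dictionary
#'
#' Runs `nModels` independent (gene-subset draw, then RFE) constructions
#' and retains models whose mean CV accuracy meets `threshold`. The number
#' and accuracies of discarded models are kept for reporting.
#'
#' @param reference standardized genes x samples matrix (or
#'   [ReferenceSet-class]; then `labels` defaults to its subtypes).
#' @param labels subtype per sample.
#' @param partition gene -> pattern group, from [partitionGenes()].
#' @param nModels base models to build.
#' @param threshold CV-accuracy filter.
#' @param seed construction seed.
#' @param step,cvFolds,minGenes,C RFE and solver parameters.
#' @return A [ModelDictionary-class].
#' @export
buildDictionary <- function(reference, labels = NULL, partition,
                            nModels = 1000L, threshold = 0.95, seed = 1L,
                            step = 5L, cvFolds = 3L, minGenes = 5L, C = 1) {
  if (methods::is(reference, "ReferenceSet")) {
    if (is.null(labels)) labels <- refSubtypes(reference)
    reference <- SummarizedExperiment::assay(reference)
  }
  stopifnot(!is.null(labels), ncol(reference) == length(labels))
  set.seed(seed)
  models <- vector("list", nModels)
  discarded <- numeric()
  for (i in seq_len(nModels)) {
    subset <- sampleGeneSubset(partition)
    spec <- rfeSelect(reference, labels, subset, step = step,
                      cvFolds = cvFolds, minGenes = minGenes, C = C)
    if (spec@cvAccuracy >= threshold) models[[i]] <- spec else
      discarded <- c(discarded, spec@cvAccuracy)
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (!length(models))
    stop("all ", nModels, " models fell below the accuracy threshold of ",
         threshold, "; the subtypes are not separable at this effect size")
  new("ModelDictionary", models = models, seed = as.numeric(seed),
      threshold = threshold, nRequested = as.integer(nModels),
      discardedAccuracies = discarded)
}

# ---------------------------------------------------------------------------
# voting
# ---------------------------------------------------------------------------

#' Plurality vote with confidence-ratio abstention
#'
#' p1 and p2 are the top and second vote fractions; the confidence score is
#' c = p1/p2 (infinite when p2 = 0). The sample is labelled with the most
#' popular class when c > 3 and "Ambiguous" when c <= 3. Ties for the top
#' class give c = 1 and therefore always abstain; the reported top class
#' under a tie follows the fixed class order.
#'
#' @param votes named numeric vector of vote counts per class.
#' @return list `p1`, `p2`, `confidence`, `label`.
#' @export
confidenceRule <- function(votes) {
  total <- sum(votes)
  if (total < 1) stop("no votes cast")
  frac <- votes / total
  ord <- order(-frac, match(names(votes), TP_LEVELS),
               seq_along(votes))
  p1 <- frac[ord[1]]
  p2 <- if (length(frac) > 1L) frac[ord[2]] else 0
  conf <- if (p2 == 0) Inf else p1 / p2
  label <- if (conf > 3) names(votes)[ord[1]] else "Ambiguous"
  list(p1 = unname(p1), p2 = unname(p2), confidence = unname(conf),
       label = label)
}

# assemble an EnsembleCalls object from a classes x samples vote matrix
.calls_from_votes <- function(votes, classes) {
  rows <- lapply(colnames(votes), function(id) {
    v <- votes[, id]
    r <- confidenceRule(setNames(v, classes))
    cbind(data.frame(sample_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(v, classes))),
          data.frame(p1 = r$p1, p2 = r$p2, confidence = r$confidence,
                     label = r$label, stringsAsFactors = FALSE))
  })
  new("EnsembleCalls", calls = do.call(rbind, rows), classes = classes)
}

#' Classify samples with a model dictionary
#'
#' Every retained model votes on every sample; the plurality +
#' confidence-ratio rule produces the final label. The full vote tally is
#' preserved in the output for audit.
#'
#' @param dict A [ModelDictionary-class] trained on the full reference.
#' @param mat genes x samples matrix on the reference scale (e.g. the test
#'   columns of [projectTest()]'s output). Missing model genes raise an
#'   error listing them.
#' @return An [EnsembleCalls-class].
#' @export
classifySamples <- function(dict, mat) {
  if (!nModels(dict)) stop("empty dictionary")
  need <- unique(unlist(lapply(dict@models, function(m) m@genes)))
  miss <- setdiff(need, rownames(mat))
  if (length(miss))
    stop("matrix is missing model genes: ",
         paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) ", ...")
  classes <- dict@models[[1]]@classes
  ids <- colnames(mat) %||% sprintf("S%d", seq_len(ncol(mat)))
  votes <- matrix(0, length(classes), ncol(mat),
                  dimnames = list(classes, ids))
  for (m in dict@models) {
    idx <- .cpp_svm_predict(m@weights, mat[m@genes, , drop = FALSE]) + 1L
    for (c in seq_along(classes))
      votes[c, ] <- votes[c, ] + (idx == c)
  }
  .calls_from_votes(votes, classes)
}

#' Out-of-fold ensemble calls on the reference cohort
#'
#' Splits the reference into stratified folds; for each fold a dictionary
#' is built on the remaining folds and votes are collected on the held-out
#' fold only, so no sample is ever predicted by a model that saw it in
#' training.
#'
#' @param reference standardized genes x samples matrix or
#'   [ReferenceSet-class].
#' @param labels subtype per sample.
#' @param partition gene -> pattern group.
#' @param folds number of outer folds.
#' @param nModels,threshold,seed,... passed to [buildDictionary()].
#' @return list: `calls` ([EnsembleCalls-class]), `foldAssignments`,
#'   `nVotesPerFold` (retained models per fold dictionary).
#' @export
outOfFoldCalls <- function(reference, labels = NULL, partition, folds = 4L,
                           nModels = 1000L, threshold = 0.95, seed = 1L,
                           ...) {
  if (methods::is(reference, "ReferenceSet")) {
    if (is.null(labels)) labels <- refSubtypes(reference)
    reference <- SummarizedExperiment::assay(reference)
  }
  stopifnot(ncol(reference) == length(labels))
  set.seed(seed)
  fold <- .stratified_folds(labels, folds)
  classes <- .class_levels(labels)
  ids <- colnames(reference)
  votes <- matrix(0, length(classes), ncol(reference),
                  dimnames = list(classes, ids))
  nvotes <- integer(folds)
  for (f in seq_len(folds)) {
    train <- fold != f
    dict <- buildDictionary(reference[, train, drop = FALSE],
                            labels[train], partition, nModels = nModels,
                            threshold = threshold, seed = seed + f, ...)
    nvotes[f] <- nModels(dict)
    held <- reference[, !train, drop = FALSE]
    calls <- classifySamples(dict, held)
    vt <- as.matrix(callTable(calls)[, classes, drop = FALSE])
    rownames(vt) <- callTable(calls)$sample_id
    votes[, rownames(vt)] <- t(vt)
  }
  list(calls = .calls_from_votes(votes, classes),
       foldAssignments = setNames(fold, ids), nVotesPerFold = nvotes)
}

#' Serialize a ModelDictionary to JSON
#' @param dict A [ModelDictionary-class].
#' @param path output file.
#' @export
writeDictionary <- function(dict, path) {
  jsonlite::write_json(list(
    seed = dict@seed, threshold = dict@threshold,
    n_requested = dict@nRequested, n_retained = nModels(dict),
    discarded_accuracies = dict@discardedAccuracies,
    models = lapply(dict@models, function(m) list(
      genes = m@genes, classes = m@classes,
      cv_accuracy = m@cvAccuracy,
      weights = apply(m@weights, 1L, identity, simplify = FALSE),
      trajectory = m@trajectory))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ensemble calls as CSV
#' @param calls An [EnsembleCalls-class].
#' @param path output file.
#' @export
writeCalls <- function(calls, path) {
  write.csv(callTable(calls), path, row.names = FALSE)
  invisible(path)
}
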