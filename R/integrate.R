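# Standardization and empirical-Bayes location/scale batch integration.
#
# Model, per gene g and batch i:  Y = alpha_g + gamma_ig + delta_ig * eps.
# Batch location/scale estimates are shrunk toward parametric cross-gene
# priors (gamma ~ Normal(gamma_bar, tau2), delta^2 ~ InverseGamma(lambda,
# theta)) via the coupled posterior equations, and non-reference batches are
# adjusted (Y - gamma*) / sqrt(delta2*). The reference batch is returned
# bitwise unchanged so classifiers trained on it stay calibrated.

#' Per-gene z-score standardization
#'
#' Centers and scales each gene (row) to mean 0, SD 1 (denominator n-1).
#' Constant genes cannot be scaled; they are dropped with a warning and
#' listed in the `dropped` attribute. The centering and scaling vectors are
#' kept as attributes for inspection.
#'
#' @param mat genes x samples numeric matrix (or a
#'   [SummarizedExperiment::SummarizedExperiment] whose first assay is
#'   used).
#' @return the standardized matrix with attributes `center`, `scale`,
#'   `dropped`.
#' @export
standardizeMatrix <- function(mat) {
  if (methods::is(mat, "SummarizedExperiment"))
    mat <- SummarizedExperiment::assay(mat)
  if (ncol(mat) < 2L) stop("standardization needs at least 2 samples")
  ctr <- rowMeans(mat)
  sc <- apply(mat, 1L, stats::sd)
  dropped <- rownames(mat)[sc == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " constant gene(s): ",
            paste(head(dropped, 5), collapse = ", "))
    keep <- sc > 0
    mat <- mat[keep, , drop = FALSE]
    ctr <- ctr[keep]
    sc <- sc[keep]
  }
  out <- (mat - ctr) / sc
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  attr(out, "dropped") <- dropped
  out
}

# method-of-moments inverse-gamma hyperparameters from a vector of
# per-gene variance estimates
.ig_moments <- function(d) {
  m <- mean(d)
  s2 <- stats::var(d)
  list(lambda = (2 * s2 + m^2) / s2, theta = (m * s2 + m^3) / s2)
}

# coupled posterior iteration for one batch
.eb_iterate <- function(sdat, g.hat, d.hat, g.bar, t2, lambda, theta,
                        conv = 1e-4, maxIter = 100L) {
  n <- ncol(sdat)
  g.old <- g.hat
  d.old <- d.hat
  for (it in seq_len(maxIter)) {
    g.new <- (t2 * n * g.hat + d.old * g.bar) / (t2 * n + d.old)
    sum2 <- rowSums((sdat - g.new)^2)
    d.new <- (0.5 * sum2 + theta) / (n / 2 + lambda - 1)
    change <- max(abs(g.new - g.old) / abs(g.old),
                  abs(d.new - d.old) / abs(d.old))
    g.old <- g.new
    d.old <- d.new
    if (is.finite(change) && change < conv) break
  }
  list(gamma = g.new, delta2 = d.new)
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction with parametric empirical-Bayes
#' shrinkage. When `refBatch` is given, the pooled standardization uses the
#' reference batch's per-gene mean and variance, only non-reference batches
#' are adjusted, and the reference batch is returned bitwise unchanged.
#'
#' @param combined genes x samples matrix (typically standardized).
#' @param batch character/factor of batch labels, one per column.
#' @param refBatch batch left unchanged (`NULL` for fully symmetric
#'   adjustment).
#' @param conv relative convergence tolerance of the posterior iteration.
#' @param maxIter iteration cap.
#' @return list with `adjusted` (matrix) and `model`
#'   ([BatchModel-class]).
#' @export
ebBatchAdjust <- function(combined, batch, refBatch = NULL, conv = 1e-4,
                          maxIter = 100L) {
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(combined))
  batches <- unique(batch)
  if (length(batches) == 1L) {
    warning("single batch: identity transform")
    model <- new("BatchModel", batches = batches,
                 refBatch = refBatch %||% batches,
                 gammaHat = matrix(0, 1, nrow(combined),
                                   dimnames = list(batches,
                                                   rownames(combined))),
                 deltaHat = matrix(1, 1, nrow(combined)),
                 gammaStar = matrix(0, 1, nrow(combined)),
                 deltaStar = matrix(1, 1, nrow(combined)),
                 hyper = list(), pooledMean = rowMeans(combined),
                 pooledVar = apply(combined, 1L, stats::var))
    return(list(adjusted = combined, model = model))
  }
  if (!is.null(refBatch) && !refBatch %in% batches)
    stop("refBatch '", refBatch, "' not among batch labels")

  idx <- lapply(batches, function(b) which(batch == b))
  names(idx) <- batches
  n_i <- lengths(idx)
  if (any(n_i < 1L)) stop("empty batch")

  batch_means <- vapply(idx, function(j)
    rowMeans(combined[, j, drop = FALSE]), numeric(nrow(combined)))
  batch_means <- t(batch_means) # batches x genes

  if (!is.null(refBatch)) {
    grand <- batch_means[refBatch, ]
    jr <- idx[[refBatch]]
    pooled_var <- rowSums((combined[, jr, drop = FALSE] - grand)^2) /
      length(jr)
  } else {
    grand <- colSums(batch_means * (n_i / sum(n_i)))
    fitted <- matrix(0, nrow(combined), ncol(combined))
    for (b in batches) fitted[, idx[[b]]] <- batch_means[b, ]
    pooled_var <- rowSums((combined - fitted)^2) / ncol(combined)
  }
  if (any(pooled_var <= 0))
    stop("genes with zero pooled variance: ",
         paste(head(rownames(combined)[pooled_var <= 0], 5), collapse = ", "))

  sdat <- (combined - grand) / sqrt(pooled_var)

  nb <- length(batches)
  nG <- nrow(combined)
  gamma_hat <- matrix(NA_real_, nb, nG, dimnames = list(batches,
                                                        rownames(combined)))
  delta_hat <- gamma_hat
  gamma_star <- gamma_hat
  delta_star <- gamma_hat
  hyper <- vector("list", nb)
  names(hyper) <- batches
  for (b in batches) {
    j <- idx[[b]]
    sb <- sdat[, j, drop = FALSE]
    g.hat <- rowMeans(sb)
    d.hat <- if (length(j) > 1L) apply(sb, 1L, stats::var) else
      rep(1, nG) # single-sample batch: location-only adjustment
    g.bar <- mean(g.hat)
    t2 <- stats::var(g.hat)
    ig <- .ig_moments(d.hat)
    hyper[[b]] <- list(gamma_bar = g.bar, tau2 = t2,
                       lambda = ig$lambda, theta = ig$theta)
    if (length(j) > 1L) {
      sol <- .eb_iterate(sb, g.hat, d.hat, g.bar, t2, ig$lambda, ig$theta,
                         conv, maxIter)
    } else {
      g.star <- (t2 * 1 * g.hat + 1 * g.bar) / (t2 * 1 + 1)
      sol <- list(gamma = g.star, delta2 = rep(1, nG))
    }
    gamma_hat[b, ] <- g.hat
    delta_hat[b, ] <- d.hat
    gamma_star[b, ] <- sol$gamma
    delta_star[b, ] <- sol$delta2
  }

  # with a reference batch, its columns stay bitwise unchanged; without
  # one, every batch is adjusted symmetrically
  adjusted <- combined
  for (b in setdiff(batches, refBatch)) {
    j <- idx[[b]]
    adj <- (sdat[, j, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
    adjusted[, j] <- adj * sqrt(pooled_var) + grand
  }

  model <- new("BatchModel", batches = batches,
               refBatch = refBatch %||% NA_character_,
               gammaHat = gamma_hat, deltaHat = delta_hat,
               gammaStar = gamma_star, deltaStar = delta_star,
               hyper = hyper, pooledMean = grand, pooledVar = pooled_var)
  list(adjusted = adjusted, model = model)
}

#' Serialize a BatchModel to JSON for audit
#' @param model A [BatchModel-class].
#' @param path output file.
#' @export
writeBatchModel <- function(model, path) {
  jsonlite::write_json(list(
    batches = model@batches, ref_batch = model@refBatch,
    hyper = model@hyper,
    gamma_hat = apply(model@gammaHat, 1L, identity, simplify = FALSE),
    gamma_star = apply(model@gammaStar, 1L, identity, simplify = FALSE),
    delta_hat = apply(model@deltaHat, 1L, identity, simplify = FALSE),
    delta_star = apply(model@deltaStar, 1L, identity, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project test samples into the reference space
#'
#' Standardizes the test matrix on its own per-gene statistics (a single
#' test sample is centered/scaled with the reference statistics instead),
#' concatenates it with the standardized reference over shared genes, and
#' applies [ebBatchAdjust()] with the reference as the unchanged batch.
#'
#' @param test A [NormalizedMatrix-class] or genes x samples matrix.
#' @param reference A [ReferenceSet-class] or genes x samples matrix.
#' @param requiredGenes genes that must be present in the test matrix
#'   (e.g. a dictionary's feature set); missing ones raise an error
#'   listing them.
#' @return list: `combined` adjusted matrix, `batch` labels, `model`
#'   ([BatchModel-class]), `referenceIds`, `testIds`, and `labels` (the
#'   reference subtypes when available).
#' @export
projectTest <- function(test, reference, requiredGenes = NULL) {
  labels <- NULL
  if (methods::is(reference, "ReferenceSet")) labels <- refSubtypes(reference)
  if (methods::is(reference, "SummarizedExperiment"))
    reference <- SummarizedExperiment::assay(reference)
  if (methods::is(test, "SummarizedExperiment"))
    test <- SummarizedExperiment::assay(test)

  if (!is.null(requiredGenes)) {
    miss <- setdiff(requiredGenes, rownames(test))
    if (length(miss))
      stop("test matrix is missing classifier genes: ",
           paste(head(miss, 10), collapse = ", "),
           if (length(miss) > 10) ", ...")
  }
  genes <- intersect(rownames(reference), rownames(test))
  if (!length(genes)) stop("no shared genes between test and reference")

  ref_std <- standardizeMatrix(reference[genes, , drop = FALSE])
  genes <- setdiff(genes, attr(ref_std, "dropped"))
  testm <- test[genes, , drop = FALSE]
  if (ncol(testm) >= 2L) {
    test_std <- standardizeMatrix(testm)
    keep <- setdiff(genes, attr(test_std, "dropped"))
    ref_std <- ref_std[keep, , drop = FALSE]
    test_std <- test_std[keep, , drop = FALSE]
    genes <- keep
  } else {
    # single sample: fall back to reference statistics
    test_std <- (testm - attr(ref_std, "center")[genes]) /
      attr(ref_std, "scale")[genes]
  }

  combined <- cbind(ref_std[genes, , drop = FALSE],
                    test_std[genes, , drop = FALSE])
  batch <- rep(c("reference", "test"), c(ncol(ref_std), ncol(test_std)))
  fit <- ebBatchAdjust(combined, batch, refBatch = "reference")
  list(combined = fit$adjusted, batch = batch, model = fit$model,
       referenceIds = colnames(ref_std), testIds = colnames(test_std),
       labels = labels)
}
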