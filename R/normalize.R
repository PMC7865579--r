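# Lane QC and the two-stage geometric-mean normalization: counts are scaled
# first to the positive spike-in controls, then to the housekeeping genes,
# and finally log2(x+1)-transformed. Endogenous probes only in the output.

#' Default lane QC thresholds
#'
#' Platform-standard defaults: imaging field-of-view ratio >= 0.75, binding
#' density within 0.1-2.25, positive-control log-log linearity R^2 >= 0.95,
#' positive normalization factor within 0.3-3, housekeeping factor within
#' 0.1-10.
#' @export
defaultQcThresholds <- function() {
  list(fov = 0.75, binding = c(0.1, 2.25), r2 = 0.95,
       posFactor = c(0.3, 3), hkFactor = c(0.1, 10))
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`. Callers normalizing control probes replace zero
#' counts by 1 beforehand (see [normalizeLanes()]); a zero here yields 0.
#'
#' @param values non-negative numeric vector, non-empty.
#' @return the geometric mean.
#' @export
geometricMean <- function(values) {
  if (!length(values)) stop("geometric mean of an empty vector")
  if (any(values < 0)) stop("geometric mean requires non-negative values")
  exp(mean(log(values)))
}

# geomean of a probe class with the zero-replacement convention
.control_geomean <- function(counts) {
  counts[counts == 0] <- 1
  geometricMean(counts)
}

.class_counts <- function(lane, which) {
  laneCounts(lane, codeClass = which)
}

#' Normalization factor of a lane within a cohort
#'
#' The multiplicative factor equalizing the geometric mean of a probe class
#' across lanes: the arithmetic mean over the cohort of per-lane geometric
#' means of the selected probes, divided by this lane's geometric mean.
#' Zero counts are replaced by 1 before the geometric means. A lane whose
#' selected probes are all zero gets `NA` (a QC failure signal, not a
#' factor).
#'
#' @param lane An [RccLane-class]; must be a member of `cohort`.
#' @param cohort list of [RccLane-class] lanes normalized together.
#' @param which `"Positive"` or `"Housekeeping"`.
#' @return the factor, or `NA_real_` for an all-zero lane.
#' @export
normalizationFactor <- function(lane, cohort,
                                which = c("Positive", "Housekeeping")) {
  which <- match.arg(which)
  ids <- vapply(cohort, laneSampleId, character(1))
  if (!laneSampleId(lane) %in% ids)
    stop("lane '", laneSampleId(lane), "' is not in the cohort")
  own <- .class_counts(lane, which)
  if (!length(own)) stop("lane has no ", which, " probes")
  if (all(own == 0)) return(NA_real_)
  geomeans <- vapply(cohort, function(l) {
    cts <- .class_counts(l, which)
    if (all(cts == 0)) NA_real_ else .control_geomean(cts)
  }, numeric(1))
  mean(geomeans, na.rm = TRUE) / .control_geomean(own)
}

# R^2 of log2(count + 1) against log2(input concentration) over the
# positive spike-in ladder
.pos_linearity <- function(lane, ladder) {
  cts <- .class_counts(lane, "Positive")
  conc <- ladder[names(cts)]
  if (anyNA(conc)) conc <- ladder[seq_along(cts)] # fall back to file order
  y <- log2(cts + 1)
  fit <- stats::lm(y ~ log2(conc))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NaN) # constant response: linearity undefined
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

.in_range <- function(x, range) !is.na(x) && x >= range[1] && x <= range[2]

#' Quality-control checks for one lane
#'
#' Computes the five lane flags: imaging (fov_counted/fov_count), binding
#' density, positive-control linearity, and the two normalization-factor
#' range checks. QC always returns a report; it never errors on a bad lane.
#'
#' @param lane An [RccLane-class].
#' @param cohort list of lanes the factors are computed against (must
#'   contain `lane`).
#' @param thresholds see [defaultQcThresholds()].
#' @param ladder named positive-control input concentrations.
#' @return one-row data.frame of flags (used by [qcLanes()]).
#' @export
qcLane <- function(lane, cohort, thresholds = defaultQcThresholds(),
                   ladder = POS_LADDER) {
  at <- laneAttributes(lane)
  fov_ratio <- if (!is.null(at$FovCounted) && !is.null(at$FovCount) &&
                   at$FovCount > 0) at$FovCounted / at$FovCount else NA_real_
  bd <- at$BindingDensity %||% NA_real_
  r2 <- .pos_linearity(lane, ladder)
  fpos <- normalizationFactor(lane, cohort, "Positive")
  fhk <- normalizationFactor(lane, cohort, "Housekeeping")
  flags <- data.frame(
    sample_id = laneSampleId(lane),
    fov_ratio = fov_ratio, binding_density = bd, pos_r2 = r2,
    pos_factor_value = fpos, hk_factor_value = fhk,
    imaging = !is.na(fov_ratio) && fov_ratio >= thresholds$fov,
    binding = .in_range(bd, thresholds$binding),
    pos_linearity = !is.na(r2) && r2 >= thresholds$r2,
    pos_factor = .in_range(fpos, thresholds$posFactor),
    hk_factor = .in_range(fhk, thresholds$hkFactor),
    stringsAsFactors = FALSE)
  flags$pass <- flags$imaging && flags$binding && flags$pos_linearity &&
    flags$pos_factor && flags$hk_factor
  flags
}

#' Quality control for a cohort of lanes
#'
#' Applies [qcLane()] to every lane. Normalization factors are computed
#' within the whole input set by default, or within per-cartridge cohorts
#' when `cohortBy = "CartridgeID"`.
#'
#' @param lanes list of [RccLane-class].
#' @param thresholds see [defaultQcThresholds()].
#' @param cohortBy lane attribute defining factor cohorts, or `NULL` for
#'   the whole input set.
#' @return A [QCReport-class].
#' @export
qcLanes <- function(lanes, thresholds = defaultQcThresholds(),
                    cohortBy = NULL) {
  stopifnot(length(lanes) >= 1L)
  groups <- if (is.null(cohortBy)) rep("all", length(lanes)) else
    vapply(lanes, function(l) as.character(laneAttributes(l)[[cohortBy]] %||%
                                             "all"), character(1))
  rows <- lapply(seq_along(lanes), function(i) {
    cohort <- lanes[groups == groups[i]]
    qcLane(lanes[[i]], cohort, thresholds)
  })
  new("QCReport", flags = do.call(rbind, rows), thresholds = thresholds)
}

#' Two-stage geometric-mean normalization
#'
#' For each lane, counts are multiplied by the positive-control factor,
#' then by the housekeeping factor recomputed on the positive-normalized
#' counts, then log2(x+1)-transformed. Only endogenous probes appear in
#' the output matrix. After this, the housekeeping geometric means are
#' identical across lanes.
#'
#' @param lanes list of [RccLane-class], all passing QC.
#' @param panel A [PanelDefinition-class].
#' @param qc optional [QCReport-class]; if supplied, including any failing
#'   lane is refused with the offending ids.
#' @return A [NormalizedMatrix-class] with per-lane factors in
#'   `metadata(x)$factors`.
#' @export
normalizeLanes <- function(lanes, panel, qc = NULL) {
  if (length(lanes) < 2L) stop("normalization needs at least 2 lanes")
  ids <- vapply(lanes, laneSampleId, character(1))
  if (!is.null(qc)) {
    failing <- intersect(ids, qcFlags(qc)$sample_id[!qcFlags(qc)$pass])
    if (length(failing))
      stop("refusing to normalize lanes failing QC: ",
           paste(failing, collapse = ", "))
  }
  endo <- panelProbes(panel, "Endogenous")
  hk <- panelProbes(panel, "Housekeeping")

  fpos <- vapply(lanes, normalizationFactor, numeric(1), cohort = lanes,
                 which = "Positive")
  if (anyNA(fpos)) stop("all-zero positive controls in: ",
                        paste(ids[is.na(fpos)], collapse = ", "))
  # housekeeping factor on positive-normalized counts, sequentially
  hk_geomeans <- vapply(seq_along(lanes), function(i) {
    cts <- laneCounts(lanes[[i]])[hk] * fpos[i]
    if (all(cts == 0)) NA_real_ else .control_geomean(cts)
  }, numeric(1))
  if (anyNA(hk_geomeans)) stop("all-zero housekeeping probes in: ",
                               paste(ids[is.na(hk_geomeans)], collapse = ", "))
  fhk <- mean(hk_geomeans) / hk_geomeans

  mat <- vapply(seq_along(lanes), function(i) {
    cts <- laneCounts(lanes[[i]])[endo]
    log2(cts * fpos[i] * fhk[i] + 1)
  }, numeric(length(endo)))
  dimnames(mat) <- list(endo, ids)

  cartridges <- vapply(lanes, function(l)
    as.character(laneAttributes(l)$CartridgeID %||% NA_character_),
    character(1))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2norm = mat),
    colData = S4Vectors::DataFrame(cartridge = cartridges, row.names = ids),
    metadata = list(factors = data.frame(
      sample_id = ids, pos_factor = unname(fpos), hk_factor = unname(fhk),
      stringsAsFactors = FALSE)))
  methods::as(se, "NormalizedMatrix")
}

#' Replicate concordance
#'
#' Pearson correlation over endogenous genes for each named pair of
#' columns, and the average over pairs. A constant column yields `NA` for
#' its pairs (correlation undefined).
#'
#' @param mat A [NormalizedMatrix-class] or plain genes x samples matrix.
#' @param pairs 2-column matrix/data.frame, or list of length-2 character
#'   vectors, naming replicate column pairs.
#' @return list with `pairs` (data.frame `a`, `b`, `r`) and `average`.
#' @export
replicateConcordance <- function(mat, pairs) {
  if (methods::is(mat, "SummarizedExperiment"))
    mat <- SummarizedExperiment::assay(mat)
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  missing <- setdiff(as.vector(pairs), colnames(mat))
  if (length(missing))
    stop("replicate columns absent from matrix: ",
         paste(missing, collapse = ", "))
  r <- apply(pairs, 1L, function(pr) {
    a <- mat[, pr[1]]
    b <- mat[, pr[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  })
  list(pairs = data.frame(a = pairs[, 1], b = pairs[, 2], r = r,
                          stringsAsFactors = FALSE),
       average = mean(r, na.rm = TRUE))
}
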