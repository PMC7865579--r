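# Synthetic-data module: generates every input the pipeline consumes --
# a labelled reference compendium, RCC-style test lanes with batch and lane
# effects, technical replicates, and survival tables -- with known ground
# truth, so all downstream stages are testable without restricted data.

#' The default housekeeping probes of the panel
#' @export
HOUSEKEEPING_GENES <- c("GAPDH", "HNRNPL", "IPO8", "MRPL19", "MRPL30",
                        "NRF1", "RNF10", "TBP")

# platform-standard positive spike-in ladder, relative concentrations
POS_LADDER <- c(POS_A = 128, POS_B = 32, POS_C = 8, POS_D = 2,
                POS_E = 0.5, POS_F = 0.125)
NEG_PROBES <- paste0("NEG_", LETTERS[1:6])

#' SimulationConfig: parameters of the synthetic study
#'
#' All knobs of the synthetic-data generators. The defaults define the
#' simulated study: 100 reference samples per subtype, a 48-lane test cohort,
#' 160 endogenous genes in 6 expression-pattern groups plus 8 housekeeping
#' genes, a 2-SD subtype effect, and a TP1 vs non-TP1 hazard ratio of 4.5.
#'
#' @slot nRefPerSubtype reference samples per subtype.
#' @slot nTestSamples number of test lanes.
#' @slot nEndogenousGenes number of endogenous (classifier) genes.
#' @slot nHousekeeping number of housekeeping probes.
#' @slot nPatternGroups number of expression-pattern groups.
#' @slot subtypeEffectSd between-subtype mean shift, in units of the
#'   within-subtype SD.
#' @slot batchShift SD of the per-gene additive (log2) batch offset between
#'   the reference and test platforms.
#' @slot batchScaleSd SD of the per-gene log multiplicative batch dispersion.
#' @slot nbDispersion negative-binomial dispersion of counts (0 = the
#'   deterministic rounded-mean limit).
#' @slot laneScaleRange range of the per-lane multiplicative scale.
#' @slot replicateNoiseSd per-gene log2 jitter SD between technical
#'   replicates.
#' @slot hazardTp1,hazardNonTp1 exponential event hazards, events/month.
#' @slot censoringRate independent exponential censoring hazard,
#'   events/month (0 = no censoring).
#' @slot corruptFraction fraction of test lanes generated with corrupted
#'   positive controls.
#' @slot seed integer seed for all generators.
#' @export
setClass("SimulationConfig", representation(
  nRefPerSubtype = "integer", nTestSamples = "integer",
  nEndogenousGenes = "integer", nHousekeeping = "integer",
  nPatternGroups = "integer", subtypeEffectSd = "numeric",
  batchShift = "numeric", batchScaleSd = "numeric",
  nbDispersion = "numeric", laneScaleRange = "numeric",
  replicateNoiseSd = "numeric", hazardTp1 = "numeric",
  hazardNonTp1 = "numeric", censoringRate = "numeric",
  corruptFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nEndogenousGenes < object@nPatternGroups)
    msg <- c(msg, "need at least one endogenous gene per pattern group")
  if (object@subtypeEffectSd < 0 || object@batchShift < 0 ||
      object@batchScaleSd < 0 || object@nbDispersion < 0 ||
      object@replicateNoiseSd < 0 || object@censoringRate < 0)
    msg <- c(msg, "rates and SDs must be >= 0")
  if (length(object@laneScaleRange) != 2L ||
      any(object@laneScaleRange <= 0) ||
      diff(object@laneScaleRange) < 0)
    msg <- c(msg, "laneScaleRange must be a positive, ordered interval")
  if (object@hazardTp1 <= 0 || object@hazardNonTp1 <= 0)
    msg <- c(msg, "hazards must be > 0")
  if (object@corruptFraction < 0 || object@corruptFraction > 1)
    msg <- c(msg, "corruptFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nRefPerSubtype,nTestSamples,nEndogenousGenes,nHousekeeping
#'   cohort and panel sizes.
#' @param nPatternGroups,subtypeEffectSd,batchShift,batchScaleSd generative
#'   effect sizes.
#' @param nbDispersion,laneScaleRange,replicateNoiseSd count-noise model.
#' @param hazardTp1,hazardNonTp1,censoringRate survival model
#'   (events/month). The defaults put the TP1 median at 12.1 months with a
#'   TP1 vs non-TP1 hazard ratio of 4.5.
#' @param corruptFraction fraction of test lanes with corrupted positive
#'   controls.
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object.
#' @export
SimulationConfig <- function(nRefPerSubtype = 100L, nTestSamples = 48L,
                             nEndogenousGenes = 160L, nHousekeeping = 8L,
                             nPatternGroups = 6L, subtypeEffectSd = 2,
                             batchShift = 0.5, batchScaleSd = 0.1,
                             nbDispersion = 0.01,
                             laneScaleRange = c(0.7, 1.4),
                             replicateNoiseSd = 0.05,
                             hazardTp1 = log(2) / 12.1,
                             hazardNonTp1 = log(2) / 12.1 / 4.5,
                             censoringRate = 0.008,
                             corruptFraction = 0, seed = 1L) {
  new("SimulationConfig",
      nRefPerSubtype = as.integer(nRefPerSubtype),
      nTestSamples = as.integer(nTestSamples),
      nEndogenousGenes = as.integer(nEndogenousGenes),
      nHousekeeping = as.integer(nHousekeeping),
      nPatternGroups = as.integer(nPatternGroups),
      subtypeEffectSd = subtypeEffectSd, batchShift = batchShift,
      batchScaleSd = batchScaleSd, nbDispersion = nbDispersion,
      laneScaleRange = laneScaleRange, replicateNoiseSd = replicateNoiseSd,
      hazardTp1 = hazardTp1, hazardNonTp1 = hazardNonTp1,
      censoringRate = censoringRate, corruptFraction = corruptFraction,
      seed = as.integer(seed))
}

#' GroundTruth: generative truth of a synthetic study
#'
#' Records, for every generated sample and endogenous gene, the quantities
#' the pipeline is later asked to recover, plus the internal generative
#' parameters needed to draw further lanes consistent with the reference.
#'
#' @slot subtypes named character, sample -> true subtype.
#' @slot geneGroups named integer, endogenous gene -> true pattern group.
#' @slot batches named character, sample -> batch.
#' @slot hazardRatio true TP1 vs non-TP1 hazard ratio.
#' @slot corruptLanes sample ids generated with corrupted positive controls.
#' @slot baseline named numeric, per-gene baseline log2 expression
#'   (endogenous + housekeeping).
#' @slot archetypes genes x subtypes matrix of generative mean offsets.
#' @slot batchShifts named numeric, per-gene additive log2 batch offset of
#'   the test platform.
#' @slot geneScale named numeric, per-gene multiplicative noise dispersion
#'   of the test platform.
#' @export
setClass("GroundTruth", representation(
  subtypes = "character", geneGroups = "integer", batches = "character",
  hazardRatio = "numeric", corruptLanes = "character",
  baseline = "numeric", archetypes = "matrix", batchShifts = "numeric",
  geneScale = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@subtypes), "samples,",
      length(object@geneGroups), "endogenous genes, true HR",
      round(object@hazardRatio, 2), "\n")
})

#' @describeIn GroundTruth Sample -> true subtype.
#' @param truth A `GroundTruth`.
#' @export
trueSubtypes <- function(truth) truth@subtypes

#' @describeIn GroundTruth Gene -> true pattern group.
#' @export
trueGeneGroups <- function(truth) truth@geneGroups

# six archetypal subtype-mean sign patterns over (TP1, TP2a, TP2b, TP3)
.archetype_patterns <- function() {
  rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
        c(0, 0, 0, 1), c(1, 1, -1, -1), c(1, -1, 1, -1))
}

# near-equal group sizes, non-increasing, summing to n
.group_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

#' Generate the synthetic reference compendium
#'
#' Draws a labelled genes-by-samples expression matrix emulating a combined
#' reference compendium: four subtypes whose per-gene means follow one of
#' six archetypal sign patterns scaled by `subtypeEffectSd`, with unit-SD
#' Gaussian within-subtype noise on a per-gene baseline.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with elements `reference` (a [ReferenceSet-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @export
generateReference <- function(config) {
  validObject(config)
  if (config@nRefPerSubtype < 2L)
    stop("invalid config: need at least 2 reference samples per subtype")
  set.seed(config@seed)
  nG <- config@nEndogenousGenes
  k <- config@nPatternGroups
  genes <- sprintf("GENE%03d", seq_len(nG))
  sizes <- .group_sizes(nG, k)
  groups <- rep.int(seq_len(k), sizes)
  names(groups) <- genes

  pat <- .archetype_patterns()
  if (k > nrow(pat)) stop("at most ", nrow(pat), " pattern groups supported")
  arch <- pat[groups, , drop = FALSE] * config@subtypeEffectSd
  dimnames(arch) <- list(genes, TP_LEVELS)

  baseline <- stats::runif(nG, 5, 9)
  hk_baseline <- stats::runif(config@nHousekeeping, 9, 11)
  hk <- HOUSEKEEPING_GENES
  if (config@nHousekeeping > length(hk))
    hk <- c(hk, sprintf("HK%02d", seq_len(config@nHousekeeping - length(hk))))
  hk <- hk[seq_len(config@nHousekeeping)]
  names(baseline) <- genes
  names(hk_baseline) <- hk

  n <- config@nRefPerSubtype
  subtype <- rep(TP_LEVELS, each = n)
  ids <- sprintf("REF_%s_%03d", subtype, sequence(rep(n, 4)))
  X <- matrix(stats::rnorm(nG * length(ids)), nrow = nG,
              dimnames = list(genes, ids))
  X <- X + baseline + arch[, subtype, drop = FALSE]

  truth <- new("GroundTruth",
               subtypes = setNames(subtype, ids), geneGroups = groups,
               batches = setNames(rep("reference", length(ids)), ids),
               hazardRatio = config@hazardTp1 / config@hazardNonTp1,
               corruptLanes = character(),
               baseline = c(baseline, hk_baseline),
               archetypes = arch,
               batchShifts = numeric(), geneScale = numeric())

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(subtype = factor(subtype,
                                                    levels = TP_LEVELS),
                                   row.names = ids),
    rowData = S4Vectors::DataFrame(pattern_group = groups, row.names = genes))
  list(reference = methods::as(se, "ReferenceSet"), truth = truth)
}

#' Default panel definition matching a simulation config
#'
#' @param config A [SimulationConfig-class].
#' @return A [PanelDefinition-class] with the configured endogenous and
#'   housekeeping probes plus 6 positive and 6 negative controls.
#' @export
defaultPanel <- function(config = SimulationConfig()) {
  nG <- config@nEndogenousGenes
  genes <- sprintf("GENE%03d", seq_len(nG))
  groups <- rep.int(seq_len(config@nPatternGroups),
                    .group_sizes(nG, config@nPatternGroups))
  hk <- HOUSEKEEPING_GENES
  if (config@nHousekeeping > length(hk))
    hk <- c(hk, sprintf("HK%02d", seq_len(config@nHousekeeping - length(hk))))
  hk <- hk[seq_len(config@nHousekeeping)]
  PanelDefinition(
    name = c(genes, hk, names(POS_LADDER), NEG_PROBES),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                     c(nG, length(hk), length(POS_LADDER),
                       length(NEG_PROBES))),
    pattern_group = c(groups, rep(NA_integer_,
                                  length(hk) + length(POS_LADDER) +
                                    length(NEG_PROBES))))
}

# draw counts: NB on a log2-mean; dispersion 0 is the deterministic
# rounded-mean limit
.draw_counts <- function(log2mu, dispersion) {
  mu <- 2^log2mu
  if (dispersion <= 0) return(as.integer(round(mu)))
  as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

.make_lane <- function(id, cartridge, endoCounts, hkCounts, posCounts,
                       negCounts, bindingDensity, fovCounted = 555L,
                       fovCount = 555L) {
  counts <- data.frame(
    CodeClass = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                    c(length(endoCounts), length(hkCounts),
                      length(posCounts), length(negCounts))),
    Name = c(names(endoCounts), names(hkCounts), names(posCounts),
             names(negCounts)),
    Accession = "synthetic",
    Count = c(endoCounts, hkCounts, posCounts, negCounts),
    row.names = NULL, stringsAsFactors = FALSE)
  RccLane(id, list(ID = id, CartridgeID = cartridge, Date = "20260101",
                   FovCount = fovCount, FovCounted = fovCounted,
                   BindingDensity = bindingDensity),
          counts)
}

# counts for one lane of a given subtype; positive ladder scaled by 30
# counts per concentration unit
.simulate_lane <- function(config, truth, id, subtype, cartridge,
                           laneScale, corrupt = FALSE, log2jitter = NULL) {
  genes <- names(truth@geneGroups)
  hk <- setdiff(names(truth@baseline), genes)
  lmu_endo <- truth@baseline[genes] + truth@archetypes[genes, subtype] +
    truth@batchShifts[genes] + log2(laneScale)
  lmu_hk <- truth@baseline[hk] + log2(laneScale)
  if (!is.null(log2jitter)) {
    lmu_endo <- lmu_endo + log2jitter[genes]
    lmu_hk <- lmu_hk + log2jitter[hk]
  }
  disp_endo <- config@nbDispersion * truth@geneScale[genes]
  endo <- setNames(mapply(.draw_counts, lmu_endo, disp_endo), genes)
  hkc <- setNames(.draw_counts(lmu_hk, config@nbDispersion), hk)
  pos_mu <- POS_LADDER * 30 * laneScale
  # corruption flattens the ladder at its geometric mean: linearity is
  # destroyed while the lane's positive geomean (hence factors) is preserved
  if (corrupt) pos_mu <- rep(exp(mean(log(pos_mu))), length(pos_mu))
  pos <- setNames(.draw_counts(log2(pos_mu), config@nbDispersion),
                  names(POS_LADDER))
  neg <- setNames(as.integer(stats::rpois(length(NEG_PROBES), 2)),
                  NEG_PROBES)
  bd <- round(stats::runif(1, 0.5, 2.0), 3)
  .make_lane(id, cartridge, endo, hkc, pos, neg, bindingDensity = bd)
}

# ensure the truth carries test-platform parameters (batch shift, per-gene
# dispersion scale), drawing them once
.ensure_platform <- function(config, truth) {
  if (length(truth@batchShifts)) return(truth)
  all_probes <- names(truth@baseline)
  truth@batchShifts <- setNames(
    stats::rnorm(length(all_probes), 0, config@batchShift), all_probes)
  genes <- names(truth@geneGroups)
  truth@geneScale <- setNames(
    exp(stats::rnorm(length(genes), 0, config@batchScaleSd)), genes)
  truth
}

#' Generate RCC-style test lanes
#'
#' Draws `nTestSamples` lanes whose endogenous and housekeeping counts are
#' negative-binomial with log2-mean = subtype archetype + per-gene batch
#' shift + lane log-scale; positive-control counts follow the 6-point
#' spike-in ladder and negative controls stay near zero. A configurable
#' fraction of lanes is generated with corrupted (flat) positive controls
#' to exercise QC.
#'
#' @param config A [SimulationConfig-class].
#' @param truth The [GroundTruth-class] returned by [generateReference()].
#' @param seed seed for this stage (defaults to `config@seed + 1`).
#' @return A list with `lanes` (list of [RccLane-class]) and the updated
#'   `truth` covering the new samples.
#' @export
generateTestLanes <- function(config, truth, seed = config@seed + 1L) {
  validObject(config)
  if (!length(truth@subtypes)) stop("generate the reference first")
  set.seed(seed)
  truth <- .ensure_platform(config, truth)
  n <- config@nTestSamples
  # TP1-dominant cohort, emulating a glioblastoma-rich archive
  subtype <- sample(TP_LEVELS, n, replace = TRUE,
                    prob = c(0.5, 0.17, 0.17, 0.16))
  ids <- sprintf("AU%03d", seq_len(n))
  nCorrupt <- round(config@corruptFraction * n)
  corrupt <- ids %in% sample(ids, nCorrupt)
  cartridge <- sprintf("CART%02d", (seq_len(n) - 1L) %/% 12L + 1L)
  scales <- stats::runif(n, config@laneScaleRange[1], config@laneScaleRange[2])
  lanes <- vector("list", n)
  for (i in seq_len(n))
    lanes[[i]] <- .simulate_lane(config, truth, ids[i], subtype[i],
                                 cartridge[i], scales[i],
                                 corrupt = corrupt[i])
  names(lanes) <- ids
  truth@subtypes <- c(truth@subtypes, setNames(subtype, ids))
  truth@batches <- c(truth@batches, setNames(rep("test", n), ids))
  truth@corruptLanes <- c(truth@corruptLanes, ids[corrupt])
  list(lanes = lanes, truth = truth)
}

#' Generate a pair of technical-replicate lanes
#'
#' Two lanes of the same underlying sample: both share the sample's
#' expected log2 counts, each receives an independent per-gene
#' N(0, `replicateNoiseSd`) log2 jitter before counts are drawn.
#'
#' @param config A [SimulationConfig-class].
#' @param truth A [GroundTruth-class] (platform parameters are drawn on
#'   first use).
#' @param subtype the sample's subtype.
#' @param idPrefix sample id prefix; replicate lanes are `<prefix>_repA`
#'   and `<prefix>_repB`.
#' @return list of two [RccLane-class] objects.
#' @export
generateReplicatePair <- function(config, truth, subtype = "TP1",
                                  idPrefix = "REP") {
  truth <- .ensure_platform(config, truth)
  probes <- names(truth@baseline)
  scale <- stats::runif(1, config@laneScaleRange[1], config@laneScaleRange[2])
  lapply(c("A", "B"), function(r) {
    jit <- setNames(stats::rnorm(length(probes), 0, config@replicateNoiseSd),
                    probes)
    .simulate_lane(config, truth, paste0(idPrefix, "_rep", r), subtype,
                   "CARTREP", scale, log2jitter = jit)
  })
}

#' Generate a survival table
#'
#' Exponential event times with hazard `hazardTp1` for TP1 samples and
#' `hazardNonTp1` otherwise, independently right-censored by an exponential
#' censoring stream (covering both loss to follow-up and unrelated death).
#'
#' @param truth A [GroundTruth-class] whose samples to draw survival for.
#' @param config A [SimulationConfig-class].
#' @param samples sample ids (default: all non-reference samples, or all
#'   samples if none are marked as test).
#' @param seed seed for this stage (defaults to `config@seed + 2`).
#' @return data.frame `sample_id`, `time_months`, `event`.
#' @export
generateSurvival <- function(truth, config, samples = NULL,
                             seed = config@seed + 2L) {
  if (config@hazardTp1 <= 0 || config@hazardNonTp1 <= 0)
    stop("invalid config: hazards must be positive")
  if (is.null(samples)) {
    samples <- names(truth@subtypes)[truth@batches[names(truth@subtypes)] !=
                                       "reference"]
    if (!length(samples)) samples <- names(truth@subtypes)
  }
  if (anyNA(truth@subtypes[samples]))
    stop("every sample needs a subtype in the ground truth")
  set.seed(seed)
  rate <- ifelse(truth@subtypes[samples] == "TP1",
                 config@hazardTp1, config@hazardNonTp1)
  event_time <- stats::rexp(length(samples), rate)
  censor_time <- if (config@censoringRate > 0)
    stats::rexp(length(samples), config@censoringRate) else Inf
  data.frame(sample_id = samples,
             time_months = pmin(event_time, censor_time),
             event = as.integer(event_time <= censor_time),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize ground truth to JSON
#'
#' @param truth A [GroundTruth-class].
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    subtypes = as.list(truth@subtypes),
    gene_groups = as.list(truth@geneGroups),
    batches = as.list(truth@batches),
    hazard_ratio = truth@hazardRatio,
    corrupt_lanes = truth@corruptLanes), path, auto_unbox = TRUE)
  invisible(path)
}
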