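# Synthetic-data generators: determinism, generative-model fidelity,
# RCC round-tripping, and survival generation.

test_that("reference generation is seeded-deterministic with the stated structure", {
  cfg <- SimulationConfig(nRefPerSubtype = 20L, seed = 11L)
  a <- generateReference(cfg)
  b <- generateReference(cfg)
  expect_identical(SummarizedExperiment::assay(a$reference),
                   SummarizedExperiment::assay(b$reference))
  X <- SummarizedExperiment::assay(a$reference)
  expect_equal(dim(X), c(160L, 80L))
  expect_equal(as.integer(table(refSubtypes(a$reference))), rep(20L, 4))
  # six pattern groups, sizes non-increasing, covering all genes
  sizes <- as.integer(table(trueGeneGroups(a$truth)))
  expect_length(sizes, 6L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sum(sizes), 160L)
})

test_that("a null subtype effect produces equal subtype means", {
  cfg <- SimulationConfig(nRefPerSubtype = 50L, subtypeEffectSd = 0,
                          seed = 5L)
  ref <- generateReference(cfg)
  expect_true(all(ref$truth@archetypes == 0))
  X <- SummarizedExperiment::assay(ref$reference)
  labs <- refSubtypes(ref$reference)
  means <- vapply(TP_LEVELS, function(s) rowMeans(X[, labs == s]),
                  numeric(nrow(X)))
  # only sampling noise (SE ~ 1/sqrt(50)) separates the subtype means
  expect_lt(max(abs(means - rowMeans(means))), 0.8)
})

test_that("too-small reference cohorts are rejected", {
  expect_error(generateReference(SimulationConfig(nRefPerSubtype = 1L)),
               "at least 2")
})

test_that("lane counts reproduce their negative-binomial means", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, nTestSamples = 1000L,
                          laneScaleRange = c(1, 1), batchShift = 0,
                          batchScaleSd = 0, nbDispersion = 0.05, seed = 21L)
  ref <- generateReference(cfg)
  tl <- generateTestLanes(cfg, ref$truth)
  subtypes <- trueSubtypes(tl$truth)[names(tl$lanes)]
  tp1 <- names(subtypes)[subtypes == "TP1"]
  counts <- vapply(tl$lanes[tp1], laneCounts, codeClass = "Endogenous",
                   numeric(160))
  mu <- 2^(tl$truth@baseline[rownames(counts)] +
             tl$truth@archetypes[rownames(counts), "TP1"])
  hi <- mu > 20 # relative error is meaningful for well-expressed genes
  rel <- abs(rowMeans(counts)[hi] - mu[hi]) / mu[hi]
  expect_lt(stats::quantile(rel, 0.9), 0.05)
})

test_that("the noise-free limit yields rounded means and identical replicates", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, nTestSamples = 4L,
                          nbDispersion = 0, laneScaleRange = c(1, 1),
                          batchShift = 0, batchScaleSd = 0,
                          replicateNoiseSd = 0, seed = 3L)
  ref <- generateReference(cfg)
  tl <- generateTestLanes(cfg, ref$truth)
  lane <- tl$lanes[[1]]
  s <- trueSubtypes(tl$truth)[laneSampleId(lane)]
  mu <- 2^(tl$truth@baseline[names(trueGeneGroups(tl$truth))] +
             tl$truth@archetypes[, s])
  expect_equal(unname(laneCounts(lane, "Endogenous")), unname(round(mu)))
  pair <- generateReplicatePair(cfg, tl$truth, subtype = "TP2a")
  expect_identical(laneCounts(pair[[1]], "Endogenous"),
                   laneCounts(pair[[2]], "Endogenous"))
})

test_that("technical replicates are tightly correlated on the log2 scale", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, replicateNoiseSd = 0.05,
                          seed = 31L)
  ref <- generateReference(cfg)
  truth <- generateTestLanes(cfg, ref$truth, seed = 32L)$truth
  set.seed(33)
  r <- replicate(100, {
    pair <- generateReplicatePair(cfg, truth)
    cor(log2(laneCounts(pair[[1]], "Endogenous") + 1),
        log2(laneCounts(pair[[2]], "Endogenous") + 1))
  })
  expect_gt(mean(r), 0.98)
})

test_that("corrupted lanes are marked in the ground truth", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, nTestSamples = 20L,
                          corruptFraction = 0.25, seed = 41L)
  ref <- generateReference(cfg)
  tl <- generateTestLanes(cfg, ref$truth)
  expect_length(tl$truth@corruptLanes, 5L)
  expect_true(all(tl$truth@corruptLanes %in% names(tl$lanes)))
})

test_that("survival generation recovers the null and degenerate regimes", {
  cfg_null <- SimulationConfig(nRefPerSubtype = 2L,
                               hazardTp1 = 0.05, hazardNonTp1 = 0.05,
                               censoringRate = 0, seed = 51L)
  truth <- new("GroundTruth",
               subtypes = setNames(rep(c("TP1", "TP2a"), each = 100),
                                   sprintf("S%03d", 1:200)),
               geneGroups = integer(), batches = setNames(
                 rep("test", 200), sprintf("S%03d", 1:200)),
               hazardRatio = 1, corruptLanes = character(),
               baseline = numeric(), archetypes = matrix(0, 0, 0),
               batchShifts = numeric(), geneScale = numeric())
  hrs <- ps <- numeric(40)
  for (i in seq_len(40)) {
    st <- generateSurvival(truth, cfg_null, seed = 1000L + i)
    st$group <- ifelse(trueSubtypes(truth)[st$sample_id] == "TP1",
                       "TP1", "non-TP1")
    hrs[i] <- coxBinary(st)$HR
    ps[i] <- logrankTest(st)$p
  }
  expect_lt(abs(mean(log(hrs))), 0.15)         # HR centered on 1
  expect_lte(mean(ps < 0.05), 0.15)            # near-nominal false positives
  # extreme censoring: everything censored near zero, median not reached
  cfg_cens <- SimulationConfig(nRefPerSubtype = 2L, censoringRate = 1e6,
                               seed = 52L)
  st <- generateSurvival(truth, cfg_cens)
  expect_true(all(st$event == 0L))
  km <- kmEstimate(st)
  expect_true(is.na(km$median))
  expect_error(SimulationConfig(hazardTp1 = 0), "hazards")
})

test_that("RCC files round-trip losslessly, one file per lane", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, nTestSamples = 12L,
                          seed = 61L)
  ref <- generateReference(cfg)
  tl <- generateTestLanes(cfg, ref$truth)
  dir <- withr::local_tempdir()
  paths <- writeRccSet(tl$lanes, dir)
  expect_length(paths, 12L)
  expect_setequal(basename(paths), paste0(names(tl$lanes), ".rcc"))
  back <- readRccSet(dir)
  for (id in names(tl$lanes)) {
    expect_identical(back[[id]]@counts, tl$lanes[[id]]@counts)
    expect_identical(back[[id]]@attributes, tl$lanes[[id]]@attributes)
  }
  # a zero count must serialize as the digit 0, not a blank field
  lane <- tl$lanes[[1]]
  lane@counts$Count[3] <- 0L
  p <- file.path(dir, "zero.rcc")
  writeRcc(lane, p)
  line <- grep(paste0("^", lane@counts$CodeClass[3]), readLines(p),
               value = TRUE)[3]
  expect_match(line, ",0$")
  expect_identical(readRcc(p)@counts$Count[3], 0L)
})
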