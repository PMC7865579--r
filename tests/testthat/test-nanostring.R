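# RCC parsing, geometric-mean normalization arithmetic, QC flags, and
# replicate concordance.

test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometricMean(c(2, 8)), 4)
  expect_equal(geometricMean(5), 5)
  expect_equal(geometricMean(c(1, 10, 100)), 10)
  expect_error(geometricMean(numeric()), "empty")
  expect_error(geometricMean(c(2, -1)), "non-negative")
})

test_that("normalization factors follow the cohort-mean / lane-geomean rule", {
  lanes <- toy_lanes(c(100L, 200L, 400L))
  f <- vapply(lanes, normalizationFactor, numeric(1), cohort = lanes,
              which = "Housekeeping")
  expect_equal(f, c(7 / 3, 7 / 6, 7 / 12))
  # all lanes identical -> unit factors; single-lane cohort -> unit factor
  same <- toy_lanes(c(150L, 150L, 150L))
  expect_equal(vapply(same, normalizationFactor, numeric(1), cohort = same,
                      which = "Housekeeping"), rep(1, 3))
  expect_equal(normalizationFactor(same[[1]], same[1], "Housekeeping"), 1)
  # an all-zero lane is a QC failure signal, not a factor
  zero <- toy_lanes(c(0L, 200L, 400L))
  expect_true(is.na(normalizationFactor(zero[[1]], zero, "Housekeeping")))
  expect_error(normalizationFactor(lanes[[1]], lanes[2:3], "Housekeeping"),
               "not in the cohort")
})

test_that("QC flags clean, corrupted, and out-of-range lanes correctly", {
  cfg <- SimulationConfig(nRefPerSubtype = 2L, nTestSamples = 20L,
                          nbDispersion = 0, corruptFraction = 0.2,
                          seed = 71L)
  ref <- generateReference(cfg)
  tl <- generateTestLanes(cfg, ref$truth)
  qc <- qcLanes(tl$lanes)
  fl <- qcFlags(qc)
  corrupt <- fl$sample_id %in% tl$truth@corruptLanes
  expect_true(all(fl$pass[!corrupt]))                # clean lanes: 100% pass
  expect_true(all(!fl$pass[corrupt]))                # corrupted lanes: 0%
  expect_true(all(!fl$pos_linearity[corrupt]))       # and for that reason
  # imaging flag: low field-of-view ratio fails
  bad <- tl$lanes[[1]]
  bad@attributes$FovCounted <- 300L
  expect_false(qcLane(bad, tl$lanes)["imaging"][[1]])
  # factor-range flag: a lane counting far below the cohort fails
  dim_lane <- tl$lanes[[2]]
  dim_lane@counts$Count <- as.integer(ceiling(dim_lane@counts$Count / 20))
  cohort <- c(tl$lanes[names(tl$lanes) != laneSampleId(dim_lane)],
              list(dim_lane))
  row <- qcLane(dim_lane, cohort)
  expect_false(row$pos_factor)
})

test_that("normalization equalizes housekeeping geomeans and ignores lane scale", {
  sc <- small_cohort()
  norm <- sc$norm
  fac <- normFactors(norm)
  # housekeeping geometric means after both factors agree to 1e-9 (log2)
  hk_after <- vapply(seq_len(nrow(fac)), function(i) {
    cts <- laneCounts(sc$lanes[[fac$sample_id[i]]], "Housekeeping") *
      fac$pos_factor[i]
    cts[cts == 0] <- 1
    log2(geometricMean(cts) * fac$hk_factor[i])
  }, numeric(1))
  expect_lt(max(hk_after) - min(hk_after), 1e-9)
  # a lane that is another lane with every count doubled normalizes to an
  # identical column: per-lane scale cancels through the factor algebra
  lanes <- sc$lanes[qcPassed(sc$qc)][1:4]
  doubled <- lanes[[1]]
  doubled@sampleId <- "doubled"
  doubled@attributes$ID <- "doubled"
  doubled@counts$Count <- doubled@counts$Count * 2L
  m1 <- SummarizedExperiment::assay(
    normalizeLanes(c(lanes, list(doubled)), sc$panel))
  expect_equal(unname(m1[, 1]), unname(m1[, "doubled"]), tolerance = 1e-12)
  # two identical lanes normalize to identical columns
  twin <- lanes[c(1, 1)]
  twin[[2]]@sampleId <- "copy"
  twin[[2]]@attributes$ID <- "copy"
  m3 <- SummarizedExperiment::assay(normalizeLanes(twin, sc$panel))
  expect_equal(unname(m3[, 1]), unname(m3[, 2]))
  # zero raw count maps to log2(1) = 0
  z <- lanes
  z[[1]]@counts$Count[1] <- 0L
  mz <- SummarizedExperiment::assay(normalizeLanes(z, sc$panel))
  expect_equal(unname(mz[z[[1]]@counts$Name[1], 1]), 0)
  # failing lanes are refused by id
  badlanes <- sc$lanes
  badlanes[[1]]@attributes$FovCounted <- 100L
  expect_error(normalizeLanes(badlanes, sc$panel, qc = qcLanes(badlanes)),
               "refusing")
  expect_error(normalizeLanes(lanes[1], sc$panel), "at least 2")
})

test_that("malformed RCC files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  sc <- small_cohort()
  lane <- sc$lanes[[1]]
  p <- file.path(dir, "ok.rcc")
  writeRcc(lane, p)
  # round trip through the reader
  expect_identical(readRcc(p)@counts, lane@counts)
  # missing Lane_Attributes
  lines <- readLines(p)
  drop <- setdiff(seq_along(lines),
                  seq(grep("<Lane_Attributes>", lines),
                      grep("</Lane_Attributes>", lines)))
  writeLines(lines[drop], file.path(dir, "noattr.rcc"))
  expect_error(readRcc(file.path(dir, "noattr.rcc")), "Lane_Attributes")
  # fractional and negative counts are type errors naming the line
  bad <- sub("^(Endogenous,GENE001,[^,]*,)[0-9]+$", "\\112.0", lines)
  writeLines(bad, file.path(dir, "frac.rcc"))
  expect_error(readRcc(file.path(dir, "frac.rcc")), "12\\.0")
  bad2 <- sub("^(Endogenous,GENE002,[^,]*,)[0-9]+$", "\\1-3", lines)
  writeLines(bad2, file.path(dir, "neg.rcc"))
  expect_error(readRcc(file.path(dir, "neg.rcc")), "not a non-negative")
  # unbalanced section marker
  writeLines(lines[-grep("</Code_Summary>", lines)],
             file.path(dir, "unbal.rcc"))
  expect_error(readRcc(file.path(dir, "unbal.rcc")), "section")
  # unknown probes are reported, not dropped; missing panel probes error
  extra <- append(lines, "Endogenous,MYSTERY,x,5",
                  after = grep("^CodeClass", lines))
  writeLines(extra, file.path(dir, "extra.rcc"))
  expect_warning(l2 <- readRcc(file.path(dir, "extra.rcc"),
                               panel = sc$panel), "MYSTERY")
  expect_true("MYSTERY" %in% l2@counts$Name)
  short <- lines[!grepl("^Endogenous,GENE001,", lines)]
  writeLines(short, file.path(dir, "short.rcc"))
  expect_error(readRcc(file.path(dir, "short.rcc"), panel = sc$panel),
               "GENE001")
})

test_that("replicate concordance reports exact and simulated correlations", {
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1,
                5, 5, 5, 5), nrow = 4,
              dimnames = list(paste0("g", 1:4),
                              c("a", "a2", "neg", "const")))
  rc <- replicateConcordance(m, list(c("a", "a2")))
  expect_equal(rc$pairs$r, 1)
  expect_equal(replicateConcordance(m, list(c("a", "neg")))$pairs$r, -1)
  expect_true(is.na(replicateConcordance(m,
                                         list(c("a", "const")))$pairs$r))
  expect_error(replicateConcordance(m, list(c("a", "nope"))), "absent")

  # simulated technical replicates at the default noise level
  sr <- small_reference()
  cfg <- sr$config
  truth <- generateTestLanes(cfg, sr$truth, seed = 81L)$truth
  set.seed(82)
  lanes <- list()
  pairs <- list()
  for (i in 1:25) {
    pr <- generateReplicatePair(cfg, truth, subtype = sample(TP_LEVELS, 1),
                                idPrefix = sprintf("R%02d", i))
    lanes <- c(lanes, pr)
    pairs[[i]] <- vapply(pr, laneSampleId, character(1))
  }
  norm <- normalizeLanes(lanes, defaultPanel(cfg))
  rc <- replicateConcordance(norm, pairs)
  expect_gt(rc$average, 0.98)
})
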