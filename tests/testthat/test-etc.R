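# The ensemble classifier: base linear SVM, gene-group partition,
# stratified subsampling, RFE, dictionary construction, and voting.

test_that("the linear classifier separates separable clouds and not XOR", {
  set.seed(1)
  p <- 10
  X <- cbind(matrix(rnorm(30 * p), p), matrix(rnorm(30 * p, 2.5), p))
  lab <- rep(c("A", "B"), each = 30)
  fit <- fitLinearClassifier(X, lab)
  expect_equal(mean(predict(fit, X) == lab), 1)
  # XOR-style clouds are not linearly separable: far from perfect
  centers <- cbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  Xx <- centers[, rep(1:4, each = 80)] + matrix(rnorm(2 * 320, 0, 0.15), 2)
  yx <- rep(c("A", "A", "B", "B"), each = 80)
  fx <- fitLinearClassifier(Xx, yx)
  expect_lt(mean(predict(fx, Xx) == yx), 0.85)
  expect_error(fitLinearClassifier(X, rep("A", 60)), "2 classes")
})

test_that("the solver agrees with an independent SVM implementation", {
  set.seed(2)
  p <- 8
  X <- cbind(matrix(rnorm(40 * p), p), matrix(rnorm(40 * p, 1.5), p))
  lab <- rep(c("A", "B"), each = 40)
  fit <- fitLinearClassifier(X, lab)
  Xte <- cbind(matrix(rnorm(60 * p), p), matrix(rnorm(60 * p, 1.5), p))
  sv <- e1071::svm(x = t(X), y = factor(lab), kernel = "linear", cost = 1,
                   scale = FALSE)
  expect_gte(mean(predict(fit, Xte) ==
                    as.character(predict(sv, t(Xte)))), 0.98)
})

test_that("relabelling classes permutes the decision functions", {
  set.seed(3)
  p <- 6
  X <- cbind(matrix(rnorm(25 * p), p), matrix(rnorm(25 * p, 2), p),
             matrix(rnorm(25 * p, -2), p))
  lab <- rep(c("A", "B", "C"), each = 25)
  swap <- c(A = "C", B = "B", C = "A")
  f1 <- fitLinearClassifier(X, lab)
  f2 <- fitLinearClassifier(X, unname(swap[lab]))
  Xte <- X + rnorm(length(X), 0, 0.1)
  expect_identical(unname(swap[predict(f1, Xte)]),
                   unname(predict(f2, Xte)))
})

test_that("gene partition recovers the generative groups and is order-invariant", {
  sr <- small_reference()
  expect_gte(mclust::adjustedRandIndex(sr$partition,
                                       trueGeneGroups(sr$truth)), 0.9)
  # permuting sample order changes nothing
  set.seed(101)
  perm <- sample(ncol(sr$X))
  set.seed(101)
  part2 <- partitionGenes(sr$X[, perm], sr$labels[perm])
  expect_identical(sr$partition, part2)
  # degenerate input: identical genes cannot form 6 groups
  flat <- matrix(1:20, nrow = 10, ncol = 20, byrow = TRUE,
                 dimnames = list(paste0("g", 1:10), NULL))
  expect_error(partitionGenes(flat, rep(TP_LEVELS, each = 5)),
               "distinct")
})

test_that("gene subsets take ceiling(m/2) from every group", {
  part <- setNames(rep.int(1:6, c(30, 30, 30, 30, 20, 20)),
                   sprintf("G%03d", 1:160))
  set.seed(7)
  sub <- sampleGeneSubset(part)
  expect_length(sub, 80L)
  for (g in 1:6)
    expect_equal(sum(part[sub] == g), ceiling(sum(part == g) / 2))
  # a singleton group is always selected
  part1 <- setNames(c(1L, 2L, 2L, 2L), c("solo", "a", "b", "c"))
  expect_true(all(replicate(10, "solo" %in% sampleGeneSubset(part1))))
  # same RNG state, same draw
  set.seed(8)
  s1 <- sampleGeneSubset(part)
  set.seed(8)
  s2 <- sampleGeneSubset(part)
  expect_identical(s1, s2)
})

test_that("RFE keeps signal genes and honors the step and tie rules", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(900 + s)
    n_per <- 30
    signal <- matrix(0, 10, 4 * n_per)
    mu <- rbind(c(3, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 3, 0),
                c(0, 0, 0, 3))[rep(1:4, length.out = 10), ]
    for (cl in 1:4)
      signal[, ((cl - 1) * n_per + 1):(cl * n_per)] <-
        mu[, cl] + rnorm(10 * n_per)
    noise <- matrix(rnorm(70 * 4 * n_per), 70)
    X <- rbind(signal, noise)
    rownames(X) <- c(paste0("sig", 1:10), paste0("noise", 1:70))
    lab <- rep(TP_LEVELS, each = n_per)
    spec <- rfeSelect(X, lab, rownames(X))
    if (sum(grepl("^sig", spec@genes)) >= 8) hits <- hits + 1L
  }
  expect_gte(hits, 18L) # >= 90% of runs keep >= 8 of the 10 signal genes

  # step larger than the subset: one elimination straight to the floor
  set.seed(20)
  X <- matrix(rnorm(12 * 80), 12, dimnames = list(paste0("g", 1:12), NULL))
  X[1:4, 1:40] <- X[1:4, 1:40] + 3
  lab <- rep(c("A", "B"), each = 40)
  spec <- rfeSelect(X, lab, rownames(X), step = 50L)
  expect_equal(spec@trajectory$size, c(12L, 5L))
  # smallest subset wins accuracy ties
  best <- min(spec@trajectory$size[spec@trajectory$accuracy ==
                                     max(spec@trajectory$accuracy)])
  expect_equal(length(spec@genes), best)
  expect_error(rfeSelect(X, lab, rownames(X)[1:3]), "smaller than")
})

test_that("dictionary construction is deterministic and filtered", {
  sr <- small_reference()
  d1 <- buildDictionary(sr$X, sr$labels, sr$partition, nModels = 8L,
                        seed = 5L)
  d2 <- buildDictionary(sr$X, sr$labels, sr$partition, nModels = 8L,
                        seed = 5L)
  expect_identical(lapply(d1@models, function(m) m@genes),
                   lapply(d2@models, function(m) m@genes))
  expect_identical(lapply(d1@models, function(m) m@weights),
                   lapply(d2@models, function(m) m@weights))
  expect_true(all(cvAccuracies(d1) >= d1@threshold))
  expect_equal(nModels(d1) + length(d1@discardedAccuracies), 8L)
  # no signal: every model is filtered out, with an informative error
  cfg0 <- SimulationConfig(nRefPerSubtype = 12L, subtypeEffectSd = 0,
                           seed = 6L)
  ref0 <- generateReference(cfg0)
  X0 <- standardizeMatrix(SummarizedExperiment::assay(ref0$reference))
  part0 <- setNames(rep.int(1:6, c(27, 27, 27, 27, 26, 26)),
                    rownames(X0))
  expect_error(buildDictionary(X0, refSubtypes(ref0$reference), part0,
                               nModels = 3L, seed = 7L),
               "below the accuracy threshold")
})

test_that("the confidence rule reproduces its worked examples", {
  # c = 3 exactly is not enough to call
  r <- confidenceRule(c(TP1 = 600, TP2a = 200, TP2b = 150, TP3 = 50))
  expect_equal(r$confidence, 3)
  expect_equal(r$label, "Ambiguous")
  # unanimity: p2 = 0, infinite confidence, call stands
  r2 <- confidenceRule(c(TP1 = 1000, TP2a = 0, TP2b = 0, TP3 = 0))
  expect_equal(r2$p2, 0)
  expect_identical(r2$confidence, Inf)
  expect_equal(r2$label, "TP1")
  # clear plurality
  r3 <- confidenceRule(c(TP1 = 900, TP2a = 50, TP2b = 30, TP3 = 20))
  expect_equal(r3$confidence, 18)
  expect_equal(r3$label, "TP1")
  # exact tie for the top: c = 1, always ambiguous
  r4 <- confidenceRule(c(TP1 = 400, TP2a = 400, TP2b = 150, TP3 = 50))
  expect_equal(r4$confidence, 1)
  expect_equal(r4$label, "Ambiguous")
  expect_error(confidenceRule(c(TP1 = 0, TP2a = 0)), "no votes")
})

test_that("ensemble calls equal an exhaustive hand computation", {
  # three fixed linear models over two features, four hand-placed samples
  W1 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  W2 <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  W3 <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1), c(0, 0, -2))
  dict <- hand_dictionary(list(hand_model(W1, c("g1", "g2")),
                               hand_model(W2, c("g1", "g2")),
                               hand_model(W3, c("g1", "g2"))))
  X <- cbind(s1 = c(2, 0.5), s2 = c(-1, 2), s3 = c(0.2, -3),
             s4 = c(-2, -2))
  rownames(X) <- c("g1", "g2")
  calls <- classifySamples(dict, X)

  # independent oracle: explicit loops over models, classes, samples
  expected <- lapply(colnames(X), function(s) {
    tally <- setNames(numeric(4), TP_LEVELS)
    for (W in list(W1, W2, W3)) {
      scores <- numeric(4)
      for (k in 1:4)
        scores[k] <- W[k, 1] * X[1, s] + W[k, 2] * X[2, s] + W[k, 3]
      win <- TP_LEVELS[which.max(scores)]
      tally[win] <- tally[win] + 1
    }
    srt <- sort(tally, decreasing = TRUE)
    conf <- if (srt[2] == 0) Inf else unname(srt[1] / srt[2])
    list(votes = tally,
         label = if (conf > 3) names(srt)[1] else "Ambiguous",
         conf = conf)
  })
  ct <- callTable(calls)
  for (i in seq_along(expected)) {
    expect_equal(unlist(ct[i, TP_LEVELS]),
                 expected[[i]]$votes, ignore_attr = TRUE)
    expect_equal(ct$label[i], expected[[i]]$label)
    expect_equal(ct$confidence[i], expected[[i]]$conf)
  }
  # vote fractions sum to one and confidence is never below one
  expect_true(all(abs(ct$p1 + ct$p2 +
                        (1 - ct$p1 - ct$p2) - 1) < 1e-12))
  expect_true(all(ct$confidence >= 1))
})

test_that("out-of-fold calls are leakage-free and accurately recover subtypes", {
  cfg <- SimulationConfig(nRefPerSubtype = 40L, subtypeEffectSd = 3,
                          seed = 17L)
  ref <- generateReference(cfg)
  X <- standardizeMatrix(SummarizedExperiment::assay(ref$reference))
  labels <- refSubtypes(ref$reference)
  set.seed(17)
  part <- partitionGenes(X, labels)
  oof <- outOfFoldCalls(X, labels, part, folds = 4L, nModels = 20L,
                        seed = 17L)
  ct <- callTable(oof$calls)
  # accounting: each sample's votes total its fold dictionary's size
  totals <- rowSums(ct[, TP_LEVELS])
  expect_identical(unname(totals),
                   unname(oof$nVotesPerFold[
                     oof$foldAssignments[ct$sample_id]]) + 0)
  # subtype recovery among non-ambiguous calls
  lab_call <- callLabels(oof$calls)
  nona <- lab_call != "Ambiguous"
  expect_gte(mean(lab_call[nona] == labels[names(lab_call)[nona]]), 0.95)
})
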