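# Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small labelled reference (30/subtype) with standardized matrix + partition
small_reference <- function() fixture("small_reference", function() {
  cfg <- SimulationConfig(nRefPerSubtype = 30L, nTestSamples = 24L,
                          seed = 101L)
  ref <- generateReference(cfg)
  X <- standardizeMatrix(SummarizedExperiment::assay(ref$reference))
  labels <- refSubtypes(ref$reference)
  set.seed(101)
  part <- partitionGenes(X, labels)
  list(config = cfg, ref = ref$reference, truth = ref$truth, X = X,
       labels = labels, partition = part)
})

# a normalized small test cohort sharing the small reference's archetypes
small_cohort <- function() fixture("small_cohort", function() {
  sr <- small_reference()
  tl <- generateTestLanes(sr$config, sr$truth)
  panel <- defaultPanel(sr$config)
  qc <- qcLanes(tl$lanes)
  norm <- normalizeLanes(tl$lanes[qcPassed(qc)], panel, qc = qc)
  list(lanes = tl$lanes, truth = tl$truth, panel = panel, qc = qc,
       norm = norm)
})

# three hand-made toy lanes with a 3-probe panel for factor arithmetic
toy_lanes <- function(hk_counts = c(100L, 200L, 400L)) {
  lapply(seq_along(hk_counts), function(i) {
    RccLane(paste0("L", i),
            list(ID = paste0("L", i), CartridgeID = "C1",
                 FovCount = 555L, FovCounted = 555L, BindingDensity = 1.0),
            data.frame(
              CodeClass = c("Endogenous", "Housekeeping", "Positive"),
              Name = c("G1", "HK1", "POS_A"),
              Accession = "x",
              Count = c(50L, hk_counts[i], 1000L),
              stringsAsFactors = FALSE))
  })
}

# deterministic hand-built linear model for ensemble-oracle tests:
# decision rows are supplied directly
hand_model <- function(W, genes, acc = 1) {
  rownames(W) <- TP_LEVELS
  new("ModelSpec", genes = genes, weights = W, classes = TP_LEVELS,
      cvAccuracy = acc,
      trajectory = data.frame(size = length(genes), accuracy = acc))
}

hand_dictionary <- function(models) {
  new("ModelDictionary", models = models, seed = 0, threshold = 0,
      nRequested = length(models), discardedAccuracies = numeric())
}
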