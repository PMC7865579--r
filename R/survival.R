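# TP1 vs non-TP1 survival comparison: Kaplan-Meier curves and medians, the
# two-group log-rank test, and a single-binary-covariate Cox proportional
# hazards fit (Efron tie handling) with Wald CI and likelihood-ratio p.

#' @importFrom survival Surv survfit survdiff coxph
NULL

.check_records <- function(records) {
  stopifnot(all(c("time_months", "event") %in% names(records)))
  if (any(records$time_months <= 0)) stop("survival times must be > 0")
  if (!all(records$event %in% c(0L, 1L))) stop("event must be 0/1")
  records
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator with the standard median convention: the
#' smallest observed time at which the survival curve drops to 0.5 or
#' below, `NA` ("not reached") when it never does.
#'
#' @param records data.frame with `time_months` and `event` (0/1).
#' @return list: `time`, `surv` (right-continuous step function values
#'   after each event time), `median` (NA when not reached), `fit` (the
#'   underlying `survfit` object).
#' @export
kmEstimate <- function(records) {
  records <- .check_records(records)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = records)
  # median convention: smallest time with S(t) <= 0.5, else not reached
  # (survfit's summary table instead midpoints an interval at exactly 0.5)
  idx <- which(fit$surv <= 0.5 + 1e-12)[1]
  med <- if (is.na(idx)) NA_real_ else fit$time[idx]
  list(time = fit$time, surv = fit$surv, median = med, fit = fit)
}

#' Two-group log-rank test
#'
#' Standard chi-square (1 df) log-rank statistic over the pooled event
#' times of two groups.
#'
#' @param records data.frame with `time_months`, `event`, and `group`.
#' @return list `statistic`, `p`.
#' @export
logrankTest <- function(records) {
  records <- .check_records(records)
  groups <- unique(records$group)
  if (length(groups) != 2L) stop("log-rank test needs exactly 2 groups")
  if (any(table(records$group) == 0L)) stop("empty group")
  if (sum(records$event) < 1L) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = records)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit on a binary indicator
#'
#' Partial-likelihood fit of `Surv(time, event) ~ I(group == indicator)`
#' with Efron tie handling. Reports the log hazard ratio, the hazard
#' ratio, the Wald 95% CI `exp(beta +/- 1.96 se)`, and the
#' likelihood-ratio p-value `chi-square(1)` of `2(l(beta) - l(0))`.
#' Monotone-likelihood divergence (all events ordered in one group) is
#' detected and flagged rather than reported as a finite estimate.
#'
#' @param records data.frame with `time_months`, `event`, `group`.
#' @param indicator the group coded 1 (hazard numerator).
#' @return list `logHR`, `HR`, `se`, `ci`, `p_lr`, `diverged`.
#' @export
coxBinary <- function(records, indicator = "TP1") {
  records <- .check_records(records)
  x <- as.integer(records$group == indicator)
  if (length(unique(x)) < 2L)
    stop("both indicator levels must be present")
  for (lev in c(0L, 1L))
    if (sum(records$event[x == lev]) < 1L)
      stop("no events in group ", if (lev) indicator else
        paste0("non-", indicator))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$time_months, records$event) ~ x,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  diverged <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) ||
    se > 1e3
  list(logHR = beta, HR = exp(beta), se = se,
       ci = exp(beta + c(-1.96, 1.96) * se),
       p_lr = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       diverged = diverged)
}

#' Compare survival of TP1 vs non-TP1 calls
#'
#' Joins ensemble calls with a survival table on sample id, dichotomizes
#' into TP1 vs non-TP1, and computes the full comparison: per-group
#' Kaplan-Meier curves and medians, log-rank test, and the binary Cox
#' fit. Ambiguous calls are grouped with non-TP1 by default (they carry
#' confident evidence against TP1), or dropped with
#' `ambiguous = "drop"`.
#'
#' @param calls An [EnsembleCalls-class] (or named character vector of
#'   labels).
#' @param survivalTable data.frame `sample_id`, `time_months`, `event`.
#' @param ambiguous `"non-TP1"` or `"drop"`.
#' @return A [SurvivalComparison-class].
#' @export
compareTP1 <- function(calls, survivalTable, ambiguous = c("non-TP1",
                                                           "drop")) {
  ambiguous <- match.arg(ambiguous)
  labels <- if (methods::is(calls, "EnsembleCalls")) callLabels(calls) else
    calls
  shared <- intersect(names(labels), survivalTable$sample_id)
  if (!length(shared)) stop("no overlap between calls and survival table")
  df <- survivalTable[match(shared, survivalTable$sample_id), , drop = FALSE]
  df$label <- unname(labels[shared])
  if (ambiguous == "drop") df <- df[df$label != "Ambiguous", , drop = FALSE]
  df$group <- ifelse(df$label == "TP1", "TP1", "non-TP1")
  if (length(unique(df$group)) < 2L)
    stop("all samples fall in one group; cannot compare")
  .check_records(df)

  km <- lapply(split(df, df$group), kmEstimate)
  medians <- vapply(km, function(k) k$median %||% NA_real_, numeric(1))
  medians <- setNames(medians[c("TP1", "non-TP1")], c("TP1", "non-TP1"))
  lr <- logrankTest(df)
  cox <- coxBinary(df, indicator = "TP1")
  new("SurvivalComparison",
      km = list(curves = lapply(km, function(k) k[c("time", "surv")]),
                medians = as.list(medians)),
      logrank = lr, cox = cox, data = df)
}

#' Read a survival table CSV (`sample_id,time_months,event`)
#' @param path CSV file.
#' @return data.frame.
#' @export
readSurvivalTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$event <- as.integer(df$event)
  .check_records(df)
}

#' Write a survival table CSV
#' @param table data.frame `sample_id`, `time_months`, `event`.
#' @param path output file.
#' @export
writeSurvivalTable <- function(table, path) {
  write.csv(table[, c("sample_id", "time_months", "event")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
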