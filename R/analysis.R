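#' ConditionSummary: per-condition SBPM summary (mean +/- SEM)
#'
#' @slot condition character label.
#' @slot values numeric, one SBPM value per replicate.
#' @slot mean numeric, sample mean.
#' @slot sem numeric, standard error of the mean (sample SD / sqrt(n),
#'   n - 1 denominator); `NA` with `semDefined = FALSE` when n < 2.
#' @slot n integer, number of replicates.
#' @slot semDefined logical.
#' @name ConditionSummary-class
#' @exportClass ConditionSummary
setClass("ConditionSummary",
  slots = c(condition = "character", values = "numeric", mean = "numeric",
            sem = "numeric", n = "integer", semDefined = "logical"))

setValidity("ConditionSummary", function(object) {
  msgs <- character(0)
  if (object@n != length(object@values))
    msgs <- c(msgs, "n must equal length(values)")
  if (object@semDefined != (object@n >= 2L))
    msgs <- c(msgs, "semDefined must be TRUE exactly when n >= 2")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConditionSummary", function(object) {
  cat("ConditionSummary '", object@condition, "': ",
      format(object@mean, digits = 4), " +/- ",
      if (object@semDefined) format(object@sem, digits = 4) else "NA",
      " (SEM), n = ", object@n, "\n", sep = "")
})

#' @rdname synchroburst-generics
#' @export
setMethod("conditionLabel", "ConditionSummary", function(x) x@condition)

#' Summarize SBPM values of one condition
#'
#' Mean and standard error of the mean over replicates, as reported for
#' each biological condition (mean +/- SEM). With a single replicate the
#' SEM is flagged undefined rather than guessed.
#'
#' @param label condition label.
#' @param values numeric SBPM values, one per replicate (>= 1).
#' @return A [ConditionSummary-class].
#' @examples
#' summarizeCondition("ctrl", c(4, 5, 6))  # mean 5, sem 0.5774
#' @export
summarizeCondition <- function(label, values) {
  if (length(values) < 1 || anyNA(values))
    stop("at least one non-missing SBPM value is required")
  n <- length(values)
  new("ConditionSummary", condition = as.character(label),
      values = as.numeric(values), mean = mean(values),
      sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
      n = as.integer(n), semDefined = n >= 2L)
}

#' PairwiseComparison: Student's t-test between two conditions
#'
#' @slot labelA,labelB condition labels.
#' @slot tStatistic,df,pValue test statistic, degrees of freedom, two-sided
#'   p-value.
#' @slot paired logical.
#' @slot degenerate logical; `TRUE` when a paired test had all-zero
#'   differences (reported as t = 0, p = 1 rather than an error).
#' @name PairwiseComparison-class
#' @exportClass PairwiseComparison
setClass("PairwiseComparison",
  slots = c(labelA = "character", labelB = "character",
            tStatistic = "numeric", df = "numeric", pValue = "numeric",
            paired = "logical", degenerate = "logical"))

setValidity("PairwiseComparison", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    "pValue must lie in [0, 1]"
  else TRUE
})

setMethod("show", "PairwiseComparison", function(object) {
  cat("PairwiseComparison (", if (object@paired) "paired" else "unpaired",
      " Student's t): ", object@labelA, " vs ", object@labelB, "\n  t = ",
      format(object@tStatistic, digits = 4), ", df = ", object@df,
      ", p = ", format(object@pValue, digits = 4),
      if (object@degenerate) " (degenerate: all differences zero)" else "",
      "\n  note: raw p-value, no multiple-testing correction applied\n",
      sep = "")
})

#' Compare mean SBPM between two conditions (Student's t-test)
#'
#' Two-sided Student's t-test: pooled-variance (classic, equal-variance)
#' for unpaired comparisons, difference-scores for paired ones. Paired
#' comparisons with all differences zero are reported as t = 0, p = 1 with
#' a degeneracy flag. P-values are raw — no multiple-testing correction is
#' applied (mirroring per-pair reporting practice); the normality
#' assumption of the t-test is the caller's to judge.
#'
#' @param a,b [ConditionSummary-class] objects with n >= 2 each; paired
#'   comparisons additionally require equal n with aligned replicate order.
#' @param paired logical.
#' @return A [PairwiseComparison-class].
#' @examples
#' a <- summarizeCondition("glc", c(5, 6, 7, 8))
#' b <- summarizeCondition("dep", c(1, 2, 3, 4))
#' compareConditions(a, b)
#' @export
compareConditions <- function(a, b, paired = FALSE) {
  stopifnot(is(a, "ConditionSummary"), is(b, "ConditionSummary"))
  if (a@n < 2 || b@n < 2)
    stop("both conditions need at least 2 replicates")
  if (paired && a@n != b@n)
    stop("paired comparison requires equal replicate counts")
  if (paired) {
    d <- a@values - b@values
    if (all(d == 0))
      return(new("PairwiseComparison", labelA = a@condition,
                 labelB = b@condition, tStatistic = 0,
                 df = as.numeric(a@n - 1), pValue = 1, paired = TRUE,
                 degenerate = TRUE))
    tt <- stats::t.test(a@values, b@values, paired = TRUE)
  } else {
    tt <- stats::t.test(a@values, b@values, var.equal = TRUE)
  }
  new("PairwiseComparison", labelA = a@condition, labelB = b@condition,
      tStatistic = unname(tt$statistic), df = unname(tt$parameter),
      pValue = tt$p.value, paired = paired, degenerate = FALSE)
}

#' Developmental time-course table of SBPM
#'
#' Runs the synchronous-burst detector on each recording, groups by the
#' `dayFromInduction` metadata, and tabulates per-day mean SBPM, SEM and
#' replicate count — the shape of a network-development time course.
#' Recordings without day metadata are skipped and listed in the `skipped`
#' attribute.
#'
#' @param recordings list of [MEARecording-class] objects carrying
#'   `dayFromInduction`.
#' @param params a [DetectorParams-class].
#' @return data.frame with columns `day`, `meanSBPM`, `sem`, `n`, sorted by
#'   day ascending; attribute `skipped` holds ids of recordings lacking day
#'   metadata.
#' @export
timecourseTable <- function(recordings, params = detectorParams()) {
  stopifnot(is.list(recordings))
  days <- vapply(recordings, function(r) r@dayFromInduction, integer(1))
  ids <- vapply(recordings, function(r) r@recordingId, character(1))
  skipped <- ids[is.na(days)]
  keep <- !is.na(days)
  vals <- vapply(recordings[keep], function(r) sbpm(runDetector(r, params)),
                 numeric(1))
  days <- days[keep]
  out <- do.call(rbind, lapply(sort(unique(days)), function(d) {
    v <- vals[days == d]
    data.frame(day = d, meanSBPM = mean(v),
               sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else
                 NA_real_,
               n = length(v))
  }))
  if (is.null(out))
    out <- data.frame(day = integer(0), meanSBPM = numeric(0),
                      sem = numeric(0), n = integer(0))
  attr(out, "skipped") <- skipped
  out
}
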