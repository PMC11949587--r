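#' Two-sided Wilcoxon rank-sum comparison
#'
#' Compares two independent samples of optimal model parameters (e.g.
#' distributions over initial conditions for two cohorts).  Uses exact
#' null enumeration when `min(n, m) <= 7` and there are no ties, and the
#' normal approximation with tie correction otherwise.  The reported mean
#' difference is `mean(a) - mean(b)`.
#'
#' @param a,b nonempty numeric samples.
#' @return a [CohortComparison-class].
#' @export
wilcoxonRankSum <- function(a, b) {
  stopIfNot(length(a) > 0L && length(b) > 0L, "both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 7L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  new("CohortComparison", test = "rank_sum",
      statistic = unname(ht$statistic), pValue = ht$p.value,
      meanDifference = mean(a) - mean(b),
      n = c(length(a), length(b)))
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Tests whether a sample of paired differences (e.g. seed-paired
#' connectotomy changes, patient minus control) is centred at zero.
#' Zero differences are dropped (with a message); the test is exact for
#' n <= 15 without ties, and the normal approximation with tie correction
#' otherwise.
#'
#' @param diffs nonempty numeric vector of paired differences.
#' @return a [CohortComparison-class]; the mean difference is the mean of
#'   `diffs` including zeros.
#' @export
wilcoxonSignedRank <- function(diffs) {
  stopIfNot(length(diffs) > 0L, "differences must be nonempty")
  nz <- diffs[diffs != 0]
  if (!length(nz))
    stop("all differences are zero; signed-rank test degenerate",
         call. = FALSE)
  if (length(nz) < length(diffs))
    message(length(diffs) - length(nz), " zero difference(s) dropped")
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= 15L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE))
  new("CohortComparison", test = "signed_rank",
      statistic = unname(ht$statistic), pValue = ht$p.value,
      meanDifference = mean(diffs), n = length(nz))
}

#' Pool per-excitability samples into one distribution
#'
#' Concatenates optimal-coupling samples (or connectotomy differences)
#' keyed by excitability into one pooled sample, preserving per-record
#' provenance (lambda, initial-condition index).
#'
#' @param x a [CouplingCurve-class], or a named list (names = lambda) of
#'   numeric vectors.
#' @return data.frame with columns lambda, ic, value.
#' @export
poolAcrossLambda <- function(x) {
  if (is(x, "CouplingCurve")) {
    lst <- lapply(seq_along(x@lambdaValues), function(i) x@optimalK[i, ])
    names(lst) <- as.character(x@lambdaValues)
    x <- lst
  }
  stopIfNot(is.list(x) && length(x) > 0L && !is.null(names(x)),
            "x must be a nonempty named list or CouplingCurve")
  do.call(rbind, lapply(names(x), function(nm)
    data.frame(lambda = as.numeric(nm), ic = seq_along(x[[nm]]),
               value = as.numeric(x[[nm]]))))
}

setMethod("show", "CohortComparison", function(object) {
  cat("CohortComparison (", object@test, "): statistic = ",
      signif(object@statistic, 4), ", p = ", signif(object@pValue, 3),
      ", mean difference = ", signif(object@meanDifference, 4),
      " (n = ", paste(object@n, collapse = ", "), ")\n", sep = "")
})

#' Write comparisons as a summary table CSV
#'
#' One row per comparison: id, test, statistic, p value, mean difference.
#'
#' @param comparisons named list of [CohortComparison-class] objects.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
writeComparisonTable <- function(comparisons, path) {
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cc <- comparisons[[nm]]
    data.frame(id = nm, test = cc@test, statistic = cc@statistic,
               p.value = cc@pValue, mean.difference = cc@meanDifference,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
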