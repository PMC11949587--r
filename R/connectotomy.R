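#' Simulate a bank of PLI matrices over a coupling grid
#'
#' Simulated PLI matrices for every (K, initial condition) pair at fixed
#' excitability.  The bank is the reusable raw material of the functional
#' connectotomy: masking only ever changes the objective submatrix, never
#' the simulations, so the same bank serves the before/after objectives
#' and the patient/control arms (exact seed pairing).
#'
#' @param W a [Connectome-class].
#' @param omega angular natural frequencies (rad/s).
#' @param KGrid coupling grid (sorted internally).
#' @param lambda fixed excitability.
#' @param ics list of complex initial conditions.
#' @param settings a [SimulationSettings-class].
#' @param C structural scaling (default 20).
#' @return list with elements `KGrid`, `nIc`, `lambda`, and `pli`, a list
#'   indexed `[[K]][[ic]]` of simulated [PLIMatrix-class] objects.
#' @export
simulatePLIBank <- function(W, omega, KGrid, lambda, ics,
                            settings = SimulationSettings(), C = 20) {
  KGrid <- sort(unique(as.numeric(KGrid)))
  pli <- lapply(KGrid, function(K) {
    params <- HopfParameters(K = K, lambda = lambda, omega = omega, C = C)
    lapply(ics, function(ic) simulatePLI(params, W, ic, settings))
  })
  list(KGrid = KGrid, nIc = length(ics), lambda = lambda, pli = pli)
}

# 1-D optimal-K scan against one empirical matrix and exclusion set;
# ties toward the smallest K, all-NA columns give NA.
scanOptimalK <- function(bank, emp, exclude = integer(0),
                         includeZeros = TRUE) {
  vapply(seq_len(bank$nIc), function(ii) {
    r <- vapply(seq_along(bank$KGrid), function(ki)
      tryCatch(goodnessOfFit(bank$pli[[ki]][[ii]], emp, exclude = exclude,
                             includeZeros = includeZeros),
               error = function(e) NA_real_), numeric(1))
    if (all(is.na(r))) NA_real_ else bank$KGrid[which.max(r)]
  }, numeric(1))
}

#' Functional connectotomy refit for one subject arm
#'
#' For each initial condition, finds the optimal coupling K at fixed
#' excitability twice against the same simulated PLI bank: once with the
#' full objective (before) and once with the mask regions' rows and
#' columns removed from both matrices (after).  The mask affects only the
#' objective; the regions are never removed from the dynamical model.
#'
#' @param emp empirical [PLIMatrix-class] of the subject (or cohort
#'   average).
#' @param mask a [TumorMask-class]; must leave at least 3 regions.
#' @param W,omega,KGrid,settings,C used to build the bank when `bank` is
#'   NULL.
#' @param lambdaFixed fixed excitability of the scan (default 40).
#' @param ics list of complex initial conditions.
#' @param bank optional precomputed [simulatePLIBank] result (for exact
#'   pairing across arms); its lambda and nIc must match.
#' @param arm arm label stored in the records (default "patient").
#' @return a [ConnectotomyOutcome-class] holding one arm of records.
#' @export
connectotomyRefit <- function(emp, mask, W = NULL, omega = NULL,
                              KGrid = defaultKGrid(), lambdaFixed = 40,
                              ics = NULL, settings = SimulationSettings(),
                              C = 20, bank = NULL, arm = "patient") {
  n <- regionCount(emp)
  stopIfNot(mask@nRegions == n, "mask does not match the PLI dimensions")
  if (n - length(mask@regions) < 3L)
    stop("mask leaves fewer than 3 regions; objective undefined",
         call. = FALSE)
  if (is.null(bank)) {
    stopIfNot(!is.null(W) && !is.null(omega) && !is.null(ics),
              "either a bank or (W, omega, ics) must be supplied")
    bank <- simulatePLIBank(W, omega, KGrid, lambdaFixed, ics,
                            settings = settings, C = C)
  } else {
    stopIfNot(isTRUE(all.equal(bank$lambda, lambdaFixed)),
              "bank lambda does not match lambdaFixed")
  }
  before <- scanOptimalK(bank, emp, exclude = integer(0))
  after <- scanOptimalK(bank, emp, exclude = mask@regions)
  rec <- data.frame(ic = seq_len(bank$nIc), arm = arm, KBefore = before,
                    KAfter = after, delta = after - before,
                    stringsAsFactors = FALSE)
  new("ConnectotomyOutcome", subjectId = mask@subjectId, mask = mask,
      lambdaFixed = bank$lambda, records = rec)
}

#' Pair a connectotomy outcome with its control arm
#'
#' Runs the identical connectotomy (same mask, same coupling grid, same
#' simulated PLI bank, hence the same seeds) against the control-average
#' empirical PLI and stores both arms.  The per-initial-condition
#' difference of changes `delta_patient - delta_control` is available
#' through [differenceOfChanges].
#'
#' @param patientHalf a [ConnectotomyOutcome-class] from
#'   [connectotomyRefit].
#' @param controlEmp control-average empirical [PLIMatrix-class].
#' @param bank the same bank used for the patient arm (required: pairing
#'   is by construction).
#' @return a completed [ConnectotomyOutcome-class] with both arms.
#' @export
pairWithControl <- function(patientHalf, controlEmp, bank) {
  stopIfNot(identical(sort(unique(patientHalf@records$arm)), "patient"),
            "patientHalf must hold exactly the patient arm")
  if (bank$nIc != nrow(patientHalf@records) ||
      !isTRUE(all.equal(bank$lambda, patientHalf@lambdaFixed)))
    stop("bank does not match the patient arm (seed/lambda pairing broken)",
         call. = FALSE)
  ctrl <- connectotomyRefit(controlEmp, patientHalf@mask,
                            lambdaFixed = patientHalf@lambdaFixed,
                            bank = bank, arm = "control")
  new("ConnectotomyOutcome", subjectId = patientHalf@subjectId,
      mask = patientHalf@mask, lambdaFixed = patientHalf@lambdaFixed,
      records = rbind(patientHalf@records, ctrl@records))
}

#' Connectotomy accessors
#'
#' `differenceOfChanges` returns the per-initial-condition
#' `delta_patient - delta_control` of a paired outcome.
#'
#' @param x a [ConnectotomyOutcome-class].
#' @return numeric vector, one value per initial condition.
#' @name connectotomy
NULL

#' @rdname connectotomy
setMethod("differenceOfChanges", "ConnectotomyOutcome", function(x) {
  rec <- x@records
  p <- rec[rec$arm == "patient", ]
  c0 <- rec[rec$arm == "control", ]
  stopIfNot(nrow(p) > 0L && nrow(c0) > 0L, "outcome is not paired")
  stopIfNot(identical(p$ic, c0$ic), "arms are not seed-paired")
  p$delta - c0$delta
})

setMethod("show", "ConnectotomyOutcome", function(object) {
  rec <- object@records
  cat("ConnectotomyOutcome '", object@subjectId, "': ",
      length(object@mask@regions), " masked regions, lambda = ",
      object@lambdaFixed, "\n", sep = "")
  for (a in unique(rec$arm)) {
    d <- rec$delta[rec$arm == a]
    cat("  ", a, ": mean delta K = ", signif(mean(d, na.rm = TRUE), 4),
        " over ", length(d), " initial conditions\n", sep = "")
  }
})

#' Serialize a connectotomy outcome
#'
#' @param outcome a [ConnectotomyOutcome-class].
#' @param csvPath output CSV (subject, ic, arm, KBefore, KAfter, delta).
#' @param jsonPath optional JSON summary path.
#' @return the records data.frame, invisibly.
#' @export
writeConnectotomy <- function(outcome, csvPath, jsonPath = NULL) {
  rec <- cbind(subject = outcome@subjectId, outcome@records)
  utils::write.csv(rec, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    summ <- lapply(split(outcome@records, outcome@records$arm), function(d)
      list(meanDelta = mean(d$delta, na.rm = TRUE),
           sdDelta = stats::sd(d$delta, na.rm = TRUE), n = nrow(d)))
    jsonlite::write_json(list(subject = outcome@subjectId,
                              lambdaFixed = outcome@lambdaFixed,
                              maskSize = length(outcome@mask@regions),
                              arms = summ),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(rec)
}
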