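# Automated exclusion: the two machine-side criteria — low registration
# accuracy, and ROI structures lost during refinement — plus typed codes
# for upstream stage failures. Manual-exclusion categories (hemisphere
# asymmetry, hemorrhage, atrophy, artifact) are physician calls; the
# phantom can generate them but the package does not attempt to detect
# them.

#' QC thresholds
#'
#' @param accuracy_min minimum registration-accuracy Dice; below it the case
#'   is excluded with `REG_LOW_ACCURACY`. Not specified by the underlying
#'   study; 0.90 is this package's configurable default.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(accuracy_min = 0.90) {
  structure(list(accuracy_min = accuracy_min), class = "qc_thresholds")
}

#' Evaluate automated exclusion for one case
#'
#' Emits `REG_LOW_ACCURACY` iff the registration accuracy score falls below
#' the threshold, and `MISSING_ROI_<structure>` for every structure group
#' (CC, CN, PU, PIC) with a member emptied by refinement — the analogues of
#' losing the CC, the CN, or both near the ventricles. A report is always
#' produced; `status` is `"excluded"` iff any code fired.
#'
#' @param accuracy_score registration accuracy in `[0, 1]` (see
#'   [registration_accuracy()]); `NA` is treated as a brain-extraction
#'   failure.
#' @param refined refined [roi_atlas()] from [refine_rois()] (with its
#'   `missing` attribute), or `NULL` if segmentation never ran.
#' @param thresholds a [qc_thresholds()].
#' @param case_id identifier carried into the report.
#' @return A `qc_report`: `case_id`, `status`, `codes`, `accuracy_score`,
#'   `surviving_fraction`.
#' @export
evaluate_case <- function(accuracy_score, refined,
                          thresholds = qc_thresholds(), case_id = "case") {
  codes <- character(0)
  if (is.na(accuracy_score)) {
    codes <- c(codes, "BRAIN_EXTRACTION_FAILED")
    accuracy_score <- 0
  } else if (accuracy_score < thresholds$accuracy_min) {
    codes <- c(codes, "REG_LOW_ACCURACY")
  }
  surv <- NULL
  if (!is.null(refined)) {
    missing <- attr(refined, "missing")
    surv <- attr(refined, "surviving_fraction")
    tab <- refined$label_table
    for (s in c("CC", "CN", "PU", "PIC")) {
      members <- tab$name[tab$structure == s]
      if (length(members) && any(missing[members]))
        codes <- c(codes, paste0("MISSING_ROI_", s))
    }
  } else if (!length(codes)) {
    codes <- c(codes, "DEGENERATE_INPUT")
  }
  structure(list(
    case_id = case_id,
    status = if (length(codes)) "excluded" else "ok",
    codes = codes,
    accuracy_score = accuracy_score,
    surviving_fraction = surv
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$case_id, ": ", x$status,
      if (length(x$codes)) paste0(" [", paste(x$codes, collapse = ", "), "]"),
      " (accuracy ", signif(x$accuracy_score, 3), ")\n", sep = "")
  invisible(x)
}

#' Patient-flow accounting
#'
#' Book-keeping for an enrollment flow with pre-imaging exclusions,
#' physician (manual) CT exclusions by reason, and automated CT exclusions
#' by reason, plus the derivation/validation split of the analyzable cohort
#' (derivation fraction rounded down).
#'
#' @param enrolled number of enrolled subjects.
#' @param pre_exclusions named numeric vector of pre-imaging exclusions
#'   (e.g. poor pre-arrest neurological status, transfer with unknown
#'   outcome).
#' @param manual_exclusions named numeric vector of physician CT-exclusion
#'   counts by reason.
#' @param automated_exclusions named numeric vector of automated
#'   CT-exclusion counts by reason.
#' @param derivation_fraction fraction of the analyzable cohort assigned to
#'   the derivation set.
#' @return List with totals per stage and the resulting cohort sizes.
#' @export
cohort_flow <- function(enrolled, pre_exclusions, manual_exclusions,
                        automated_exclusions, derivation_fraction = 0.6) {
  pre <- sum(pre_exclusions)
  man <- sum(manual_exclusions)
  auto <- sum(automated_exclusions)
  analyzed <- enrolled - pre - man - auto
  if (analyzed < 0) stop("exclusions exceed enrollment")
  deriv <- floor(derivation_fraction * analyzed)
  list(
    enrolled = enrolled,
    pre_exclusions_total = pre,
    manual_exclusions_total = man,
    automated_exclusions_total = auto,
    analyzed = analyzed,
    derivation_n = deriv,
    validation_n = analyzed - deriv
  )
}
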