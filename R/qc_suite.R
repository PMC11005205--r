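# Canonical phantom QC suite: 15 clean subjects spanning the severity
# range and 5 corrupted subjects reproducing the automated-exclusion
# failure taxonomy (loss of CC, loss of CN, loss of both, and registration
# collapse under severe malposition).

#' Phantom QC suite definition
#'
#' Returns the 20-case suite used to exercise automated exclusion: 15
#' clean subjects with severities spread over `[0, 1]` and randomized
#' poses, plus 5 corrupted subjects with their expected exclusion codes.
#' The ablation cases empty specific structures; the malposition case
#' combines an extreme, field-of-view-truncating pose with a registration
#' configuration whose rigid stage is disabled and whose deformable stage
#' is capped at one sweep, so that registration genuinely fails.
#'
#' @param seed base RNG seed; each case derives its own seed from it.
#' @return List of case descriptors: `case_id`, `subject`
#'   ([subject_spec()]), `registration` (`NULL` for the pipeline default
#'   or a [registration_settings()] override) and `expected_codes`
#'   (empty for clean cases).
#' @export
phantom_qc_suite <- function(seed = .gwrct_default_seed) {
  sev <- rep(c(0, 0.25, 0.5, 0.75, 1), 3)
  clean <- lapply(seq_along(sev), function(i) {
    list(case_id = sprintf("clean%02d", i),
         subject = subject_spec(severity = sev[i], seed = seed + i),
         registration = NULL,
         expected_codes = character(0))
  })
  crippled <- registration_settings(
    stages = "deformable",
    iterations = list(rigid = 1L, affine = 1L, deformable = 1L))
  corrupted <- list(
    list(case_id = "corrupt_cc",
         subject = subject_spec(severity = 0.3, lesion = "cc_ablation",
                                seed = seed + 101L),
         registration = NULL, expected_codes = "MISSING_ROI_CC"),
    list(case_id = "corrupt_cn",
         subject = subject_spec(severity = 0.2, lesion = "cn_ablation",
                                seed = seed + 102L),
         registration = NULL, expected_codes = "MISSING_ROI_CN"),
    list(case_id = "corrupt_cc_cn",
         subject = subject_spec(severity = 0.4, lesion = "cc_cn_ablation",
                                seed = seed + 103L),
         registration = NULL,
         expected_codes = c("MISSING_ROI_CC", "MISSING_ROI_CN")),
    list(case_id = "corrupt_cc2",
         subject = subject_spec(severity = 0.1, lesion = "cc_ablation",
                                seed = seed + 104L),
         registration = NULL, expected_codes = "MISSING_ROI_CC"),
    list(case_id = "corrupt_malposition",
         subject = subject_spec(severity = 0.2,
                                rotation_deg = c(0, 0, 40),
                                translation_mm = c(55, -40, 20),
                                deformation_amp = 0,
                                seed = seed + 105L),
         registration = crippled,
         expected_codes = "REG_LOW_ACCURACY")
  )
  c(clean, corrupted)
}

#' Run the QC suite
#'
#' Generates each suite subject against the given template and runs the
#' full pipeline on it.
#'
#' @param tpl output of [make_template()].
#' @param suite output of [phantom_qc_suite()].
#' @param spec the [phantom_spec()] used for the template.
#' @param config base [pipeline_config()]; per-case registration
#'   overrides from the suite are applied on top.
#' @return Data frame with one row per case: `case_id`, `expected`
#'   (`"ok"`/`"excluded"`), `status`, `codes`, `expected_codes`,
#'   `codes_match` (all expected codes present), `accuracy`.
#' @export
run_qc_suite <- function(tpl, suite = phantom_qc_suite(),
                         spec = phantom_spec(),
                         config = pipeline_config()) {
  rows <- lapply(suite, function(cs) {
    cfg <- config
    if (!is.null(cs$registration)) cfg$registration <- cs$registration
    subj <- make_subject(tpl, cs$subject, spec)
    res <- run_case(subj$ct, tpl$template, tpl$atlas, tpl$brain, cfg,
                    case_id = cs$case_id)
    data.frame(
      case_id = cs$case_id,
      expected = if (length(cs$expected_codes)) "excluded" else "ok",
      status = res$qc$status,
      codes = paste(res$qc$codes, collapse = ";"),
      expected_codes = paste(cs$expected_codes, collapse = ";"),
      codes_match = all(cs$expected_codes %in% res$qc$codes),
      accuracy = res$qc$accuracy_score,
      gwr_s = res$gwr_s,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
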