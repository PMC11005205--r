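# Orchestration of the full automated workflow:
# register -> brain_extract -> kmeans_tissues -> refine_rois ->
# inverse_map_rois -> roi_statistics -> GWR -> QC.

#' Pipeline configuration
#'
#' Bundles the stage settings; serializable to/from a YAML file with
#' unknown keys rejected.
#'
#' @param registration a [registration_settings()].
#' @param refinement a [refinement_settings()].
#' @param qc a [qc_thresholds()].
#' @param hu_window optional statistics-time HU inclusion window.
#' @param seed seed forwarded to the K-means stage.
#' @param keep_intermediates write warped volume / masks next to results.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(registration = registration_settings(),
                            refinement = refinement_settings(),
                            qc = qc_thresholds(),
                            hu_window = NULL,
                            seed = .gwrct_default_seed,
                            keep_intermediates = FALSE) {
  structure(list(registration = registration, refinement = refinement,
                 qc = qc, hu_window = hu_window, seed = as.integer(seed),
                 keep_intermediates = isTRUE(keep_intermediates)),
            class = "pipeline_config")
}

config_known_keys <- function() {
  list(
    registration = names(registration_settings()),
    refinement = names(refinement_settings()),
    qc = names(qc_thresholds()),
    top = c("registration", "refinement", "qc", "hu_window", "seed",
            "keep_intermediates")
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kk <- config_known_keys()
  unknown <- setdiff(names(raw), kk$top)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (sec in c("registration", "refinement", "qc")) {
    bad <- setdiff(names(raw[[sec]]), kk[[sec]])
    if (length(bad))
      stop("unknown keys in ", sec, ": ", paste(bad, collapse = ", "))
  }
  reg <- do.call(registration_settings, raw$registration %||% list())
  ref <- do.call(refinement_settings, raw$refinement %||% list())
  qc <- do.call(qc_thresholds, raw$qc %||% list())
  pipeline_config(registration = reg, refinement = ref, qc = qc,
                  hu_window = raw$hu_window,
                  seed = raw$seed %||% .gwrct_default_seed,
                  keep_intermediates = raw$keep_intermediates %||% FALSE)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  out <- list(
    registration = unclass(config$registration),
    refinement = unclass(config$refinement),
    qc = unclass(config$qc),
    hu_window = config$hu_window,
    seed = config$seed,
    keep_intermediates = config$keep_intermediates
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

settings_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the automated GWR pipeline on one case
#'
#' Executes registration, brain extraction, K-means tissue segmentation,
#' ROI refinement, inverse mapping, HU statistics and QC for a single
#' native CT against the template and atlas. Stage failures are converted
#' into QC exclusion codes rather than raised, except for unreadable or
#' degenerate inputs.
#'
#' @param ct native-space [volume_image()].
#' @param template template [volume_image()].
#' @param atlas template-space [roi_atlas()].
#' @param template_brain template-space [binary_mask()].
#' @param config a [pipeline_config()].
#' @param case_id identifier used in reports.
#' @return A `gwr_result`; its `qc` field reports status and codes, and
#'   `provenance$accuracy` the registration accuracy score. The transform
#'   and intermediates are attached as attribute `stages` when
#'   `config$keep_intermediates` is set.
#' @export
run_case <- function(ct, template, atlas, template_brain,
                     config = pipeline_config(), case_id = "case") {
  pair <- register(ct, template, config$registration)
  tgrid <- grid_of(template)
  warped <- resample(ct, pair, tgrid)
  brain_w <- tryCatch(brain_extract(warped), error = function(e) NULL)
  refined <- NULL
  shu <- NULL
  if (is.null(brain_w)) {
    acc <- NA_real_
  } else {
    acc <- dice(brain_w, template_brain)
    tissues <- tryCatch(
      kmeans_tissues(warped, brain_w, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(tissues)) {
      refined <- refine_rois(atlas, tissues, config$refinement)
      native_rois <- inverse_map_rois(refined, pair, grid_of(ct))
      shu <- roi_statistics(ct, native_rois, config$hu_window)
    }
  }
  qc <- evaluate_case(acc, refined, config$qc, case_id = case_id)
  if (is.null(shu)) {
    empty <- roi_atlas(array(0L, dim(ct$voxels)), ct$spacing, ct$origin)
    shu <- roi_statistics(ct, empty, config$hu_window)
  }
  res <- gwr_result(shu, qc, provenance = list(
    case_id = case_id, settings_hash = settings_hash(config),
    seed = config$seed, accuracy = acc,
    registration_similarity = pair$meta$similarity))
  if (config$keep_intermediates)
    attr(res, "stages") <- list(pair = pair, warped = warped,
                                brain = brain_w, refined = refined)
  res
}

result_row <- function(res) {
  data.frame(
    case_id = res$provenance$case_id %||% NA_character_,
    status = res$qc$status,
    codes = paste(res$qc$codes, collapse = ";"),
    accuracy = res$qc$accuracy_score,
    gwr_b = res$gwr_b,
    gwr_s = res$gwr_s,
    cn_hu = structure_mean(res$structure_hu, "CN"),
    pu_hu = structure_mean(res$structure_hu, "PU"),
    pic_hu = structure_mean(res$structure_hu, "PIC"),
    cc_hu = structure_mean(res$structure_hu, "CC"),
    stringsAsFactors = FALSE
  )
}

#' Write a per-case JSON report
#'
#' @param res a `gwr_result`.
#' @param path output JSON path.
#' @export
write_case_report <- function(res, path) {
  payload <- list(
    case_id = res$provenance$case_id,
    status = res$qc$status,
    codes = res$qc$codes,
    accuracy_score = res$qc$accuracy_score,
    gwr_b = res$gwr_b,
    gwr_s = res$gwr_s,
    structures = res$structure_hu$pooled,
    parts = res$structure_hu$parts,
    provenance = res$provenance[setdiff(names(res$provenance), "case_id")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Batch execution over a case manifest
#'
#' Runs [run_case()] for every row of a manifest (`case_id`, `ct_path`),
#' writing one JSON report per case into `out_dir` and returning (and
#' writing) a cohort CSV with one row per case, excluded ones included.
#' Completed cases (existing report with the same settings hash) are
#' skipped, making reruns cheap and idempotent.
#'
#' @param manifest data.frame with `case_id` and `ct_path` columns, or path
#'   to such a CSV.
#' @param template_path,atlas_path,brain_path template NIfTI inputs.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return Data frame of per-case rows (invisibly also written to
#'   `out_dir/batch.csv`).
#' @export
run_batch <- function(manifest, template_path, atlas_path, brain_path,
                      out_dir, config = pipeline_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                          stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(manifest) == 0L) {
    warning("empty manifest: nothing to do")
    out <- data.frame(case_id = character(0), status = character(0),
                      codes = character(0), accuracy = numeric(0),
                      gwr_b = numeric(0), gwr_s = numeric(0),
                      cn_hu = numeric(0), pu_hu = numeric(0),
                      pic_hu = numeric(0), cc_hu = numeric(0))
    utils::write.csv(out, file.path(out_dir, "batch.csv"), row.names = FALSE)
    return(invisible(out))
  }
  template <- read_volume(template_path)
  atlas <- read_atlas(atlas_path)
  brain <- read_mask(brain_path)
  hash <- settings_hash(config)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cid <- manifest$case_id[i]
    jpath <- file.path(out_dir, paste0(cid, ".json"))
    if (file.exists(jpath)) {
      prev <- jsonlite::read_json(jpath)
      if (identical(prev$provenance$settings_hash, hash)) {
        rows[[i]] <- data.frame(
          case_id = cid, status = prev$status,
          codes = paste(unlist(prev$codes), collapse = ";"),
          accuracy = as.numeric(prev$accuracy_score %||% NA),
          gwr_b = as.numeric(prev$gwr_b %||% NA),
          gwr_s = as.numeric(prev$gwr_s %||% NA),
          cn_hu = NA_real_, pu_hu = NA_real_, pic_hu = NA_real_,
          cc_hu = NA_real_, stringsAsFactors = FALSE)
        next
      }
    }
    row <- tryCatch({
      ct <- read_volume(manifest$ct_path[i])
      res <- run_case(ct, template, atlas, brain, config, case_id = cid)
      write_case_report(res, jpath)
      result_row(res)
    }, error = function(e) {
      warning("case ", cid, " failed: ", conditionMessage(e))
      data.frame(case_id = cid, status = "error",
                 codes = conditionMessage(e), accuracy = NA_real_,
                 gwr_b = NA_real_, gwr_s = NA_real_, cn_hu = NA_real_,
                 pu_hu = NA_real_, pic_hu = NA_real_, cc_hu = NA_real_,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(out_dir, "batch.csv"), row.names = FALSE)
  invisible(out)
}

#' Cohort-level prognostic evaluation
#'
#' For each GWR column: the Youden cutoff on the derivation set, then AUC
#' (DeLong 95% CI) and sensitivity/specificity/PPV/NPV (Clopper-Pearson
#' CIs) in the derivation and validation sets at that one cutoff; pairwise
#' DeLong comparisons between GWR columns; and, when covariates are given,
#' a multiple logistic model per set with the binarized GWR
#' (`gwr > derivation cutoff`) plus the covariates screened at `p < 0.1`.
#'
#' @param cohort `cohort_table` (or data.frame) with `outcome`, the GWR
#'   columns and optionally a `set` column; subjects without a set are
#'   assigned by [split_cohort()].
#' @param gwr_cols GWR column names to evaluate.
#' @param outcome outcome column name (favorable = 1).
#' @param covariates candidate clinical covariates for the logistic model;
#'   `NULL` skips the model stage.
#' @param delong compute pairwise DeLong tests between `gwr_cols`.
#' @return List with `performance` (long data.frame), `cutoffs`, `delong`,
#'   `models`.
#' @export
evaluate_cohort <- function(cohort, gwr_cols = c("automated_s"),
                            outcome = "outcome", covariates = NULL,
                            delong = TRUE) {
  stopifnot(all(gwr_cols %in% names(cohort)), outcome %in% names(cohort))
  if (!("set" %in% names(cohort)) || anyNA(cohort$set))
    cohort <- split_cohort(cohort)
  sets <- list(derivation = cohort[cohort$set == "derivation", ],
               validation = cohort[cohort$set == "validation", ])
  for (nm in names(sets))
    if (length(unique(sets[[nm]][[outcome]])) < 2L)
      stop("single-class outcome in the ", nm, " set")

  cutoffs <- vapply(gwr_cols, function(g)
    as.numeric(youden_cutoff(sets$derivation[[g]],
                             sets$derivation[[outcome]])), numeric(1))
  perf <- do.call(rbind, lapply(gwr_cols, function(g) {
    do.call(rbind, lapply(names(sets), function(nm) {
      d <- sets[[nm]]
      ra <- roc_auc(d[[g]], d[[outcome]])
      bm <- binary_metrics(d[[g]], d[[outcome]], cutoffs[[g]])
      data.frame(gwr = g, set = nm, cutoff = cutoffs[[g]],
                 auc = ra$auc, auc_lo = ra$ci[1], auc_hi = ra$ci[2],
                 metric = bm$metric, estimate = bm$estimate,
                 lo = bm$lo, hi = bm$hi, stringsAsFactors = FALSE)
    }))
  }))

  dl <- NULL
  if (delong && length(gwr_cols) > 1L) {
    cmb <- utils::combn(gwr_cols, 2, simplify = FALSE)
    dl <- do.call(rbind, lapply(names(sets), function(nm) {
      d <- sets[[nm]]
      do.call(rbind, lapply(cmb, function(pr) {
        dt <- delong_test(d[[pr[1]]], d[[pr[2]]], d[[outcome]])
        data.frame(set = nm, a = pr[1], b = pr[2], auc_a = dt$auc_a,
                   auc_b = dt$auc_b, p = dt$p, stringsAsFactors = FALSE)
      }))
    }))
  }

  models <- NULL
  if (!is.null(covariates)) {
    models <- lapply(gwr_cols, function(g) {
      lapply(sets, function(d) {
        d$gwr_bin <- as.integer(d[[g]] > cutoffs[[g]])
        scr <- screen_variables(d, outcome, variables = covariates)
        preds <- c("gwr_bin", attr(scr, "selected"))
        list(screen = scr,
             model = logistic_model(d, outcome, preds))
      })
    })
    names(models) <- gwr_cols
  }
  list(performance = perf, cutoffs = cutoffs, delong = dl, models = models)
}

#' @importFrom utils combn
NULL
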