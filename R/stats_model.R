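# Univariate screening into multiple logistic regression, mirroring the
# evaluation protocol: continuous variables compared by Student's t test,
# categorical by chi-square, variables at p < 0.1 entering the logistic
# model; odds ratios with Wald 95% CIs.

#' Univariate screening of candidate predictors
#'
#' Continuous variables (more than two distinct values) are screened with
#' the two-sample Student's t test (equal variances), binary/categorical
#' variables with the chi-square test. Variables with `p < alpha` are
#' selected. Constant variables are skipped with a warning.
#'
#' @param cohort data.frame of subjects.
#' @param outcome name of the 0/1 outcome column.
#' @param variables candidate column names; default every column except the
#'   outcome and the bookkeeping columns `id` and `set`.
#' @param alpha inclusion threshold (default 0.1).
#' @return Data frame (`variable`, `test`, `p`, `included`), with the
#'   selected names in attribute `selected`.
#' @export
screen_variables <- function(cohort, outcome, variables = NULL, alpha = 0.1) {
  stopifnot(is.data.frame(cohort), outcome %in% names(cohort))
  y <- check_labels(cohort[[outcome]])
  if (min(table(y)) < 2L) stop("need >= 2 subjects per outcome class")
  if (is.null(variables))
    variables <- setdiff(names(cohort), c(outcome, "id", "set"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    xs <- x[ok]; ys <- y[ok]
    if (length(unique(xs)) < 2L) {
      warning("skipping constant variable: ", v)
      return(data.frame(variable = v, test = "none", p = NA_real_,
                        included = FALSE, stringsAsFactors = FALSE))
    }
    if (is.numeric(xs) && length(unique(xs)) > 2L) {
      p <- stats::t.test(xs ~ ys, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(stats::chisq.test(table(xs, ys))$p.value)
      test <- "chisq"
    }
    data.frame(variable = v, test = test, p = p, included = !is.na(p) &&
                 p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$variable[out$included]
  out
}

#' Multiple logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on the given
#' predictors (typically the screened clinical variables plus the binarized
#' GWR, `gwr > cutoff`). Reports odds ratios with Wald 95% CIs and the
#' in-sample AUC of the predicted probabilities. Complete-case analysis;
#' the number of dropped rows is reported.
#'
#' @param cohort data.frame of subjects.
#' @param outcome name of the 0/1 outcome column.
#' @param predictors character vector of predictor column names.
#' @return List with `coefficients` (data.frame: `term`, `or`, `lo`, `hi`,
#'   `p`), `auc`, `n`, `n_dropped`, and the underlying `fit`.
#' @export
logistic_model <- function(cohort, outcome, predictors) {
  stopifnot(is.data.frame(cohort), outcome %in% names(cohort),
            all(predictors %in% names(cohort)))
  dat <- cohort[, c(outcome, predictors), drop = FALSE]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L) stop("outcome is constant")
  if (nrow(dat) <= length(predictors) + 1L)
    stop("more predictors than subjects")
  f <- stats::as.formula(paste(outcome, "~",
                               paste(predictors, collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    stats::glm(f, data = dat, family = stats::binomial()),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged)
    stop("logistic model did not converge after ", fit$iter, " iterations")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # separation: a coefficient running to +/- infinity with an exploding
  # Wald SE (glm stops at a huge finite value)
  sep <- abs(cf[-1]) > 15 & se[-1] > 10
  if (any(sep)) {
    worst <- names(cf[-1])[sep][which.max(abs(cf[-1])[sep])]
    stop("perfect separation detected for covariate: ", worst)
  }
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    term = names(cf),
    or = exp(cf),
    lo = exp(cf - z * se),
    hi = exp(cf + z * se),
    p = 2 * stats::pnorm(-abs(cf / se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  auc <- roc_auc(stats::fitted(fit), y)$auc
  list(coefficients = tab, auc = auc, n = nrow(dat),
       n_dropped = sum(!cc), fit = fit)
}

#' Derivation/validation split stratified on sex and age
#'
#' Assigns subjects to derivation and validation sets by stratified
#' sampling within sex-by-age-quartile cells with a fixed seed, the
#' operational reading of a split "based on age and sex".
#'
#' @param cohort data.frame with `age` and `sex` columns.
#' @param derivation_fraction target derivation fraction.
#' @param seed RNG seed.
#' @return The cohort with a `set` column (`"derivation"`/`"validation"`).
#' @export
split_cohort <- function(cohort, derivation_fraction = 0.6,
                         seed = .gwrct_default_seed) {
  stopifnot(all(c("age", "sex") %in% names(cohort)))
  set.seed(seed)
  q <- stats::quantile(cohort$age, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  cell <- interaction(cohort$sex, findInterval(cohort$age, q))
  setv <- character(nrow(cohort))
  for (lev in levels(droplevels(cell))) {
    idx <- which(cell == lev)
    n_d <- round(derivation_fraction * length(idx))
    pick <- if (n_d > 0) sample(idx, n_d) else integer(0)
    setv[pick] <- "derivation"
    setv[setdiff(idx, pick)] <- "validation"
  }
  cohort$set <- setv
  cohort
}
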