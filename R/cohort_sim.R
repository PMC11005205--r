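# Synthetic cohort generator for the statistics layer: per-subject
# covariates drawn with directions patterned on post-arrest cohorts (older
# age, higher epinephrine dose, lower diastolic pressure in poor outcome),
# injury severity driving the true GWR, and the favorable-outcome label
# generated from a logistic model with stated coefficients.

#' Default outcome model for simulated cohorts
#'
#' Logistic coefficients on standardized predictor scales, plus the
#' centring/scaling constants. The favorable-outcome log-odds are
#' `intercept + sum(coef * z)` with `z = (value - center) / scale`.
#'
#' @return List with `coefs` (named) and `scales` (named list of
#'   `c(center, scale)`).
#' @export
default_outcome_model <- function() {
  list(
    coefs = c(gwr_true = 2.0, age = -0.5, epinephrine = -0.7, dbp = 0.5,
              witnessed = 0.4, malignancy = -0.8),
    intercept = -1.2,
    scales = list(gwr_true = c(1.15, 0.08), age = c(63, 16),
                  epinephrine = c(4, 4), dbp = c(72, 26),
                  witnessed = c(0, 1), malignancy = c(0, 1))
  )
}

cohort_linear_predictor <- function(dat, model) {
  lp <- rep(model$intercept, nrow(dat))
  for (v in names(model$coefs)) {
    sc <- model$scales[[v]]
    lp <- lp + model$coefs[[v]] * (dat[[v]] - sc[1]) / sc[2]
  }
  lp
}

#' Simulate a cohort table
#'
#' Draws per-subject covariates, injury severity and the implied true GWR,
#' generates observed manual/automated GWR readings (the manual readings
#' carry larger measurement noise, reflecting small 2-D circular ROIs), and
#' samples the favorable-outcome label from the logistic `outcome_model`.
#' Survival is favorable outcome or a severity-independent residual chance.
#' Fully deterministic per seed.
#'
#' @param n number of subjects, >= 20.
#' @param severity_model list with `min` and `max` of the uniform severity
#'   draw.
#' @param outcome_model see [default_outcome_model()]; set all `coefs` to 0
#'   for a null model.
#' @param gwr_noise named SDs of the observed GWR readings.
#' @param seed RNG seed.
#' @return Data frame (class `cohort_table`) with id, set (unassigned,
#'   see [split_cohort()]), outcome, survival, severity, gwr_true, the four
#'   observed GWR columns and the clinical covariates.
#' @export
simulate_cohort <- function(n, severity_model = list(min = 0, max = 1),
                            outcome_model = default_outcome_model(),
                            gwr_noise = c(manual = 0.06, automated = 0.025),
                            seed = .gwrct_default_seed) {
  stopifnot(n >= 20)
  set.seed(seed)
  severity <- runif(n, severity_model$min, severity_model$max)
  gwr_true <- (38 - 8 * severity) / 30
  dat <- data.frame(
    id = sprintf("sim%04d", seq_len(n)),
    age = pmax(18, round(rnorm(n, 63, 16))),
    sex = rbinom(n, 1, 0.7),
    malignancy = rbinom(n, 1, 0.11),
    htn = rbinom(n, 1, 0.25),
    witnessed = rbinom(n, 1, 0.77),
    epinephrine = round(pmax(0, rnorm(n, 4, 4)), 1),
    cpr_duration = round(pmax(1, rnorm(n, 22, 11))),
    dbp = round(pmax(20, rnorm(n, 72, 26))),
    sbp = round(pmax(50, rnorm(n, 120, 42))),
    heart_rate = round(pmax(30, rnorm(n, 101, 30))),
    ph = round(rnorm(n, 7.1, 0.15), 2),
    lactate = round(pmax(0.5, rnorm(n, 10, 4)), 1),
    troponin = round(pmax(0, stats::rexp(n, 1 / 15)), 1),
    pci = rbinom(n, 1, 0.4),
    ecmo = rbinom(n, 1, 0.25),
    ttm = rbinom(n, 1, 0.44),
    ct_timing_min = round(pmax(10, rnorm(n, 103, 77))),
    severity = severity,
    gwr_true = gwr_true,
    stringsAsFactors = FALSE
  )
  dat$manual_b <- gwr_true + rnorm(n, 0, gwr_noise[["manual"]])
  dat$manual_s <- gwr_true + rnorm(n, 0, gwr_noise[["manual"]])
  dat$automated_b <- gwr_true + rnorm(n, 0, gwr_noise[["automated"]])
  dat$automated_s <- gwr_true + rnorm(n, 0, gwr_noise[["automated"]])
  lp <- cohort_linear_predictor(dat, outcome_model)
  dat$outcome <- rbinom(n, 1, stats::plogis(lp))
  if (length(unique(dat$outcome)) < 2L)
    stop("degenerate simulation: all subjects share one outcome")
  dat$survival <- ifelse(dat$outcome == 1L, 1L, rbinom(n, 1, 0.17))
  dat$set <- NA_character_
  class(dat) <- c("cohort_table", "data.frame")
  dat
}

#' @importFrom stats rexp as.formula fitted
NULL
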