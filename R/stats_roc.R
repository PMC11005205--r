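# Prognostic evaluation statistics: correlation, ROC/AUC with DeLong
# variance, Youden cutoffs, diagnostic 2x2 metrics with exact CIs, and the
# paired DeLong AUC comparison. The positive class is the favorable
# neurological outcome and higher scores (higher GWR) predict it.

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  labels
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value; used to
#' compare manual against automated HU measurements per structure.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# DeLong placement values: V10 per positive, V01 per negative
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney concordance probability (ties count one half),
#' with a 95% CI from the DeLong placement-value variance.
#'
#' @param scores numeric predictor (higher predicts the positive class).
#' @param labels 0/1 outcome, both classes present.
#' @param conf_level confidence level.
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pl <- delong_placements(scores, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = pl$auc, ci = ci, se = se, n_pos = m, n_neg = n)
}

#' Youden-index operating cutoff
#'
#' Maximises sensitivity + specificity - 1 over the midpoints between
#' adjacent distinct observed scores, calling `score > cutoff` positive.
#' Ties in the Youden index are broken toward the higher cutoff (higher
#' specificity).
#'
#' @inheritParams roc_auc
#' @return The cutoff value (numeric scalar), with attribute `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("degenerate cutoff: all scores are equal")
  cand <- (u[-1] + u[-length(u)]) / 2
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  j <- vapply(cand, function(cut) {
    sum(scores > cut & labels == 1L) / m +
      sum(scores <= cut & labels == 0L) / n - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cut <- cand[max(best)]  # highest cutoff among ties = higher specificity
  structure(cut, youden = max(j))
}

ci_prop <- function(x, n, conf_level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Diagnostic metrics at a cutoff
#'
#' Sensitivity, specificity, PPV and NPV from the 2x2 table obtained by
#' calling `score > cutoff` positive, each with an exact (Clopper-Pearson)
#' 95% CI. Predictive values are `NA` (flagged) when their denominator cell
#' is empty.
#'
#' @inheritParams roc_auc
#' @param cutoff operating threshold (e.g. from [youden_cutoff()]).
#' @return Data frame with one row per metric: `estimate`, `lo`, `hi`,
#'   `numerator`, `denominator`; attribute `table` holds the 2x2 counts.
#' @export
binary_metrics <- function(scores, labels, cutoff, conf_level = 0.95) {
  labels <- check_labels(labels)
  pred <- as.integer(scores > cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  mk <- function(metric, x, n) {
    ci <- ci_prop(x, n, conf_level)
    data.frame(metric = metric,
               estimate = if (n > 0) x / n else NA_real_,
               lo = ci[1], hi = ci[2], numerator = x, denominator = n,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    mk("sensitivity", tp, tp + fn),
    mk("specificity", tn, tn + fp),
    mk("ppv", tp, tp + fp),
    mk("npv", tn, tn + fn)
  )
  attr(out, "table") <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  attr(out, "cutoff") <- cutoff
  out
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two predictors measured on the same
#' subjects, using the covariance of the DeLong placement values and a
#' two-sided normal p-value.
#'
#' @param scores_a,scores_b paired predictors on identical subjects.
#' @inheritParams roc_auc
#' @return List with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::var(pa$v10) + stats::var(pb$v10) -
    2 * stats::cov(pa$v10, pb$v10)
  s01 <- stats::var(pa$v01) + stats::var(pb$v01) -
    2 * stats::cov(pa$v01, pb$v01)
  v <- s10 / m + s01 / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    p <- if (abs(d) < 1e-12) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = 0,
                z = if (abs(d) < 1e-12) 0 else Inf, p = p))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(v), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' @importFrom stats cov
NULL
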