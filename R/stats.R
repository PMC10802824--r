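#' Paired reference/automated measurements
#'
#' @param reference conventional (manual) measurements, strain %.
#' @param test automated measurements, aligned with `reference` by study.
#' @param ids optional study identifiers.
#' @return Object of class `paired_measurements`.
#' @export
paired_measurements <- function(reference, test, ids = NULL) {
  reference <- as.double(reference); test <- as.double(test)
  if (length(reference) != length(test))
    abort("invalid_pairs", "reference and test must have equal length")
  if (length(reference) < 2L)
    abort("invalid_pairs", "need at least 2 pairs")
  if (any(!is.finite(reference)) || any(!is.finite(test)))
    abort("invalid_pairs", "measurements must be finite")
  structure(list(reference = reference, test = test,
                 ids = ids %||% seq_along(reference)),
            class = "paired_measurements")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement statistics between reference and automated measurements
#'
#' Differences are taken reference minus test (manual minus automated).
#' Reports the Bland-Altman mean bias with its 1.96 SD limits of agreement
#' and a t-based 95% confidence interval on the bias, the mean absolute
#' difference (MAD) with its SD, the root-mean-squared error, the Pearson
#' correlation, and the Shapiro-Wilk p-value for normality of the bias.
#' Sample (n - 1) standard deviations are used throughout.
#'
#' @param pairs a [paired_measurements()] (or two vectors via `reference`,
#'   `test`).
#' @return Object of class `agreement_stats`: a list with `n`, `bias_mean`,
#'   `bias_sd`, `bias_ci` (length 2), `loa_lower`, `loa_upper`, `mad_mean`,
#'   `mad_sd`, `rmse`, `pearson_r` (NA with flag `r_undefined` when either
#'   series has zero variance), `normality_p`.
#' @export
agreement <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$reference - pairs$test
  n <- length(d)
  bias <- mean(d)
  bsd <- sd(d)
  r_undefined <- sd(pairs$reference) == 0 || sd(pairs$test) == 0
  r <- if (r_undefined) NA_real_ else cor(pairs$reference, pairs$test)
  norm_p <- if (bsd == 0 || n < 3L || n > 5000) NA_real_ else shapiro.test(d)$p.value
  se <- bsd / sqrt(n)
  structure(
    list(n = n, bias_mean = bias, bias_sd = bsd,
         bias_ci = bias + c(-1, 1) * qt(0.975, n - 1L) * se,
         loa_lower = bias - 1.96 * bsd, loa_upper = bias + 1.96 * bsd,
         mad_mean = mean(abs(d)), mad_sd = sd(abs(d)),
         rmse = sqrt(mean(d^2)), pearson_r = r, r_undefined = r_undefined,
         normality_p = norm_p),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): bias %.2f +/- %.2f [LoA %.2f, %.2f]\n",
              x$n, x$bias_mean, x$bias_sd, x$loa_lower, x$loa_upper))
  cat(sprintf("  MAD %.2f +/- %.2f, RMSE %.2f, r = %s, Shapiro-Wilk p = %s\n",
              x$mad_mean, x$mad_sd, x$rmse,
              ifelse(is.na(x$pearson_r), "undefined", sprintf("%.3f", x$pearson_r)),
              ifelse(is.na(x$normality_p), "NA", format.pval(x$normality_p))))
  invisible(x)
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation with tie correction:
#' `AUC = (concordant + 0.5 * tied) / (n_pos * n_neg)`, computed from
#' mid-ranks (exact, no trapezoidal plotting). Higher scores must indicate
#' the positive class; for regional strain the caller passes peak strain
#' directly, since less negative (worse) strain marks the abnormal segment.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    abort("invalid_pairs", "scores and labels must have equal length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    abort("undefined_statistic", "AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified Bland-Altman agreement table
#'
#' [agreement()] per stratum plus a pooled row. Strata with fewer than 3
#' pairs are reported as insufficient.
#'
#' @param pairs a [paired_measurements()].
#' @param strata vector of stratum labels aligned with the pairs.
#' @return Named list of `agreement_stats` (or the string `"insufficient"`),
#'   with the pooled result under `"pooled"`.
#' @export
bland_altman_table <- function(pairs, strata) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (length(strata) != length(pairs$reference))
    abort("invalid_pairs", "strata must align with the pairs")
  out <- list()
  for (s in unique(strata)) {
    keep <- strata == s
    out[[as.character(s)]] <- if (sum(keep) < 3L) "insufficient" else
      agreement(paired_measurements(pairs$reference[keep], pairs$test[keep],
                                    ids = pairs$ids[keep]))
  }
  out[["pooled"]] <- agreement(pairs)
  out
}
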