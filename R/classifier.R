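#' Decision rule for pure uric-acid stones
#'
#' The peak attenuation - peak point Laplacian rule: a stone is called
#' pure uric acid (UA) when `maxHU <= max_hu_cutoff` AND
#' `ppLapl <= pp_lapl_cutoff`, both comparisons inclusive. The published
#' default is 1000 HU / 195 HU; the alternative limits for the main UA
#' cluster are 800 HU / 190 HU; and the best single-parameter rule is
#' `maxHU <= 745` HU.
#'
#' @param max_hu_cutoff maxHU cutoff in HU (dual mode).
#' @param pp_lapl_cutoff ppLapl cutoff in HU (dual mode).
#' @param mode `"dual"` (attenuation + Laplacian) or `"single"`
#'   (attenuation only).
#' @param single_cutoff maxHU cutoff for single mode.
#' @return A `classifier_rule`.
#' @seealso [rule_default()], [rule_alternative()], [rule_single()]
#' @export
classifier_rule <- function(max_hu_cutoff = 1000, pp_lapl_cutoff = 195,
                            mode = c("dual", "single"),
                            single_cutoff = 745) {
  mode <- match.arg(mode)
  if (max_hu_cutoff <= 0 || pp_lapl_cutoff <= 0 || single_cutoff <= 0)
    stop("cutoffs must be positive")
  structure(list(max_hu_cutoff = max_hu_cutoff,
                 pp_lapl_cutoff = pp_lapl_cutoff,
                 mode = mode, single_cutoff = single_cutoff),
            class = "classifier_rule")
}

#' Published cutoff presets
#'
#' `rule_default()` is the 1000 HU / 195 HU dual rule, `rule_alternative()`
#' the 800 HU / 190 HU dual rule aimed at the main UA cluster, and
#' `rule_single()` the single-parameter `maxHU <= 745` HU rule.
#'
#' @return A [classifier_rule].
#' @export
rule_default <- function() classifier_rule(1000, 195)

#' @rdname rule_default
#' @export
rule_alternative <- function() classifier_rule(800, 190)

#' @rdname rule_default
#' @export
rule_single <- function() classifier_rule(mode = "single")

#' @export
print.classifier_rule <- function(x, ...) {
  if (x$mode == "dual")
    cat(sprintf("<classifier_rule> UA iff maxHU <= %g HU and ppLapl <= %g HU\n",
                x$max_hu_cutoff, x$pp_lapl_cutoff))
  else
    cat(sprintf("<classifier_rule> UA iff maxHU <= %g HU\n", x$single_cutoff))
  invisible(x)
}

#' Classify one stone as UA or non-UA/Mix
#'
#' Applies a [classifier_rule] to a stone's maxHU and ppLapl values. The
#' input may be a `stone_features` object or a list/row with `max_hu` and
#' `pp_lapl` fields.
#'
#' @param features a `stone_features` (or anything with `max_hu` and
#'   `pp_lapl`).
#' @param rule a [classifier_rule]; default [rule_default()].
#' @return A `classification_result` with `label` (`"UA"` or
#'   `"non-UA/Mix"`), the rule used and the two feature values.
#' @examples
#' classify_stone(list(max_hu = 966, pp_lapl = 191))$label   # "UA"
#' classify_stone(list(max_hu = 966, pp_lapl = 191),
#'                rule_alternative())$label                  # "non-UA/Mix"
#' @export
classify_stone <- function(features, rule = rule_default()) {
  stopifnot(inherits(rule, "classifier_rule"))
  max_hu <- features$max_hu
  pp_lapl <- features$pp_lapl
  if (is.null(max_hu) || is.na(max_hu))
    stop("`features` must carry a max_hu value")
  ua <- if (rule$mode == "single") {
    max_hu <= rule$single_cutoff
  } else {
    if (is.null(pp_lapl) || is.na(pp_lapl))
      stop("`features` must carry a pp_lapl value for the dual rule")
    max_hu <= rule$max_hu_cutoff && pp_lapl <= rule$pp_lapl_cutoff
  }
  structure(list(label = if (ua) "UA" else "non-UA/Mix",
                 rule = rule, max_hu = max_hu,
                 pp_lapl = if (is.null(pp_lapl)) NA_real_ else pp_lapl),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s  (maxHU %.1f, ppLapl %s)\n", x$label,
              x$max_hu,
              if (is.na(x$pp_lapl)) "-" else sprintf("%.1f", x$pp_lapl)))
  invisible(x)
}

#' Classify a table of stones
#'
#' @param features_df data frame with `max_hu` and `pp_lapl` columns (as
#'   written by [write_features_table()]).
#' @param rule a [classifier_rule].
#' @return Character vector of labels, one per row.
#' @export
classify_stones <- function(features_df, rule = rule_default()) {
  vapply(seq_len(nrow(features_df)), function(i)
    classify_stone(features_df[i, ], rule)$label, "")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by
#' inverting the binomial tail tests (beta-quantile form). The lower
#' bound is exactly 0 when `x = 0` and the upper exactly 1 when `x = n`.
#' A Wilson score interval is available for sensitivity analysis.
#'
#' @param x number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' round(100 * exact_binomial_ci(21, 22), 0)   # 77 100
#' @export
exact_binomial_ci <- function(x, n, level = 0.95,
                              method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer counts with 0 <= x <= n, n >= 1")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)")
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  c(lower = lo, upper = hi)
}

#' Diagnostic performance with exact confidence intervals
#'
#' Confusion counts and diagnostic metrics for UA classification, with UA
#' as the positive class. Sensitivity, specificity, accuracy, PPV and NPV
#' are reported as percentages with two-sided exact binomial confidence
#' intervals ([exact_binomial_ci()]). Metrics with a zero denominator are
#' reported as `NA`.
#'
#' @param predicted,truth equal-length character vectors of labels
#'   (`"UA"` / `"non-UA/Mix"`).
#' @param level confidence level (default 0.95).
#' @param ci_method passed to [exact_binomial_ci()].
#' @return An `evaluation_report`: counts `tp`, `fp`, `tn`, `fn` and a
#'   `metrics` data frame with `estimate`, `lower`, `upper` (percent),
#'   `successes`, `trials` per metric.
#' @examples
#' rep <- evaluate_classifier(c("UA", "UA", "non-UA/Mix"),
#'                            c("UA", "non-UA/Mix", "non-UA/Mix"))
#' rep$counts
#' @export
evaluate_classifier <- function(predicted, truth, level = 0.95,
                                ci_method = "clopper-pearson") {
  labs <- c("UA", "non-UA/Mix")
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` differ in length")
  if (length(truth) == 0L) stop("empty label vectors")
  if (!all(predicted %in% labs) || !all(truth %in% labs))
    stop("labels must be 'UA' or 'non-UA/Mix'")
  tp <- sum(predicted == "UA" & truth == "UA")
  fp <- sum(predicted == "UA" & truth != "UA")
  tn <- sum(predicted != "UA" & truth != "UA")
  fn <- sum(predicted != "UA" & truth == "UA")
  one <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_, x, n))
    ci <- exact_binomial_ci(x, n, level, ci_method)
    c(100 * x / n, 100 * ci[["lower"]], 100 * ci[["upper"]], x, n)
  }
  m <- rbind(sensitivity = one(tp, tp + fn),
             specificity = one(tn, tn + fp),
             accuracy    = one(tp + tn, tp + tn + fp + fn),
             ppv         = one(tp, tp + fp),
             npv         = one(tn, tn + fn))
  metrics <- data.frame(metric = rownames(m), estimate = m[, 1],
                        lower = m[, 2], upper = m[, 3],
                        successes = m[, 4], trials = m[, 5],
                        row.names = NULL)
  structure(list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 metrics = metrics, level = level, ci_method = ci_method),
            class = "evaluation_report")
}

# half-away-from-zero rounding (R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.evaluation_report <- function(x, ...) {
  cts <- x$counts
  cat(sprintf("<evaluation_report> TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              cts["tp"], cts["fp"], cts["tn"], cts["fn"], sum(cts)))
  for (i in seq_len(nrow(x$metrics))) {
    r <- x$metrics[i, ]
    if (is.na(r$estimate)) {
      cat(sprintf("  %-12s NA (zero denominator)\n", r$metric))
      next
    }
    # display granularity: accuracy to one decimal, the rest whole percent
    dg <- if (r$metric == "accuracy") 1 else 0
    cat(sprintf("  %-12s %s%% [%d/%d, %d%% CI (%s-%s%%)]\n", r$metric,
                format(round_half_up(r$estimate, dg)),
                r$successes, r$trials, round(100 * x$level),
                format(round_half_up(r$lower, dg)),
                format(round_half_up(r$upper, dg))))
  }
  invisible(x)
}
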