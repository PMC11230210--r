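#' Build a fitness table from fit results
#'
#' A fitness table holds one row per fitted unit (participant x condition
#' x outcome) and one column per model family, with cells carrying a
#' goodness-of-fit metric (R-squared or AIC).
#'
#' @param fits list of per-unit fit collections, each a named list of
#'   [fit_model()] results (as returned by [fit_all_families()]).
#' @param metric `"r2"` or `"aic"`.
#' @return a `fitness_table`: numeric matrix (units x families) with a
#'   `metric` attribute.
#' @export
fitness_table <- function(fits, metric = c("r2", "aic")) {
  metric <- match.arg(metric)
  fams <- names(fits[[1L]])
  m <- t(vapply(fits, function(f) {
    vapply(f[fams], function(x) x[[metric]], numeric(1))
  }, numeric(length(fams))))
  colnames(m) <- fams
  if (is.null(rownames(m))) rownames(m) <- paste0("unit", seq_len(nrow(m)))
  as_fitness_table(m, metric)
}

#' @rdname fitness_table
#' @param x numeric matrix of metric values (units x model families).
#' @export
as_fitness_table <- function(x, metric = "metric") {
  x <- as.matrix(x)
  if (anyNA(x)) stop("fitness table must have no missing cells")
  if (nrow(x) < 3L) stop("at least 3 rows are required for omnibus tests")
  structure(x, metric = metric, class = c("fitness_table", "matrix", "array"))
}

#' Normality gate for the model-comparison workflow
#'
#' Shapiro-Wilk test on each model's column of metric values; the
#' parametric branch (repeated-measures ANOVA + paired t) is taken only
#' when every column is consistent with normality, otherwise the
#' nonparametric branch (Friedman + Wilcoxon signed-rank).
#'
#' @param table a [fitness_table()] / numeric matrix.
#' @param alpha per-column normality test level (default 0.05).
#' @return list with `branch` (`"parametric"` or `"nonparametric"`) and
#'   `normality_p` (named per-column p-values).
#' @export
normality_gate <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  p <- apply(table, 2L, function(col) {
    if (length(unique(col)) == 1L)
      stop("constant column: Shapiro-Wilk test undefined")
    stats::shapiro.test(col)$p.value
  })
  list(branch = if (all(p > alpha)) "parametric" else "nonparametric",
       normality_p = p)
}

#' Omnibus test across model families
#'
#' Parametric branch: one-way repeated-measures ANOVA with unit as the
#' repeated factor (no sphericity correction applied; recorded in the
#' output for transparency). Nonparametric branch: Friedman rank test.
#'
#' @param table a [fitness_table()] / numeric matrix (units x families).
#' @param branch `"parametric"` or `"nonparametric"` (from
#'   [normality_gate()]).
#' @return list with `statistic`, `p`, `method`, and for the parametric
#'   branch `sphericity_correction = "none"`.
#' @export
omnibus_test <- function(table, branch = c("parametric", "nonparametric")) {
  branch <- match.arg(branch)
  table <- as.matrix(table)
  if (ncol(table) < 2L) stop("omnibus test requires at least 2 columns")
  if (branch == "nonparametric") {
    ft <- stats::friedman.test(table)
    stat <- unname(ft$statistic); p <- ft$p.value
    if (is.nan(stat)) { stat <- 0; p <- 1 }  # every row fully tied
    return(list(statistic = stat, p = p,
                method = "Friedman rank sum test"))
  }
  d <- data.frame(
    value = as.vector(table),
    model = factor(rep(colnames(table), each = nrow(table))),
    unit = factor(rep(seq_len(nrow(table)), times = ncol(table))))
  fit <- stats::aov(value ~ model + Error(unit / model), data = d)
  tab <- summary(fit)[["Error: unit:model"]][[1L]]
  list(statistic = tab["model", "F value"], p = tab["model", "Pr(>F)"],
       method = "one-way repeated-measures ANOVA",
       sphericity_correction = "none")
}

# Wilcoxon signed-rank test with Pratt handling of zero differences:
# zeros are ranked with the rest, then dropped from the signed statistic;
# normal approximation with zero- and tie-corrected variance.
wilcoxon_pratt <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  nz <- sum(d == 0)
  if (nz == n)
    return(list(statistic = NA_real_, p = NA_real_, all_zero = TRUE))
  Wp <- sum(r[d > 0])
  mu <- n * (n + 1) / 4 - nz * (nz + 1) / 4
  ties <- table(r[d != 0])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (Wp - mu) / sqrt(sig2)
  list(statistic = Wp, p = 2 * stats::pnorm(-abs(z)), all_zero = FALSE)
}

#' Pairwise post-hoc comparisons with Bonferroni-corrected level
#'
#' Tests every pair of model families with a paired t-test (parametric
#' branch) or a Wilcoxon signed-rank test with Pratt zero handling
#' (nonparametric branch), flagging significance at the corrected level
#' `alpha / C(5, 2) = 0.05 / 10 = 0.005` by default. Pairs whose
#' differences are identically zero are reported non-significant with a
#' diagnostic flag rather than an error. The operation computes all pairs
#' regardless of the omnibus outcome; gating on a significant omnibus is
#' the caller's responsibility (see [compare_models()], which records it).
#'
#' @param table a [fitness_table()] / numeric matrix.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param corrected_alpha per-pair significance level (default 0.005).
#' @return data frame with one row per pair: `model_a`, `model_b`,
#'   `statistic`, `p`, `significant`, `degenerate` (all-zero differences).
#' @export
pairwise_posthoc <- function(table, branch = c("parametric", "nonparametric"),
                             corrected_alpha = 0.005) {
  branch <- match.arg(branch)
  table <- as.matrix(table)
  fams <- colnames(table)
  pairs <- utils::combn(fams, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- table[, a] - table[, b]
    if (branch == "parametric") {
      if (stats::sd(d) == 0) {
        # all-zero differences: test undefined, flagged non-significant;
        # a constant nonzero difference is instead maximal evidence
        zero <- all(d == 0)
        return(data.frame(model_a = a, model_b = b,
                          statistic = if (zero) NA_real_ else sign(mean(d)) * Inf,
                          p = if (zero) NA_real_ else 0,
                          significant = !zero, degenerate = zero))
      }
      tt <- stats::t.test(table[, a], table[, b], paired = TRUE)
      data.frame(model_a = a, model_b = b, statistic = unname(tt$statistic),
                 p = tt$p.value, significant = tt$p.value < corrected_alpha,
                 degenerate = FALSE)
    } else {
      wt <- wilcoxon_pratt(d)
      data.frame(model_a = a, model_b = b, statistic = wt$statistic,
                 p = wt$p, significant = isTRUE(wt$p < corrected_alpha),
                 degenerate = wt$all_zero)
    }
  })
  do.call(rbind, out)
}

#' Full model-comparison workflow
#'
#' Chains the normality gate, the omnibus test on the selected branch and
#' the Bonferroni-corrected pairwise post-hoc table, mirroring the
#' group-comparison analysis of fitted R-squared / AIC values.
#'
#' @param table a [fitness_table()] / numeric matrix (units x families).
#' @param alpha omnibus / normality level (default 0.05).
#' @param corrected_alpha pairwise level (default `0.05 / 10`).
#' @return object of class `comparison_report`: list with `metric`,
#'   `branch`, `normality_p`, `omnibus`, `omnibus_significant`, `pairwise`
#'   (10-row data frame), `corrected_alpha`.
#' @export
compare_models <- function(table, alpha = 0.05, corrected_alpha = 0.05 / 10) {
  gate <- normality_gate(table, alpha)
  omni <- omnibus_test(table, gate$branch)
  pw <- pairwise_posthoc(table, gate$branch, corrected_alpha)
  structure(list(metric = attr(table, "metric"), branch = gate$branch,
                 normality_p = gate$normality_p, omnibus = omni,
                 omnibus_significant = omni$p < alpha, pairwise = pw,
                 corrected_alpha = corrected_alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> metric %s, %s branch\n",
              x$metric %||% "?", x$branch))
  cat(sprintf("  omnibus (%s): statistic %.4g, p = %.3g%s\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p,
              if (x$omnibus_significant) "" else " (not significant)"))
  cat(sprintf("  %d of %d pairs significant at alpha = %g\n",
              sum(x$pairwise$significant), nrow(x$pairwise),
              x$corrected_alpha))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
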