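#' Read / write long-format stride tables
#'
#' The on-disk interchange format is a long CSV with columns
#' `participant, condition, outcome, stride, session, value`; an empty
#' `value` cell marks a missing stride. One [stride_series()] is built per
#' `(participant, condition, outcome)` group, sorted by stride; stride
#' indices must be consecutive from 1 and session labels must be valid
#' protocol blocks.
#'
#' @param path CSV file path.
#' @return `read_stride_table` returns a named list of [stride_series()];
#'   `write_stride_table` returns `path` invisibly.
#' @export
read_stride_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("participant", "condition", "outcome", "stride", "session", "value")
  header <- names(utils::read.csv(path, nrows = 1L))
  if (!all(need %in% header))
    stop("stride table must have columns: ", paste(need, collapse = ", "))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant = "character",
                                      condition = "character",
                                      outcome = "character"))
  key <- interaction(d$participant, d$condition, d$outcome, drop = TRUE,
                     sep = "/")
  full_key <- paste(key, d$stride, sep = "#")
  if (anyDuplicated(full_key)) {
    dup <- full_key[duplicated(full_key)][1L]
    stop("duplicate (participant, condition, outcome, stride) row: ", dup)
  }
  out <- lapply(split(d, key), function(g) {
    g <- g[order(g$stride), , drop = FALSE]
    if (!identical(as.integer(g$stride), seq_len(nrow(g)))) {
      stop("strides for ", g$participant[1L], "/", g$condition[1L], "/",
           g$outcome[1L], " are not consecutive integers starting at 1")
    }
    stride_series(g$value, g$session,
                  participant = g$participant[1L],
                  condition = g$condition[1L], outcome = g$outcome[1L])
  })
  out
}

#' @rdname read_stride_table
#' @param series_list a [stride_series()] or list of them.
#' @export
write_stride_table <- function(series_list, path) {
  if (inherits(series_list, "stride_series")) series_list <- list(series_list)
  d <- do.call(rbind, lapply(series_list, as.data.frame))
  # full double precision so tables round-trip exactly
  d$value <- ifelse(is.na(d$value), "", sprintf("%.17g", d$value))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a fit result as JSON
#'
#' Serializes the winning spec, goodness-of-fit metrics, the per-restart
#' RSS trace and the fit options used, for downstream model comparison.
#'
#' @param fit a [fit_model()] result.
#' @param path JSON file path.
#' @param unit optional list of identifiers (participant, condition,
#'   outcome) stored alongside.
#' @return `read_fit_result` returns the parsed list; `write_fit_result`
#'   returns `path` invisibly.
#' @export
write_fit_result <- function(fit, path, unit = NULL) {
  o <- fit$options
  doc <- list(
    family = fit$family,
    spec = list(family = fit$spec$family, params = as.list(fit$spec$params),
                x_init = fit$spec$x_init),
    rss = fit$rss, r2 = fit$r2, aic = fit$aic,
    n_obs = fit$n_obs, k_params = fit$k_params,
    converged = fit$converged,
    restart_rss = fit$restart_rss,
    options = list(fit_start_stride = o$fit_start_stride,
                   n_restarts = o$n_restarts, seed = o$seed,
                   maxit = o$maxit, factr = o$factr, ndeps = o$ndeps,
                   strict_ordering_epsilon = o$strict_ordering_epsilon,
                   penalty_weight = o$penalty_weight))
  if (!is.null(unit)) doc$unit <- unit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a comparison report as JSON (and the pairwise table as CSV)
#'
#' @param report a [compare_models()] result.
#' @param path JSON output path.
#' @param csv_path optional CSV path for the flat 10-row pairwise table.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path, csv_path = NULL) {
  doc <- list(metric = report$metric, branch = report$branch,
              normality_p = as.list(report$normality_p),
              omnibus = report$omnibus,
              omnibus_significant = report$omnibus_significant,
              corrected_alpha = report$corrected_alpha,
              pairwise = report$pairwise)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$pairwise, csv_path, row.names = FALSE)
  invisible(path)
}
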