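#' Stride series: one outcome trajectory over consecutive strides
#'
#' A `stride_series` holds the per-stride values of one outcome measure
#' (hip extension angle HE, or normalized propulsive impulse NPI) for one
#' participant and one torque-pulse condition, together with the session
#' label of every stride and a missing-data mask. Stride indices are the
#' implicit positions `1..length(values)`.
#'
#' @param values numeric vector of per-stride responses; `NA` marks a
#'   missing stride (equivalently set `missing`).
#' @param sessions character vector, one of `"baseline"`, `"intervention"`,
#'   `"washout"` per stride; must form contiguous blocks in that order.
#' @param participant,condition,outcome identifiers carried along for
#'   bookkeeping (outcome conventionally `"HE"` or `"NPI"`).
#' @param missing optional logical vector; defaults to `is.na(values)`.
#'
#' @return an object of class `stride_series`: a list with elements
#'   `values`, `sessions`, `missing`, `participant`, `condition`, `outcome`.
#' @export
#' @examples
#' s <- stride_series(c(0.1, NA, 0.3), rep("baseline", 3))
#' s$missing
stride_series <- function(values, sessions,
                          participant = "P1", condition = "1",
                          outcome = "HE", missing = NULL) {
  values <- as.numeric(values)
  sessions <- as.character(sessions)
  if (length(values) == 0L)
    stop("stride series must contain at least one stride")
  if (length(values) != length(sessions))
    stop("'values' and 'sessions' must have equal length")
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing) | is.na(values)
  if (length(missing) != length(values))
    stop("'missing' must match the series length")
  check_sessions(sessions)
  structure(
    list(values = values, sessions = sessions, missing = missing,
         participant = as.character(participant),
         condition = as.character(condition),
         outcome = as.character(outcome)),
    class = "stride_series")
}

SESSION_LEVELS <- c("baseline", "intervention", "washout")

check_sessions <- function(sessions) {
  bad <- setdiff(unique(sessions), SESSION_LEVELS)
  if (length(bad))
    stop("unknown session label(s): ", paste(bad, collapse = ", "))
  # contiguous blocks in protocol order
  r <- rle(sessions)$values
  if (anyDuplicated(r))
    stop("session labels must form contiguous blocks")
  if (!identical(r, SESSION_LEVELS[SESSION_LEVELS %in% r]))
    stop("sessions must appear in the order baseline, intervention, washout")
  invisible(TRUE)
}

#' @export
length.stride_series <- function(x) length(x$values)

#' @export
print.stride_series <- function(x, ...) {
  n <- length(x$values)
  tab <- table(factor(x$sessions, levels = SESSION_LEVELS))
  cat(sprintf("<stride_series> participant %s, condition %s, outcome %s\n",
              x$participant, x$condition, x$outcome))
  cat(sprintf("  %d strides (%s); %d missing\n", n,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.stride_series <- function(x, ...) {
  data.frame(participant = x$participant, condition = x$condition,
             outcome = x$outcome, stride = seq_along(x$values),
             session = x$sessions,
             value = ifelse(x$missing, NA_real_, x$values),
             stringsAsFactors = FALSE)
}

# internal: replace values, keep metadata
set_values <- function(series, values, missing = rep(FALSE, length(values))) {
  series$values <- as.numeric(values)
  series$missing <- missing
  series
}

#' Validate that an input schedule is aligned with a stride series
#'
#' The exoskeleton input u(n) is a plain numeric vector, one entry per
#' stride, zero outside the intervention session.
#'
#' @param u numeric input schedule.
#' @param series a [stride_series()].
#' @return `u`, invisibly, after checking alignment.
#' @export
check_schedule <- function(u, series) {
  if (length(u) != length(series))
    stop("input schedule length (", length(u),
         ") does not match series length (", length(series), ")")
  off <- series$sessions != "intervention" & u != 0
  if (any(off))
    stop("input schedule must be zero on baseline and washout strides")
  invisible(u)
}
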