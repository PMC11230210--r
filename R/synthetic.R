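#' Torque-pulse training protocol
#'
#' The study protocol: a baseline block without assistance, a torque-pulse
#' intervention block, and a washout block, with the exoskeleton input
#' held at `u_level` during intervention and zero elsewhere. Defaults are
#' the 100 / 200 / 100-stride blocks of the experiment; `u_level = 1`
#' leaves the physical pulse magnitude to the model gain `d`, since
#' responses are SD-normalized anyway.
#'
#' @param n_baseline,n_intervention,n_washout block lengths in strides.
#' @param u_level input level during the intervention block.
#' @return object of class `protocol`.
#' @export
protocol <- function(n_baseline = 100L, n_intervention = 200L,
                     n_washout = 100L, u_level = 1) {
  stopifnot(n_baseline >= 0, n_intervention >= 0, n_washout >= 0,
            n_baseline + n_intervention + n_washout >= 1)
  structure(list(n_baseline = as.integer(n_baseline),
                 n_intervention = as.integer(n_intervention),
                 n_washout = as.integer(n_washout),
                 u_level = as.numeric(u_level)),
            class = "protocol")
}

#' Build the input schedule and session labels of a protocol
#'
#' @param proto a [protocol()].
#' @return list with `u` (numeric input per stride) and `sessions`
#'   (character labels aligned with `u`).
#' @export
#' @examples
#' p <- build_protocol(protocol())
#' range(which(p$u != 0))  # strides 101..300
build_protocol <- function(proto = protocol()) {
  u <- c(rep(0, proto$n_baseline),
         rep(proto$u_level, proto$n_intervention),
         rep(0, proto$n_washout))
  sessions <- c(rep("baseline", proto$n_baseline),
                rep("intervention", proto$n_intervention),
                rep("washout", proto$n_washout))
  list(u = u, sessions = sessions)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate one noisy stride series from a known model
#'
#' Simulates the canonical model over the protocol, adds i.i.d. Gaussian
#' observation noise of standard deviation `noise_sd`, and marks a random
#' fraction of strides missing. Deterministic given `seed`; the same seed
#' with a different `noise_sd` reuses the same underlying noise draws
#' (scaled), so noise-level sweeps are coupled by common random numbers.
#'
#' @param spec a [model_spec()] (must pass [check_constraints()]).
#' @param proto a [protocol()].
#' @param noise_sd observation-noise SD (normalized response units).
#' @param missing_rate fraction of strides marked missing, in `[0, 1)`.
#' @param seed integer seed.
#' @param participant,condition,outcome identifiers for the series.
#' @return a [stride_series()].
#' @export
generate_trajectory <- function(spec, proto = protocol(), noise_sd = 0.05,
                                missing_rate = 0, seed = 1L,
                                participant = "P1", condition = "1",
                                outcome = "HE") {
  stopifnot(missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  rep_con <- check_constraints(spec)
  if (!rep_con$valid)
    stop("invalid model spec: ",
         paste(rep_con$violations$constraint, collapse = ", "))
  sched <- build_protocol(proto)
  y <- simulate_ss(canonical_form(spec), sched$u)
  n <- length(y)
  with_seed(seed, {
    y_obs <- y + stats::rnorm(n) * noise_sd
    miss <- stats::runif(n) < missing_rate
  })
  if (all(miss)) miss[1L] <- FALSE  # keep the series interpolatable
  stride_series(ifelse(miss, NA_real_, y_obs), sched$sessions,
                participant = participant, condition = condition,
                outcome = outcome, missing = miss)
}

#' Cohort generation configuration
#'
#' @param n_participants cohort size (default 16, the study cohort).
#' @param truth a [model_spec()] giving the cohort-level true parameters;
#'   defaults to a modified UDL model with moderate retention and a
#'   persistent reference-state drift (`amu = 0.6`, `bmu = 0.2`,
#'   `cmu = 0.9`, `dmu = 1`).
#' @param jitter_sd per-parameter SD of the Gaussian inter-participant
#'   jitter; a scalar is recycled (default 0.02).
#' @param noise_sd observation-noise SD (default 0.05).
#' @param missing_rate fraction of missing strides (default 0).
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 16L,
                          truth = model_spec("modified_udl",
                                             c(amu = 0.6, bmu = 0.2,
                                               cmu = 0.9, dmu = 1)),
                          jitter_sd = 0.02, noise_sd = 0.05,
                          missing_rate = 0, seed = 1L) {
  stopifnot(n_participants >= 1L, missing_rate >= 0, missing_rate < 1)
  k <- length(truth$params)
  jitter_sd <- rep_len(as.numeric(jitter_sd), k)
  names(jitter_sd) <- names(truth$params)
  structure(list(n_participants = as.integer(n_participants), truth = truth,
                 jitter_sd = jitter_sd, noise_sd = as.numeric(noise_sd),
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort with a truth table
#'
#' Each participant's parameters are a Gaussian-jittered copy of the truth
#' spec, resampled (up to 1000 tries) until [check_constraints()] passes;
#' each series is then generated with [generate_trajectory()]. The
#' returned truth table allows parameter-recovery scoring.
#'
#' @param config a [cohort_config()].
#' @param proto a [protocol()].
#' @return list with `series` (list of [stride_series()]) and `truth`
#'   (data frame: `participant` plus one column per parameter).
#' @export
generate_cohort <- function(config = cohort_config(), proto = protocol()) {
  truth <- config$truth
  k <- length(truth$params)
  specs <- vector("list", config$n_participants)
  with_seed(config$seed, {
    for (i in seq_len(config$n_participants)) {
      for (try in seq_len(1000L)) {
        p <- truth$params + stats::rnorm(k) * config$jitter_sd
        sp <- model_spec(truth$family, p)
        if (check_constraints(sp)$valid) { specs[[i]] <- sp; break }
      }
      if (is.null(specs[[i]]))
        stop("parameter jitter repeatedly violated constraints for ",
             "participant ", i)
    }
  })
  series <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    series[[i]] <- generate_trajectory(
      specs[[i]], proto, noise_sd = config$noise_sd,
      missing_rate = config$missing_rate,
      seed = config$seed + 7919L * i,
      participant = sprintf("P%02d", i))
  }
  truth_tab <- cbind(
    data.frame(participant = vapply(series, `[[`, "", "participant"),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(specs, function(s) as.data.frame(t(s$params)))))
  list(series = series, truth = truth_tab)
}
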