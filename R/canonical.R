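#' Canonical discrete-time state-space realization of a model spec
#'
#' Every model family is simulated through a common canonical form
#' \deqn{X(n+1) = A X(n) + B u(n), \quad y(n+1) = C X(n+1) + D u(n+1)}
#' with state dimension 1 (single-state, UDL) or 2 (fast/slow, modified
#' UDL, two-state). The family-specific mappings are:
#' \itemize{
#'   \item single-state: `A = [a']`, `B = [b']`, `C = [c]`, `D = d`
#'   \item UDL: `A = [au + bu]`, `B = [bu * du]`, `C = [1]`, `D = du`
#'   \item fast/slow: `A = diag(af, as)`, `B = d * (bf, bs)`, `C = (1, 1)`,
#'     `D = d`
#'   \item modified UDL (state `(x0, x)`):
#'     `A = [[cmu, 1 - cmu], [1 - amu - bmu, amu + bmu]]`,
#'     `B = dmu * (1 - cmu, bmu)`, `C = (0, 1)`, `D = dmu`
#'   \item two-state: the matrices verbatim.
#' }
#'
#' @param spec a [model_spec()].
#' @param x_init optional initial state overriding the spec's (defaults to
#'   the spec's stored `x_init`, itself zero by default).
#' @return object of class `ss_realization`: list with `A` (k x k matrix),
#'   `B`, `C` (length-k vectors), `D` (scalar), `x_init`, `family`.
#' @export
#' @examples
#' canonical_form(model_spec("udl", c(au = 0.5, bu = 0.2, du = 1)))
canonical_form <- function(spec, x_init = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as.list(spec$params)
  r <- switch(spec$family,
    single_state = list(
      A = matrix(p$a_prime, 1, 1), B = p$b_prime, C = p$c, D = p$d),
    udl = list(
      A = matrix(p$au + p$bu, 1, 1), B = p$bu * p$du, C = 1, D = p$du),
    fast_slow = list(
      A = diag(c(p$af, p$as), 2L), B = p$d * c(p$bf, p$bs),
      C = c(1, 1), D = p$d),
    modified_udl = list(
      A = matrix(c(p$cmu, 1 - p$amu - p$bmu,
                   1 - p$cmu, p$amu + p$bmu), 2, 2),
      B = p$dmu * c(1 - p$cmu, p$bmu), C = c(0, 1), D = p$dmu),
    two_state = list(
      A = matrix(c(p$a11, p$a21, p$a12, p$a22), 2, 2),
      B = c(p$b1, p$b2), C = c(p$c1, p$c2), D = p$d),
    stop("unknown model family: ", spec$family))
  if (is.null(x_init)) x_init <- spec$x_init
  k <- nrow(r$A)
  if (length(x_init) != k)
    stop("x_init must have length ", k)
  structure(c(r, list(x_init = as.numeric(x_init), family = spec$family)),
            class = "ss_realization")
}

#' @export
print.ss_realization <- function(x, ...) {
  cat(sprintf("<ss_realization> family %s, state dim %d\n", x$family,
              nrow(x$A)))
  cat("A:\n"); print(unname(x$A))
  cat("B:", x$B, " C:", x$C, " D:", x$D, "\n")
  invisible(x)
}

#' Simulate a state-space realization over an input schedule
#'
#' Iterates `X(n+1) = A X(n) + B u(n)`, `y(n+1) = C X(n+1) + D u(n+1)` from
#' `X(0) = x_init`. The schedule holds the per-stride inputs `u(1..N)`
#' aligned with the reported outputs `y(1..N)`; `u(0)` is taken as the
#' schedule's first entry (zero for protocol schedules, which start in
#' baseline).
#'
#' @param realization an `ss_realization` from [canonical_form()].
#' @param u numeric input schedule (nonempty).
#' @param return_states if `TRUE`, also return the state trajectory
#'   (an N x k matrix of `X(n)`).
#' @return numeric vector `y(1..N)` of the same length as `u`, or a list
#'   `list(y, states)` when `return_states = TRUE`.
#' @export
simulate_ss <- function(realization, u, return_states = FALSE) {
  stopifnot(inherits(realization, "ss_realization"))
  u <- as.numeric(u)
  if (length(u) < 1L) stop("empty input schedule")
  y <- sim_lds(realization$A, realization$B, realization$C, realization$D,
               realization$x_init, u)
  if (!return_states) return(y)
  # recompute states in R (diagnostic path, not performance-critical)
  k <- nrow(realization$A)
  X <- matrix(0, length(u), k)
  x <- realization$x_init
  for (n in seq_along(u)) {
    uprev <- if (n == 1L) u[1L] else u[n - 1L]
    x <- drop(realization$A %*% x) + realization$B * uprev
    X[n, ] <- x
  }
  list(y = y, states = X)
}

#' Simulate a model from its native recursion (reference oracle)
#'
#' Runs each family's original update equations, with the error signal
#' `e(n) = y(n) - x(n)` where the family uses one, rather than the
#' canonical matrix iteration. Serves as the independent brute-force check
#' of `canonical_form()` followed by [simulate_ss()].
#'
#' For the single-state family, the stored canonical parameters (a', b',
#' c, d) are first mapped back to a native pair `b = b'/d`,
#' `a = a' + b - b*c` (any such pair realizes the same canonical model);
#' alternatively pass `native` with named entries `a, b, c, d` to simulate
#' a native parameterization directly.
#'
#' @param spec a [model_spec()].
#' @param u numeric input schedule (same convention as [simulate_ss()]).
#' @param native optional named vector `c(a=, b=, c=, d=)` for the
#'   single-state family's native form.
#' @return numeric vector of outputs, same length as `u`.
#' @export
simulate_native <- function(spec, u, native = NULL) {
  u <- as.numeric(u)
  N <- length(u)
  if (N < 1L) stop("empty input schedule")
  uprev <- c(u[1L], u[-N])   # u(0), u(1), ..., u(N-1)
  p <- as.list(spec$params)
  y <- numeric(N)

  if (spec$family == "single_state" || !is.null(native)) {
    if (is.null(native)) {
      if (p$d == 0 && p$b_prime != 0)
        stop("canonical single-state with d = 0, b' != 0 has no native form")
      b <- if (p$d != 0) p$b_prime / p$d else 0
      native <- c(a = p$a_prime + b - b * p$c, b = b, c = p$c, d = p$d)
    }
    a <- native[["a"]]; b <- native[["b"]]
    cc <- native[["c"]]; d <- native[["d"]]
    x <- spec$x_init
    yprev <- cc * x + d * uprev[1L]           # y(0) with u(0)
    for (n in seq_len(N)) {
      e <- yprev - x
      x <- a * x + b * e
      y[n] <- cc * x + d * u[n]
      yprev <- y[n]
    }
    return(y)
  }

  switch(spec$family,
    udl = {
      # x(n+1) = au x(n) + bu y(n) + (1 - au - bu) x0, x0 fixed at 0
      x <- spec$x_init
      yprev <- x + p$du * uprev[1L]
      for (n in seq_len(N)) {
        x <- p$au * x + p$bu * yprev
        y[n] <- x + p$du * u[n]
        yprev <- y[n]
      }
    },
    fast_slow = {
      # x = xf + xs; e(n) = y(n) - x(n) = d u(n)
      xf <- spec$x_init[1L]; xs <- spec$x_init[2L]
      yprev <- (xf + xs) + p$d * uprev[1L]
      for (n in seq_len(N)) {
        e <- yprev - (xf + xs)
        xf_new <- p$af * xf + p$bf * e
        xs_new <- p$as * xs + p$bs * e
        xf <- xf_new; xs <- xs_new
        y[n] <- (xf + xs) + p$d * u[n]
        yprev <- y[n]
      }
    },
    modified_udl = {
      # x0(n+1) = cmu x0(n) + (1 - cmu) y(n)
      # x(n+1)  = amu x(n) + bmu y(n) + (1 - amu - bmu) x0(n)
      x0 <- spec$x_init[1L]; x <- spec$x_init[2L]
      yprev <- x + p$dmu * uprev[1L]
      for (n in seq_len(N)) {
        x0_new <- p$cmu * x0 + (1 - p$cmu) * yprev
        x_new <- p$amu * x + p$bmu * yprev + (1 - p$amu - p$bmu) * x0
        x0 <- x0_new; x <- x_new
        y[n] <- x + p$dmu * u[n]
        yprev <- y[n]
      }
    },
    two_state = {
      # matrices are the native form; plain R iteration as the oracle
      A <- matrix(c(p$a11, p$a21, p$a12, p$a22), 2, 2)
      B <- c(p$b1, p$b2); C <- c(p$c1, p$c2)
      x <- spec$x_init
      for (n in seq_len(N)) {
        x <- drop(A %*% x) + B * uprev[n]
        y[n] <- sum(C * x) + p$d * u[n]
      }
    },
    stop("unknown model family: ", spec$family))
  y
}

#' Convert a native single-state parameterization to the canonical spec
#'
#' The native model `x(n+1) = a x(n) + b e(n)`, `y(n+1) = c x(n+1) +
#' d u(n+1)` with `e(n) = y(n) - x(n)` collapses to the canonical
#' `a' = a - b + b c`, `b' = b d`.
#'
#' @param a,b,c,d native single-state parameters.
#' @return a `model_spec` of family `single_state`.
#' @export
single_state_from_native <- function(a, b, c, d) {
  model_spec("single_state",
             c(a_prime = a - b + b * c, b_prime = b * d, c = c, d = d))
}

# spectral-radius slack: eigenvalues up to 1 + STAB_TOL count as stable
# (marginal stability admitted; the modified UDL transition matrix has a
# structural unit eigenvalue)
STAB_TOL <- 1e-9

#' Eigen-analysis of a realization's transition matrix
#'
#' @param realization an `ss_realization`.
#' @return list with `eigenvalues` (possibly complex), `magnitudes`,
#'   `spectral_radius` and logical `stable` (radius at most `1 + 1e-9`;
#'   marginal stability counts as stable).
#' @export
eigen_analysis <- function(realization) {
  ev <- eigen(realization$A, only.values = TRUE)$values
  mags <- Mod(ev)
  list(eigenvalues = ev, magnitudes = mags,
       spectral_radius = max(mags),
       stable = max(mags) <= 1 + STAB_TOL)
}

#' Check the validity constraints of a model spec
#'
#' Evaluates the family's fitting constraints: stability of the canonical
#' transition matrix for every family (spectral radius at most 1, with
#' marginal stability admitted), `as > af > 0` and `bf > bs` for the
#' fast/slow family, and `0 <= cmu <= 1` for the modified UDL family.
#' Violations are returned as data, never raised.
#'
#' @param spec a [model_spec()].
#' @return object of class `constraint_report`: list with logical `valid`
#'   and a data frame `violations` (columns `constraint`, `value`).
#' @export
check_constraints <- function(spec) {
  p <- as.list(spec$params)
  cons <- character(0); vals <- numeric(0)
  add <- function(name, value) {
    cons <<- c(cons, name); vals <<- c(vals, value)
  }
  if (spec$family == "fast_slow") {
    if (!(p$as > p$af)) add("as>af", p$as - p$af)
    if (!(p$af > 0)) add("af>0", p$af)
    if (!(p$bf > p$bs)) add("bf>bs", p$bf - p$bs)
  }
  if (spec$family == "modified_udl") {
    if (p$cmu < 0 || p$cmu > 1) add("cmu in [0,1]", p$cmu)
  }
  ea <- eigen_analysis(canonical_form(spec))
  if (!ea$stable) add("stability", ea$spectral_radius)
  structure(list(valid = length(cons) == 0L,
                 violations = data.frame(constraint = cons, value = vals,
                                         stringsAsFactors = FALSE)),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  if (x$valid) cat("<constraint_report> valid\n")
  else {
    cat("<constraint_report> INVALID:\n")
    print(x$violations)
  }
  invisible(x)
}

#' Asymptotic after-effect under washout (u = 0)
#'
#' The limit of the output as the stride count grows with the input held
#' at zero, starting from a given state (typically the state at the end of
#' training). Strictly stable single-state, UDL, fast/slow and two-state
#' models wash out to 0. The modified UDL transition matrix carries a
#' structural unit eigenvalue along the consensus direction `(1, 1)`: the
#' reference and planned states equalize at the weighted average
#' \deqn{y_\infty = \frac{(1-a_{mu}-b_{mu})\,x_{0,w} + (1-c_{mu})\,x_w}
#'                       {2-a_{mu}-b_{mu}-c_{mu}},}
#' the left-eigenvector mixture of the washout-entry state — a persistent,
#' generically nonzero after-effect.
#'
#' @param spec a [model_spec()].
#' @param state_at_washout state vector at washout onset (length 1 or 2).
#' @return scalar limit of `y`.
#' @export
#' @examples
#' m <- model_spec("modified_udl", c(amu = 0.6, bmu = 0.2, cmu = 0.9, dmu = 1))
#' after_effect_asymptote(m, c(0.21, 0.38))
after_effect_asymptote <- function(spec, state_at_washout) {
  p <- as.list(spec$params)
  k <- family_info(spec$family)$state_dim
  if (length(state_at_washout) != k)
    stop("state_at_washout must have length ", k)
  if (spec$family == "modified_udl") {
    lam2 <- p$amu + p$bmu + p$cmu - 1
    if (abs(lam2) >= 1 - STAB_TOL) {
      if (abs(p$amu + p$bmu + p$cmu - 2) < 1e-12)
        stop("degenerate modified UDL: amu + bmu + cmu = 2 gives a second ",
             "marginal mode with no finite asymptote")
      stop("free eigenvalue of the modified UDL model is not strictly ",
           "stable (|amu + bmu + cmu - 1| >= 1)")
    }
    den <- 2 - p$amu - p$bmu - p$cmu
    return(((1 - p$amu - p$bmu) * state_at_washout[1L] +
              (1 - p$cmu) * state_at_washout[2L]) / den)
  }
  ea <- eigen_analysis(canonical_form(spec))
  if (ea$spectral_radius >= 1 - STAB_TOL)
    stop("after-effect asymptote requires strict stability for family '",
         spec$family, "'")
  0
}
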