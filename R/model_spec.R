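#' The five motor-adaptation model families
#'
#' Family registry used throughout the package. Parameter counts follow the
#' model definitions: single-state (canonical a', b', c, d), UDL (au, bu,
#' du; reference movement x0 fixed at 0), two-state fast/slow (af, bf, as,
#' bs, d), modified UDL (amu, bmu, cmu, dmu), and the general two-state
#' model (the 9 free entries of A, B, C, D).
#'
#' @format A named list; each entry has `params` (parameter names in order),
#'   `k` (free parameter count) and `state_dim`.
#' @export
MODEL_FAMILIES <- list(
  single_state = list(
    params = c("a_prime", "b_prime", "c", "d"), k = 4L, state_dim = 1L),
  udl = list(
    params = c("au", "bu", "du"), k = 3L, state_dim = 1L),
  fast_slow = list(
    params = c("af", "bf", "as", "bs", "d"), k = 5L, state_dim = 2L),
  modified_udl = list(
    params = c("amu", "bmu", "cmu", "dmu"), k = 4L, state_dim = 2L),
  two_state = list(
    params = c("a11", "a12", "a21", "a22", "b1", "b2", "c1", "c2", "d"),
    k = 9L, state_dim = 2L)
)

family_info <- function(family) {
  info <- MODEL_FAMILIES[[family]]
  if (is.null(info))
    stop("unknown model family: ", family,
         " (expected one of ", paste(names(MODEL_FAMILIES), collapse = ", "), ")")
  info
}

#' Construct a model specification
#'
#' A `model_spec` bundles a family tag with its native parameter vector and
#' an optional initial state. The single-state family is stored in its
#' canonical (a', b', c, d) parameterization, which is the fitted one; the
#' native (a, b, c, d) form is accepted by [simulate_native()] directly.
#'
#' @param family one of `"single_state"`, `"udl"`, `"fast_slow"`,
#'   `"modified_udl"`, `"two_state"`.
#' @param params named numeric vector (names may be omitted if given in the
#'   registry order, see [MODEL_FAMILIES]).
#' @param x_init optional initial state (length 1 or 2 per family);
#'   defaults to zeros, the post-referencing baseline.
#' @return object of class `model_spec`.
#' @export
#' @examples
#' model_spec("modified_udl", c(amu = 0.6, bmu = 0.2, cmu = 0.9, dmu = 1))
model_spec <- function(family, params, x_init = NULL) {
  info <- family_info(family)
  params <- unlist(params)
  if (length(params) != info$k)
    stop(sprintf("family '%s' requires %d parameters, got %d",
                 family, info$k, length(params)))
  if (is.null(names(params)) || all(names(params) == "")) {
    names(params) <- info$params
  } else if (!setequal(names(params), info$params)) {
    stop(sprintf("parameter names for '%s' must be {%s}", family,
                 paste(info$params, collapse = ", ")))
  }
  params <- params[info$params]
  storage.mode(params) <- "double"
  if (is.null(x_init)) x_init <- rep(0, info$state_dim)
  if (length(x_init) != info$state_dim)
    stop(sprintf("x_init must have length %d for family '%s'",
                 info$state_dim, family))
  structure(list(family = family, params = params,
                 x_init = as.numeric(x_init)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> family %s (%d parameters)\n", x$family,
              length(x$params)))
  print(round(x$params, 6))
  if (any(x$x_init != 0))
    cat("  x_init:", paste(signif(x$x_init, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Number of free parameters of a model family
#'
#' @param family family tag (see [MODEL_FAMILIES]).
#' @return integer parameter count.
#' @export
n_params <- function(family) family_info(family)$k

#' Write / read a model spec as JSON
#'
#' Round-trips the family tag, named parameters and initial state.
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `read_model_spec` returns a `model_spec`; `write_model_spec`
#'   returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(
    list(family = spec$family, params = as.list(spec$params),
         x_init = spec$x_init),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(doc$family, unlist(doc$params), x_init = doc$x_init)
}
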