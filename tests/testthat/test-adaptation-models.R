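test_that("model specs validate family and parameter count", {
  expect_error(model_spec("bogus", c(a = 1)), "unknown model family")
  expect_error(model_spec("udl", c(au = 0.5, bu = 0.2)), "requires 3")
  expect_error(model_spec("udl", c(x = 1, y = 2, z = 3)), "parameter names")
  expect_error(model_spec("udl", c(au = 0.5, bu = 0.2, du = 1),
                          x_init = c(0, 0)), "length 1")
  # unnamed vectors are taken in registry order
  m <- model_spec("fast_slow", c(0.5, 0.3, 0.9, 0.1, 2))
  expect_named(m$params, c("af", "bf", "as", "bs", "d"))
})

test_that("canonical forms match the family templates", {
  # c = 1 collapses a' = a - b + b c to a
  s <- single_state_from_native(a = 0.9, b = 0.2, c = 1, d = 0.5)
  expect_equal(unname(s$params[c("a_prime", "b_prime")]), c(0.9, 0.1))

  fs <- canonical_form(model_spec("fast_slow",
                                  c(af = 0.5, bf = 0.3, as = 0.9, bs = 0.1,
                                    d = 2)))
  expect_equal(fs$A, diag(c(0.5, 0.9)))
  expect_equal(fs$B, c(0.6, 0.2))
  expect_equal(fs$C, c(1, 1))
  expect_equal(fs$D, 2)

  mu <- canonical_form(mudl_example())
  expect_equal(mu$A, matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2))
  expect_equal(mu$B, c(0.1, 0.2))
  expect_equal(mu$C, c(0, 1))
  expect_equal(mu$D, 1)

  ud <- canonical_form(udl_example())
  expect_equal(drop(ud$A), 0.7)
  expect_equal(ud$B, 0.2)
  expect_equal(c(ud$C, ud$D), c(1, 1))

  ts <- canonical_form(model_spec("two_state",
    c(a11 = 1, a12 = 2, a21 = 3, a22 = 4, b1 = 5, b2 = 6, c1 = 7, c2 = 8,
      d = 9)))
  expect_equal(ts$A, matrix(c(1, 3, 2, 4), 2, 2))  # matrices verbatim
  expect_equal(ts$B, c(5, 6))
})

test_that("simulation follows the printed recursion and hand-computed steps", {
  # zero input, zero state: identically zero for any realization
  set.seed(11)
  for (fam in names(MODEL_FAMILIES)) {
    r <- canonical_form(random_valid_spec(fam))
    expect_equal(simulate_ss(r, rep(0, 50)), rep(0, 50))
  }
  # hand recursion of the modified UDL matrix iteration under a step input
  y <- simulate_ss(canonical_form(mudl_example()), c(0, 1, 1, 1))
  expect_equal(y, c(0, 1, 1.2, 1.38))
  # hand recursion of the UDL update equations
  yu <- simulate_ss(canonical_form(udl_example()), c(0, 1, 1))
  expect_equal(yu, c(0, 1, 1.2))
  # bu = 0 removes the learning term: pure feedthrough on a decayed state
  yd <- simulate_ss(canonical_form(model_spec("udl", c(au = 0.5, bu = 0,
                                                       du = 1))),
                    c(0, 1, 1, 1))
  expect_equal(yd, c(0, 1, 1, 1))  # state never leaves zero
  expect_error(simulate_ss(canonical_form(udl_example()), numeric(0)),
               "empty")
})

test_that("native recursions agree with the canonical simulation (oracle)", {
  sched <- protocol_schedule()$u
  set.seed(2024)
  for (fam in names(MODEL_FAMILIES)) {
    for (rep in 1:25) {
      spec <- random_valid_spec(fam)
      y_can <- simulate_ss(canonical_form(spec), sched)
      y_nat <- simulate_native(spec, sched)
      expect_lt(max(abs(y_can - y_nat)), 1e-10)
    }
  }
  # the native single-state pair (a, b) and its canonical image coincide
  spec <- single_state_from_native(0.9, 0.2, 1, 0.5)
  y_nat <- simulate_native(spec, sched,
                           native = c(a = 0.9, b = 0.2, c = 1, d = 0.5))
  expect_lt(max(abs(simulate_ss(canonical_form(spec), sched) - y_nat)), 1e-12)
})

test_that("modified UDL with cmu = 1 reduces exactly to UDL", {
  sched <- protocol_schedule()$u
  set.seed(5)
  for (rep in 1:10) {
    au <- runif(1, 0, 0.9); bu <- runif(1, -0.5, 0.5); du <- runif(1, -2, 2)
    mu <- model_spec("modified_udl", c(amu = au, bmu = bu, cmu = 1, dmu = du))
    ud <- model_spec("udl", c(au = au, bu = bu, du = du))
    expect_equal(simulate_ss(canonical_form(mu), sched),
                 simulate_ss(canonical_form(ud), sched))
  }
})

test_that("fast/slow and modified UDL realizations embed in the two-state family", {
  sched <- protocol_schedule()$u
  set.seed(6)
  for (fam in c("fast_slow", "modified_udl")) {
    spec <- random_valid_spec(fam)
    r <- canonical_form(spec)
    ts <- model_spec("two_state",
                     c(a11 = r$A[1, 1], a12 = r$A[1, 2], a21 = r$A[2, 1],
                       a22 = r$A[2, 2], b1 = r$B[1], b2 = r$B[2],
                       c1 = r$C[1], c2 = r$C[2], d = r$D))
    expect_equal(simulate_ss(canonical_form(ts), sched),
                 simulate_ss(r, sched))
  }
})

test_that("constraint checking flags Table-style violations as data", {
  ok <- check_constraints(model_spec("fast_slow",
    c(af = 0.5, bf = 0.3, as = 0.9, bs = 0.1, d = 3)))
  expect_true(ok$valid)
  expect_equal(nrow(ok$violations), 0L)

  rev <- check_constraints(model_spec("fast_slow",
    c(af = 0.9, bf = 0.3, as = 0.5, bs = 0.1, d = 1)))
  expect_false(rev$valid)
  expect_true("as>af" %in% rev$violations$constraint)

  unst <- check_constraints(model_spec("single_state",
    c(a_prime = 1.05, b_prime = 0.1, c = 1, d = 1)))
  expect_false(unst$valid)
  expect_equal(unst$violations$constraint, "stability")

  bad_c <- check_constraints(model_spec("modified_udl",
    c(amu = 0.3, bmu = 0.1, cmu = 1.2, dmu = 1)))
  expect_false(bad_c$valid)
  expect_true(any(grepl("cmu", bad_c$violations$constraint)))
})

test_that("eigen-analysis: structural unit eigenvalue and marginal stability", {
  ea <- eigen_analysis(canonical_form(mudl_example()))
  expect_equal(sort(Re(ea$eigenvalues)), c(0.7, 1))
  expect_true(ea$stable)  # marginal counts as stable

  fs <- eigen_analysis(canonical_form(model_spec("fast_slow",
    c(af = 0.5, bf = 0.3, as = 0.9, bs = 0.1, d = 2))))
  expect_equal(fs$spectral_radius, 0.9)

  id1 <- eigen_analysis(canonical_form(model_spec("single_state",
    c(a_prime = 1, b_prime = 0, c = 1, d = 0))))
  expect_equal(id1$spectral_radius, 1)
  expect_true(id1$stable)

  # for random modified UDL parameters the spectrum is {1, amu+bmu+cmu-1}
  set.seed(31)
  for (rep in 1:20) {
    spec <- random_valid_spec("modified_udl")
    p <- spec$params
    ev <- sort(Re(eigen_analysis(canonical_form(spec))$eigenvalues))
    expect_lt(max(abs(ev - sort(c(1, p[["amu"]] + p[["bmu"]] + p[["cmu"]] - 1)))),
              1e-10)
  }
})

test_that("modified UDL conserves the left-eigenvector mixture under washout", {
  set.seed(32)
  for (rep in 1:10) {
    spec <- random_valid_spec("modified_udl")
    p <- as.list(spec$params)
    w <- c(1 - p$amu - p$bmu, 1 - p$cmu)
    r <- canonical_form(spec, x_init = runif(2, -1, 1))
    st <- simulate_ss(r, rep(0, 100), return_states = TRUE)$states
    q <- st %*% w
    expect_lt(max(abs(q - sum(w * r$x_init))), 1e-9)
  }
})

test_that("after-effect asymptotics separate the model families", {
  m <- mudl_example()
  # closed form equals the left-eigenvector weighted average ...
  expect_equal(after_effect_asymptote(m, c(0.21, 0.38)),
               (2 / 3) * 0.21 + (1 / 3) * 0.38, tolerance = 1e-12)
  # ... and the 500-step washout iteration
  r <- canonical_form(m, x_init = c(0.21, 0.38))
  y <- simulate_ss(r, rep(0, 500))
  expect_equal(y[500], after_effect_asymptote(m, c(0.21, 0.38)),
               tolerance = 1e-8)
  # consensus state is a fixed point
  expect_equal(after_effect_asymptote(m, c(0.7, 0.7)), 0.7)
  # strictly stable single-state / UDL / fast-slow wash out to zero
  expect_equal(after_effect_asymptote(udl_example(), 2.5), 0)
  expect_equal(after_effect_asymptote(model_spec("fast_slow",
    c(af = 0.5, bf = 0.3, as = 0.9, bs = 0.1, d = 2)), c(1, 2)), 0)
  # UDL washout is geometric to zero
  yu <- simulate_ss(canonical_form(udl_example(), x_init = 2.5), rep(0, 200))
  expect_lt(abs(yu[200]), 1e-20)
  # degenerate second marginal mode has no finite limit
  expect_error(after_effect_asymptote(
    model_spec("modified_udl", c(amu = 0.9, bmu = 0.2, cmu = 0.9, dmu = 1)),
    c(1, 2)), "marginal|strictly stable")
})

test_that("modified UDL under sustained input ramps when B leaves range(I - A)", {
  # gradual, non-exponential buildup: output grows linearly in n
  m <- mudl_example()
  y <- simulate_ss(canonical_form(m), rep(1, 2000))
  slopes <- diff(y[1500:2000])
  expect_gt(min(slopes), 0)
  expect_lt(max(abs(slopes - slopes[1])), 1e-6)
  # whereas a strictly stable UDL model saturates
  yu <- simulate_ss(canonical_form(udl_example()), rep(1, 2000))
  expect_lt(abs(yu[2000] - yu[1999]), 1e-12)
})

test_that("model specs round-trip through JSON exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- model_spec("fast_slow", c(af = 0.51, bf = 0.32, as = 0.93, bs = 0.11,
                                 d = -2.25), x_init = c(0.5, -1))
  write_model_spec(m, path)
  m2 <- read_model_spec(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$x_init, m$x_init)
  expect_identical(m2$family, m$family)
})
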