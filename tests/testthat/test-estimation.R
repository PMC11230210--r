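# short protocol + modest restart counts keep unit tests quick; the full
# study-sized conditions are exercised in test-acceptance.R
short_proto <- protocol(n_baseline = 100L, n_intervention = 120L,
                        n_washout = 60L)
short_opts <- function(...) fit_options(n_restarts = 15L, seed = 3L, ...)

test_that("r_squared matches its defining identity and edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(4, 5, 7, 2)
  expect_equal(r_squared(x, rep(mean(x), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)  # RSS = 1, TSS = 2
  expect_lt(r_squared(c(1, 2, 3), c(3, 3, 3)), 0)       # worse than mean
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("least-squares AIC trades fit against parameter count", {
  expect_equal(aic_ls(320, 320, 4), 8)                    # ln(1) = 0
  expect_equal(aic_ls(100, 50, 4) - aic_ls(100, 50, 3), 2)
  expect_equal(aic_ls(160, 320, 9), 320 * log(0.5) + 18)
  expect_equal(round(aic_ls(160, 320, 9), 2), -203.81)
  expect_warning(res <- aic_ls(0, 100, 3), "perfect fit")
  expect_identical(res, -Inf)
  # on equal RSS the ranking follows parameter counts 3 < 4 = 4 < 5 < 9
  ks <- vapply(names(MODEL_FAMILIES), n_params, integer(1))
  aics <- vapply(ks, aic_ls, numeric(1), rss = 50, n_obs = 320)
  expect_equal(order(aics),
               order(ks))
  expect_equal(aics[["single_state"]], aics[["modified_udl"]])
  expect_lt(aics[["udl"]], aics[["single_state"]])
  expect_lt(aics[["fast_slow"]], aics[["two_state"]])
})

test_that("noiseless UDL data are recovered to the identifiable combination", {
  truth <- udl_example()
  s <- generate_trajectory(truth, proto = protocol(), noise_sd = 0, seed = 1)
  sched <- build_protocol(protocol())$u
  f <- suppressWarnings(
    fit_model(s, sched, "udl", fit_options(n_restarts = 30L, seed = 2L)))
  p <- f$spec$params; tp <- truth$params
  expect_lt(abs((p[["au"]] + p[["bu"]]) - (tp[["au"]] + tp[["bu"]])), 1e-3)
  expect_lt(abs(p[["bu"]] * p[["du"]] - tp[["bu"]] * tp[["du"]]), 1e-3)
  expect_lt(abs(p[["du"]] - tp[["du"]]), 1e-3)
  expect_gt(f$r2, 0.999)
  expect_true(check_constraints(f$spec)$valid)
})

test_that("fits are deterministic in the seed and monotone in restarts", {
  truth <- mudl_example()
  s <- generate_trajectory(truth, proto = short_proto, noise_sd = 0.1,
                           seed = 8)
  sched <- build_protocol(short_proto)$u
  f1 <- fit_model(s, sched, "modified_udl", short_opts())
  f2 <- fit_model(s, sched, "modified_udl", short_opts())
  expect_identical(f1$spec$params, f2$spec$params)
  expect_identical(f1$restart_rss, f2$restart_rss)
  expect_identical(f1$rss, f2$rss)
  # nested seed sequences: more restarts never increase the best rss
  f3 <- fit_model(s, sched, "modified_udl",
                  fit_options(n_restarts = 5L, seed = 3L))
  f8 <- fit_model(s, sched, "modified_udl",
                  fit_options(n_restarts = 15L, seed = 3L))
  expect_equal(f8$restart_rss[seq_along(f3$restart_rss)], f3$restart_rss)
  expect_lte(f8$rss, f3$rss)
})

test_that("reported rss equals the recomputed free-run residual", {
  truth <- mudl_example()
  s <- generate_trajectory(truth, proto = short_proto, noise_sd = 0.1,
                           seed = 12)
  sched <- build_protocol(short_proto)$u
  for (fam in c("udl", "modified_udl", "single_state")) {
    f <- fit_model(s, sched, fam, short_opts())
    idx <- f$fit_start_stride:length(s)
    y_sim <- simulate_ss(canonical_form(f$spec), sched[idx])
    expect_equal(f$rss, sum((s$values[idx] - y_sim)^2), tolerance = 1e-10)
    expect_equal(f$n_obs, length(idx))
    expect_equal(f$k_params, n_params(fam))
  }
})

test_that("fitting degenerate all-zero data reports rss 0 and undefined R2", {
  sess <- c(rep("baseline", 100), rep("intervention", 20), rep("washout", 10))
  s <- stride_series(rep(0, 130), sess)
  sched <- rep(0, 130)
  f <- suppressWarnings(fit_model(s, sched, "udl", short_opts()))
  expect_equal(f$rss, 0)
  expect_true(is.na(f$r2))
  expect_identical(f$aic, -Inf)
})

test_that("fit window and schedule misalignment are rejected", {
  s <- generate_trajectory(udl_example(), proto = short_proto, seed = 1)
  sched <- build_protocol(short_proto)$u
  expect_error(fit_model(s, sched[-1], "udl", short_opts()), "length")
  expect_error(fit_model(s, sched, "udl",
                         fit_options(fit_start_stride = 500L)), "empty")
  smiss <- generate_trajectory(udl_example(), proto = short_proto,
                               missing_rate = 0.1, seed = 2)
  expect_error(fit_model(smiss, sched, "udl", short_opts()), "missing")
})

test_that("chained initialization makes supermodels at least as good (nesting)", {
  truth <- mudl_example()
  s <- generate_trajectory(truth, proto = short_proto, noise_sd = 0.1,
                           seed = 21)
  sched <- build_protocol(short_proto)$u
  fits <- fit_all_families(s, sched, short_opts())
  expect_named(fits, names(MODEL_FAMILIES))
  expect_gte(fits$two_state$r2, fits$modified_udl$r2 - 1e-6)
  expect_gte(fits$two_state$r2, fits$fast_slow$r2 - 1e-6)
  expect_gte(fits$single_state$r2, fits$udl$r2 - 1e-6)
  expect_equal(vapply(fits, `[[`, integer(1), "k_params"),
               c(single_state = 4L, udl = 3L, fast_slow = 5L,
                 modified_udl = 4L, two_state = 9L))
  for (f in fits) expect_true(check_constraints(f$spec)$valid)
  # subset selection
  two <- fit_all_families(s, sched, short_opts(),
                          families = c("udl", "modified_udl"))
  expect_named(two, c("udl", "modified_udl"))
})
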