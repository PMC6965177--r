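# Simulators: types, determinism, distributional fidelity.

test_that("true_signal validates and round-trips its covariance", {
  s <- true_signal(1, 2, 4, 9, rho0 = -0.5)
  expect_identical(s$cov_xy, -0.5 * sqrt(4 * 9))
  expect_identical(s$cov_xy / sqrt(s$var_x * s$var_y), s$rho0)
  expect_error(true_signal(var_x = 0), class = "attencor_config_error")
  expect_error(true_signal(rho0 = 1.2), class = "attencor_config_error")
})

test_that("multi_true_signal rejects asymmetric or non-PD covariances", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_s3_class(multi_true_signal(c(0, 0), m), "multi_true_signal")
  bad <- m; bad[1, 2] <- 0.7
  expect_error(multi_true_signal(c(0, 0), bad),
               class = "attencor_config_error")
  sing <- matrix(1, 2, 2)
  expect_error(multi_true_signal(c(0, 0), sing),
               class = "attencor_config_error")
})

test_that("error_spec enforces the model-kind invariants", {
  expect_error(error_spec("none", var_au = 0.1),
               class = "attencor_config_error")
  expect_error(error_spec("additive", var_mu = 0.1),
               class = "attencor_config_error")
  expect_error(error_spec("multiplicative", var_au = 0.1),
               class = "attencor_config_error")
  expect_error(error_spec("realistic", var_ac = c(0.1, 0.2)),
               class = "attencor_config_error")
  expect_error(error_spec("realistic", pi_ac = 0.5),
               class = "attencor_config_error")
  # generalized accepts all of the above
  e <- error_spec("generalized", var_ac = c(0.1, 0.2), pi_ac = 0.5)
  expect_identical(e$var_ac_y, 0.2)
})

test_that("simulate_bivariate is bit-reproducible and shaped correctly", {
  s <- true_signal(100, 100, 1, 1, rho0 = 0.8)
  e <- error_spec("realistic", var_au = 0.2, var_ac = 0.1, var_mu = 0.05,
                  var_mc = 0.02)
  m1 <- simulate_bivariate(s, e, n = 50, seed = 7)
  m2 <- simulate_bivariate(s, e, n = 50, seed = 7)
  expect_identical(unclass(m1), unclass(m2))
  expect_identical(dim(m1), c(50L, 2L))
  expect_true(all(is.finite(m1)))
  m3 <- simulate_bivariate(s, e, n = 50, seed = 8)
  expect_false(identical(unclass(m1), unclass(m3)))
  expect_error(simulate_bivariate(s, e, n = 1, seed = 1),
               class = "attencor_config_error")
})

test_that("error-free simulation recovers the true correlation", {
  s <- true_signal(100, 100, 1, 1, rho0 = 0.8)
  m <- simulate_bivariate(s, error_spec("none"), n = 1e4, seed = 42)
  tol <- 3 * (1 - 0.8^2) / sqrt(1e4)
  expect_lt(abs(sample_corr(m) - 0.8), tol)
})

test_that("toggling one error component leaves the others' draws intact", {
  s <- true_signal(0, 0, 1, 1, rho0 = 0.3)
  e_both <- error_spec("additive", var_au = c(0.5, 0.5), var_ac = 0.2)
  e_au <- error_spec("additive", var_au = c(0.5, 0.5))
  m_both <- simulate_bivariate(s, e_both, n = 100, seed = 3, debug = TRUE)
  m_au <- simulate_bivariate(s, e_au, n = 100, seed = 3, debug = TRUE)
  cb <- attr(m_both, "components"); ca <- attr(m_au, "components")
  expect_identical(cb$x0, ca$x0)
  expect_identical(cb$eau_x, ca$eau_x)
  expect_identical(cb$eau_y, ca$eau_y)
})

test_that("sample mean and variance match theory across models (4 SE)", {
  set.seed(11)
  n <- 1e5
  for (kind in all_kinds) {
    for (rep in 1:5) {
      s <- random_signal()
      e <- random_err(kind)
      m <- simulate_bivariate(s, e, n = n, seed = rep * 101 + match(kind, all_kinds))
      for (w in c("x", "y")) {
        col <- m[, w]
        mu <- if (w == "x") s$mu_x else s$mu_y
        v <- theoretical_var(s, e, w)
        # SE of the mean; SE of the variance approximated by the normal
        # formula (kurtosis of the product terms makes it conservative only
        # approximately, hence 6 SE for the variance under mult. error)
        expect_lt(abs(mean(col) - mu), 4 * sqrt(v / n))
        k_se <- if (kind %in% c("none", "additive")) 4 else 8
        expect_lt(abs(var(col) - v), k_se * sqrt(2 / n) * v)
      }
    }
  }
})

test_that("injected error streams are uncorrelated with the signal", {
  s <- true_signal(2, -1, 1.5, 0.8, rho0 = 0.4)
  e <- error_spec("realistic", var_au = 0.5, var_ac = 0.3, var_mu = 0.1,
                  var_mc = 0.05)
  m <- simulate_bivariate(s, e, n = 1e5, seed = 99, debug = TRUE)
  cmp <- attr(m, "components")
  for (nm in c("eau_x", "eac_x", "emu_x", "emc_x")) {
    cv <- cov(cmp$x0, cmp[[nm]])
    se <- sqrt(var(cmp$x0) * var(cmp[[nm]]) / length(cmp$x0))
    expect_lt(abs(cv), 4 * se)
  }
  # distinct error streams mutually uncorrelated
  cv <- cov(cmp$eau_x, cmp$eac_x)
  se <- sqrt(var(cmp$eau_x) * var(cmp$eac_x) / length(cmp$eau_x))
  expect_lt(abs(cv), 4 * se)
})

test_that("generalized model with pi = +1 reduces exactly to realistic", {
  s <- true_signal(3, 1, 1, 2, rho0 = 0.5)
  e_gen <- error_spec("generalized", var_au = 0.4, var_ac = 0.2,
                      var_mu = 0.05, var_mc = 0.02, pi_ac = 1, pi_mc = 1)
  e_real <- error_spec("realistic", var_au = 0.4, var_ac = 0.2,
                       var_mu = 0.05, var_mc = 0.02)
  m_gen <- simulate_bivariate(s, e_gen, n = 200, seed = 5)
  m_real <- simulate_bivariate(s, e_real, n = 200, seed = 5)
  expect_identical(strip_sample(m_gen), strip_sample(m_real))
  # and distributionally (different seeds, KS on each margin)
  a <- simulate_bivariate(s, e_gen, n = 1e4, seed = 21)
  b <- simulate_bivariate(s, e_real, n = 1e4, seed = 22)
  expect_gt(suppressWarnings(ks.test(a[, 1], b[, 1]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(a[, 2], b[, 2]))$p.value, 0.01)
})

test_that("multivariate simulator matches its stated structure", {
  # p = 2 realistic reduces in distribution to the bivariate simulator
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  ms <- multi_true_signal(c(5, 3), m)
  e <- error_spec("realistic", var_au = 0.3, var_ac = 0.2, var_mu = 0.05,
                  var_mc = 0.02)
  X <- simulate_multivariate(ms, e, n = 2e4, seed = 31)
  s2 <- true_signal(5, 3, 1, 1, 0.5)
  Y <- simulate_bivariate(s2, e, n = 2e4, seed = 77)
  expect_gt(suppressWarnings(ks.test(X[, 1], Y[, 1]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(X[, 2], Y[, 2]))$p.value, 0.01)
  # err = none: sample covariance converges to sigma0
  p <- 4
  set.seed(2)
  W <- matrix(rnorm(p * p), p)
  sig0 <- crossprod(W) / p + diag(p) * 0.5
  ms4 <- multi_true_signal(rnorm(p), sig0)
  X0 <- simulate_multivariate(ms4, error_spec("none"), n = 1e5, seed = 8)
  cv <- cov(unclass(X0))
  se <- sqrt((outer(diag(sig0), diag(sig0)) + sig0^2) / 1e5)
  expect_true(all(abs(cv - sig0) < 4 * se))
})

test_that("shared additive correlated error induces the Eq-53 correlation", {
  # p = 10, identity covariance, gamma^2 = 0.25 only: mean off-diagonal
  # sample correlation approaches 0.25 / 1.25 = 0.2
  p <- 10
  ms <- multi_true_signal(rep(0, p), diag(p))
  e <- error_spec("additive", var_ac = 0.25)
  X <- simulate_multivariate(ms, e, n = 5e4, seed = 13)
  R <- cor(unclass(X))
  off <- R[upper.tri(R)]
  expect_lt(abs(mean(off) - 0.2), 0.01)
})

test_that("sample_corr implements the product-moment estimator", {
  expect_equal(sample_corr(cbind(1:3, c(2, 4, 6))), 1.0)
  expect_equal(sample_corr(cbind(1:3, c(3, 2, 1))), -1.0)
  # hand-evaluated oracle (frozen from an independent computation)
  expect_equal(sample_corr(cbind(1:3, c(1, 2, 4))), 0.981980506061966,
               tolerance = 1e-12)
  # invariance to positive affine rescaling
  set.seed(4)
  m <- cbind(rnorm(20), rnorm(20))
  m2 <- cbind(3 * m[, 1] + 7, 0.5 * m[, 2] - 2)
  expect_equal(sample_corr(m2), sample_corr(m), tolerance = 1e-12)
  expect_error(sample_corr(cbind(rep(1, 5), 1:5)),
               class = "attencor_numeric_error")
  expect_error(sample_corr(cbind(1:2, 1:2)), class = "attencor_config_error")
})

test_that("theoretical_var matches the closed forms", {
  s <- true_signal(0, 0, 1, 1)
  expect_equal(theoretical_var(s, error_spec("additive", var_au = 0.75), "x"),
               1.75)
  s1 <- true_signal(1, 1, 1, 1)
  expect_equal(theoretical_var(s1, error_spec("multiplicative",
                                              var_mu = 0.1), "x"), 1.2)
  expect_equal(theoretical_var(s1, error_spec("none"), "y"), 1)
})

test_that("relative error-variance convention scales against the signal", {
  s <- true_signal(0, 0, 4, 4, rho0 = 0.5)
  e_rel <- error_spec("additive", var_au = 0.25, relative = TRUE)
  e_abs <- error_spec("additive", var_au = 1)
  expect_equal(theoretical_var(s, e_rel, "x"),
               theoretical_var(s, e_abs, "x"))
  expect_equal(expected_corr(s, e_rel)$rho, expected_corr(s, e_abs)$rho)
})

test_that("samples round-trip through CSV plus sidecar", {
  s <- true_signal(1, 2, 1, 1, rho0 = 0.3)
  e <- error_spec("additive", var_au = 0.5)
  smp <- simulate_bivariate(s, e, n = 20, seed = 6)
  d <- withr::local_tempdir()
  path <- file.path(d, "sample.csv")
  sidecar <- write_noisy_sample(smp, path)
  got <- as.matrix(utils::read.csv(path))
  expect_equal(unname(got), strip_sample(smp), tolerance = 1e-12)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  replay <- simulate_bivariate(
    true_signal(meta$signal$mu_x, meta$signal$mu_y, meta$signal$var_x,
                meta$signal$var_y, meta$signal$rho0),
    error_spec(meta$err$model_kind, var_au = c(meta$err$var_au_x,
                                               meta$err$var_au_y)),
    n = meta$n, seed = meta$seed)
  expect_identical(strip_sample(replay), strip_sample(smp))
})
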