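# Replicate-averaging, Monte-Carlo envelope and corrected-recovery
# experiments, plus the synthetic covariance generator that stands in for a
# real metabolomics data set (no real data is consumed by this package).

#' Simulate a technical-replicate data set
#'
#' Draws `S` biological samples of the true pair \eqn{(x_0, y_0)} and, for
#' each sample, `R` replicate measurements sharing the same true value but
#' with independent error realizations under `err`. This emulates an
#' experiment where each biological sample is measured repeatedly
#' (technical replicates): the replicate scatter is pure measurement
#' error.
#'
#' @param signal A [true_signal()].
#' @param err An [error_spec()].
#' @param S Number of biological samples (>= 3); default 5.
#' @param R Replicates per sample; default 12.
#' @param seed Integer seed.
#' @return A list of class `"replicate_set"` with `x` and `y` (each an
#'   `S x R` matrix) and `truth` (S x 2 matrix of the error-free values).
#' @export
simulate_replicate_set <- function(signal, err, S = 5, R = 12, seed = 1L) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  err <- resolve_error_spec(check_error_spec(err), signal)
  S <- check_count(S, "S", lower = 3L)
  R <- check_count(R, "R", lower = 1L)
  seed <- check_seed(seed)

  st <- rng_streams(seed)
  z <- draw_stream(st, "signal", function() matrix(stats::rnorm(2L * S), S, 2L))
  x0 <- signal$mu_x + sqrt(signal$var_x) * z[, 1]
  y0 <- signal$mu_y + sqrt(signal$var_y) *
    (signal$rho0 * z[, 1] + sqrt(1 - signal$rho0^2) * z[, 2])

  draw_mat <- function(name, sd)
    draw_stream(st, name, function() matrix(stats::rnorm(S * R, 0, sd), S, R))
  eau_x <- draw_mat("au_x", sqrt(err$var_au_x))
  eau_y <- draw_mat("au_y", sqrt(err$var_au_y))
  emu_x <- draw_mat("mu_x", sqrt(err$var_mu_x))
  emu_y <- draw_mat("mu_y", sqrt(err$var_mu_y))
  zac <- draw_stream(st, "ac", function()
    array(stats::rnorm(2L * S * R), c(S, R, 2L)))
  zmc <- draw_stream(st, "mc", function()
    array(stats::rnorm(2L * S * R), c(S, R, 2L)))
  eac_x <- sqrt(err$var_ac_x) * zac[, , 1]
  eac_y <- sqrt(err$var_ac_y) *
    (err$pi_ac * zac[, , 1] + sqrt(max(0, 1 - err$pi_ac^2)) * zac[, , 2])
  emc_x <- sqrt(err$var_mc_x) * zmc[, , 1]
  emc_y <- sqrt(err$var_mc_y) *
    (err$pi_mc * zmc[, , 1] + sqrt(max(0, 1 - err$pi_mc^2)) * zmc[, , 2])

  x <- x0 * (1 + emu_x + emc_x) + eau_x + eac_x
  y <- y0 * (1 + emu_y + emc_y) + eau_y + eac_y
  structure(list(x = x, y = y, truth = cbind(x0 = x0, y0 = y0)),
            class = "replicate_set")
}

#' Distribution of the correlation of replicate-averaged measurements
#'
#' For each of `n_draws` resampling rounds, `J` technical replicates are
#' chosen without replacement for every sample (independently per sample),
#' averaged, and the Pearson correlation of the two S-vectors of means is
#' computed. The spread of the returned correlations shows how technical
#' replication narrows (but does not debias) the sampling distribution of
#' the correlation.
#'
#' @param x,y `S x R` replicate matrices (same dimensions), e.g. the `x`
#'   and `y` of [simulate_replicate_set()].
#' @param J Number of replicates averaged per sample (`1 <= J <= R`).
#' @param n_draws Number of resampling rounds.
#' @param seed Integer seed.
#' @param paired If `TRUE` (default) the same replicate indices are used
#'   for `x` and `y` within a sample, as when both variables are read from
#'   the same replicate measurement; if `FALSE` indices are drawn
#'   independently for the two variables.
#' @return Numeric vector of `n_draws` correlations.
#' @export
replicate_avg_corr <- function(x, y, J, n_draws, seed = 1L, paired = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop_config("'x' and 'y' must have identical dimensions")
  S <- nrow(x); R <- ncol(x)
  if (S < 3L) stop_config("need at least S = 3 samples")
  J <- check_count(J, "J")
  if (J > R) stop_config("'J' (", J, ") exceeds available replicates (", R, ")")
  n_draws <- check_count(n_draws, "n_draws")
  seed <- check_seed(seed)

  st <- rng_streams(seed, "resample")
  draw_stream(st, "resample", function() {
    out <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      mx <- numeric(S); my <- numeric(S)
      for (i in seq_len(S)) {
        idx <- if (J == R) seq_len(R) else sample.int(R, J)
        mx[i] <- mean(x[i, idx])
        idy <- if (paired) idx else if (J == R) seq_len(R) else sample.int(R, J)
        my[i] <- mean(y[i, idy])
      }
      out[d] <- stats::cor(mx, my)
    }
    out
  })
}

#' Monte-Carlo envelope of the expected correlation
#'
#' For each true correlation \eqn{\rho_0} on a grid over \eqn{[-1, 1]},
#' repeatedly draws random signal and error configurations - means from
#' \eqn{U(0, \mu_{max})}, biological variances from \eqn{U(0,
#' \sigma_0^2)} (`var_scale`), every active error variance from
#' \eqn{U(0, \sigma_0^2/4)} - evaluates the analytic expected correlation
#' under the requested model, and records the minimum, maximum and the
#' 5th/95th percentiles of the realized \eqn{\rho}. Degenerate draws with
#' near-zero biological variance are rejected and redrawn (counted).
#'
#' @param rho0_step Grid step over \eqn{[-1, 1]}; must divide 2 evenly.
#' @param n_per_point Draws per grid point (>= 100); default `1e4`.
#' @param mu_max Upper bound of the uniform mean prior; default 23.4.
#' @param var_scale Upper bound of the uniform biological-variance prior.
#' @param model_kind `"additive"`, `"multiplicative"` or `"realistic"`.
#' @param sign `"pos"` or `"neg"` correlated error.
#' @param seed Integer seed.
#' @return Object of class `"envelope_result"`: list with `rho0_grid`,
#'   `stats` (matrix with columns `min`, `p5`, `p95`, `max`), `n_per_point`,
#'   `n_rejected`, `model_kind`, `sign`.
#' @export
mc_envelope <- function(rho0_step = 0.1, n_per_point = 1e4, mu_max = 23.4,
                        var_scale = 2, model_kind = c("additive",
                                                      "multiplicative",
                                                      "realistic"),
                        sign = c("pos", "neg"), seed = 1L) {
  model_kind <- match.arg(model_kind)
  sign <- match.arg(sign)
  rho0_step <- check_number(rho0_step, "rho0_step", lower = 1e-6, upper = 2)
  k <- 2 / rho0_step
  if (abs(k - round(k)) > 1e-8)
    stop_config("'rho0_step' must divide the grid [-1, 1] evenly")
  n_per_point <- check_count(n_per_point, "n_per_point", lower = 100L)
  mu_max <- check_number(mu_max, "mu_max", lower = 0)
  var_scale <- check_number(var_scale, "var_scale")
  if (var_scale <= 0) stop_config("'var_scale' must be positive")
  seed <- check_seed(seed)

  grid <- seq(-1, 1, by = rho0_step)
  st <- rng_streams(seed, "envelope")
  n_rejected <- 0L
  stats_mat <- matrix(NA_real_, length(grid), 4L,
                      dimnames = list(NULL, c("min", "p5", "p95", "max")))
  additive <- model_kind %in% c("additive", "realistic")
  multiplicative <- model_kind %in% c("multiplicative", "realistic")

  draw_stream(st, "envelope", function() {
    for (g in seq_along(grid)) {
      rho0 <- grid[g]
      vals <- numeric(n_per_point)
      for (i in seq_len(n_per_point)) {
        repeat {
          v <- stats::runif(2, 0, var_scale)
          if (min(v) > 1e-8 * var_scale) break
          n_rejected <<- n_rejected + 1L
        }
        mu <- stats::runif(2, 0, mu_max)
        ev <- stats::runif(4, 0, var_scale / 4)
        sig <- true_signal(mu[1], mu[2], v[1], v[2], rho0)
        err <- error_spec(model_kind,
                          var_au = if (additive) ev[1] else 0,
                          var_ac = if (additive) ev[2] else 0,
                          var_mu = if (multiplicative) ev[3] else 0,
                          var_mc = if (multiplicative) ev[4] else 0,
                          sign = sign)
        vals[i] <- expected_corr(sig, err)$rho
      }
      q <- stats::quantile(vals, c(0.05, 0.95), names = FALSE, type = 7)
      stats_mat[g, ] <<- c(min(vals), q[1], q[2], max(vals))
    }
  })
  structure(
    list(rho0_grid = grid, stats = stats_mat, n_per_point = n_per_point,
         n_rejected = n_rejected, model_kind = model_kind, sign = sign),
    class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("Expected-correlation envelope (%s error, %s sign)\n",
              x$model_kind, x$sign))
  cat(sprintf("  %d grid points, %d draws each, %d degenerate draws rejected\n",
              length(x$rho0_grid), x$n_per_point, x$n_rejected))
  invisible(x)
}

#' Synthetic multivariate covariance fixture
#'
#' Builds a random but reproducible p-variate signal with heterogeneous
#' means and variances and a mixed-sign, guaranteed positive-definite
#' correlation structure. It plays the role of the moments of a real
#' metabolomics data set in the envelope and recovery experiments, without
#' consuming any real data.
#'
#' The correlation matrix is obtained by normalizing \eqn{W W^\top} for a
#' p x p standard normal factor matrix `W`, which is positive definite
#' with probability one and yields both positive and negative
#' correlations of realistic magnitude.
#'
#' @param p Number of variables (>= 2).
#' @param mean_range Range `c(lo, hi)` of the uniform mean draw; default
#'   `c(0, 23.4)`.
#' @param var_range Range of the uniform variance draw; default
#'   `c(0.5, 3.5)` (average 2).
#' @param seed Integer seed.
#' @return A [multi_true_signal()].
#' @export
synth_covariance <- function(p, mean_range = c(0, 23.4),
                             var_range = c(0.5, 3.5), seed = 1L) {
  p <- check_count(p, "p", lower = 2L)
  if (length(mean_range) != 2L || diff(mean_range) < 0)
    stop_config("'mean_range' must be c(lo, hi) with lo <= hi")
  if (length(var_range) != 2L || diff(var_range) < 0 || var_range[1] <= 0)
    stop_config("'var_range' must be c(lo, hi) with 0 < lo <= hi")
  seed <- check_seed(seed)

  st <- rng_streams(seed, "fixture")
  draw_stream(st, "fixture", function() {
    mu <- stats::runif(p, mean_range[1], mean_range[2])
    v <- stats::runif(p, var_range[1], var_range[2])
    W <- matrix(stats::rnorm(p * p), p, p)
    C <- stats::cov2cor(tcrossprod(W))
    sigma0 <- diag(sqrt(v)) %*% C %*% diag(sqrt(v))
    sigma0 <- (sigma0 + t(sigma0)) / 2
    multi_true_signal(mu, sigma0)
  })
}

#' Corrected-correlation recovery experiment
#'
#' Simulates a p-variate data set under the realistic error model with all
#' error variances equal to `err_var`, computes all pairwise sample
#' correlations, corrects them with [correct_matrix()] using the *true*
#' error components, and averages both the uncorrected and corrected
#' coefficients over `reps` independent repetitions. With an exact
#' inverse and known components, the corrected coefficients recover the
#' true correlations up to sampling noise while the uncorrected ones stay
#' biased.
#'
#' @param p Number of variables; default 25.
#' @param n Observations per repetition; default `1e4`.
#' @param err_var Common value for all error variances (additive
#'   uncorrelated/correlated and multiplicative uncorrelated/correlated);
#'   default 0.1.
#' @param reps Repetitions; default 100.
#' @param seed Integer seed.
#' @param msignal Optional [multi_true_signal()]; by default a
#'   [synth_covariance()] fixture with a seed derived from `seed`.
#' @return A data frame with one row per variable pair: `i`, `j`, `rho0`,
#'   `r_mean` (uncorrected), `r_corrected_mean`; attribute `n_clipped`
#'   counts clipping events over all repetitions.
#' @export
recovery_experiment <- function(p = 25, n = 1e4, err_var = 0.1, reps = 100,
                                seed = 1L, msignal = NULL) {
  p <- check_count(p, "p", lower = 2L)
  n <- check_count(n, "n", lower = 10L)
  err_var <- check_number(err_var, "err_var", lower = 0)
  reps <- check_count(reps, "reps")
  seed <- check_seed(seed)
  if (is.null(msignal))
    msignal <- synth_covariance(p, seed = seed %% 100000L + 1L)
  if (!inherits(msignal, "multi_true_signal") || msignal$p != p)
    stop_config("'msignal' must be a multi_true_signal with p = ", p)
  err <- if (err_var == 0) error_spec("none") else
    error_spec("realistic", var_au = err_var, var_mu = err_var,
               var_ac = err_var, var_mc = err_var)

  R0 <- stats::cov2cor(msignal$sigma0)
  acc_r <- acc_c <- matrix(0, p, p)
  n_clipped <- 0L
  rep_seeds <- derive_seeds(seed, reps)
  for (k in seq_len(reps)) {
    X <- simulate_multivariate(msignal, err, n = n, seed = rep_seeds[k])
    R <- stats::cor(unclass(X))
    res <- correct_matrix(R, msignal, err)
    acc_r <- acc_r + R
    acc_c <- acc_c + res$corrected
    n_clipped <- n_clipped + res$n_clipped
  }
  acc_r <- acc_r / reps
  acc_c <- acc_c / reps
  ut <- which(upper.tri(R0), arr.ind = TRUE)
  out <- data.frame(i = ut[, 1], j = ut[, 2],
                    rho0 = R0[ut], r_mean = acc_r[ut],
                    r_corrected_mean = acc_c[ut])
  attr(out, "n_clipped") <- n_clipped
  out
}

# Derive k child seeds (< 2^31) deterministically from a root seed.
derive_seeds <- function(seed, k) {
  st <- rng_streams(seed, "seeder")
  draw_stream(st, "seeder", function()
    sample.int(.Machine$integer.max, k, replace = FALSE))
}
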