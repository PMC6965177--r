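# Simulation of measured data under the structural error models.
#
# Reproducibility contract: every simulator takes an integer seed and is
# bit-reproducible. Each stochastic component (signal, each error stream)
# draws from its own L'Ecuyer-CMRG substream spawned deterministically from
# the root seed, so switching one error component on or off never perturbs
# the draws of the others.

# Canonical component order; fixed so stream assignment is stable.
.stream_names <- c("signal", "au_x", "au_y", "ac", "mu_x", "mu_y", "mc")

rng_streams <- function(seed, names = .stream_names) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  out <- vector("list", length(names))
  names(out) <- names
  for (i in seq_along(names)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

# Draw by evaluating `expr` with .Random.seed set to the named substream.
draw_stream <- function(streams, name, fun) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  assign(".Random.seed", streams[[name]], envir = globalenv())
  fun()
}

#' Simulate bivariate measurements under an error model
#'
#' Draws `n` independent observations of the measured pair \eqn{(x, y)}:
#' the error-free signal is bivariate normal as described by `signal`, the
#' error components are zero-mean normal deviates drawn independently of
#' the signal and of each other, and they are combined according to the
#' structural equation of `err$model_kind` (see [error_spec()]).
#'
#' The correlated components are constructed from shared standard normal
#' deviates \eqn{z_1, z_2}:
#' \eqn{\epsilon_{ac_x} = \sigma_{ac_x} z_1},
#' \eqn{\epsilon_{ac_y} = \sigma_{ac_y} (\pi_{ac} z_1 +
#' \sqrt{1-\pi_{ac}^2}\, z_2)}, so that \eqn{\pi_{ac} = \pm 1} reproduces
#' the perfectly (anti-)correlated special models exactly, draw for draw.
#'
#' @param signal A [true_signal()].
#' @param err An [error_spec()].
#' @param n Number of observations (>= 2).
#' @param seed Integer seed.
#' @param debug If `TRUE`, the individual signal and error component draws
#'   are attached as attribute `"components"` (a named list of vectors),
#'   for auditing the independence contract.
#' @return An `n x 2` numeric matrix with columns `x`, `y`, of class
#'   `"noisy_sample"`; attributes `signal`, `err`, `seed` record the
#'   provenance for exact replay.
#' @examples
#' s <- true_signal(100, 100, 1, 1, rho0 = 0.8)
#' e <- error_spec("additive", var_au = 0.75)
#' m <- simulate_bivariate(s, e, n = 500, seed = 1)
#' sample_corr(m)  # attenuated below 0.8
#' @export
simulate_bivariate <- function(signal, err, n, seed, debug = FALSE) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  err <- resolve_error_spec(check_error_spec(err), signal)
  n <- check_count(n, "n", lower = 2L)
  seed <- check_seed(seed)

  st <- rng_streams(seed)
  z <- draw_stream(st, "signal", function() matrix(stats::rnorm(2L * n), n, 2L))
  x0 <- signal$mu_x + sqrt(signal$var_x) * z[, 1]
  y0 <- signal$mu_y + sqrt(signal$var_y) *
    (signal$rho0 * z[, 1] + sqrt(1 - signal$rho0^2) * z[, 2])

  # zero-variance components are skipped without consuming their stream;
  # independent substreams keep the other components' draws unchanged
  norm_or_0 <- function(name, sd)
    if (sd == 0) numeric(n) else
      draw_stream(st, name, function() stats::rnorm(n, 0, sd))
  pair_or_0 <- function(name, sd_x, sd_y, pi) {
    if (sd_x == 0 && sd_y == 0) return(list(x = numeric(n), y = numeric(n)))
    z <- draw_stream(st, name, function() matrix(stats::rnorm(2L * n), n, 2L))
    list(x = sd_x * z[, 1],
         y = sd_y * (pi * z[, 1] + sqrt(max(0, 1 - pi^2)) * z[, 2]))
  }
  eau_x <- norm_or_0("au_x", sqrt(err$var_au_x))
  eau_y <- norm_or_0("au_y", sqrt(err$var_au_y))
  emu_x <- norm_or_0("mu_x", sqrt(err$var_mu_x))
  emu_y <- norm_or_0("mu_y", sqrt(err$var_mu_y))
  ac <- pair_or_0("ac", sqrt(err$var_ac_x), sqrt(err$var_ac_y), err$pi_ac)
  mc <- pair_or_0("mc", sqrt(err$var_mc_x), sqrt(err$var_mc_y), err$pi_mc)
  eac_x <- ac$x; eac_y <- ac$y
  emc_x <- mc$x; emc_y <- mc$y

  x <- x0 * (1 + emu_x + emc_x) + eau_x + eac_x
  y <- y0 * (1 + emu_y + emc_y) + eau_y + eac_y

  out <- cbind(x = x, y = y)
  class(out) <- c("noisy_sample", class(out))
  attr(out, "signal") <- signal
  attr(out, "err") <- err
  attr(out, "seed") <- seed
  if (isTRUE(debug))
    attr(out, "components") <- list(
      x0 = x0, y0 = y0, eau_x = eau_x, eau_y = eau_y,
      eac_x = eac_x, eac_y = eac_y, emu_x = emu_x, emu_y = emu_y,
      emc_x = emc_x, emc_y = emc_y)
  out
}

#' Simulate multivariate measurements under a shared correlated error
#'
#' p-variate analogue of [simulate_bivariate()] used for network and
#' correction-recovery experiments. Per observation a single additive
#' correlated deviate \eqn{\epsilon_{ac}} and a single multiplicative
#' correlated deviate \eqn{\epsilon_{mc}} are shared by all variables
#' (positive-sign model), while the uncorrelated components are drawn
#' independently per variable:
#' \deqn{x_j = x_{0j}(1 + \epsilon_{mu_j} + \epsilon_{mc}) +
#'       \epsilon_{au_j} + \epsilon_{ac}.}
#'
#' @param signal A [multi_true_signal()].
#' @param err An [error_spec()] with the shared-scalar correlated structure
#'   (any non-generalized kind; `pi_ac`, `pi_mc` must be +1).
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return `n x p` matrix of class `"noisy_sample"` with provenance
#'   attributes as in [simulate_bivariate()].
#' @export
simulate_multivariate <- function(signal, err, n, seed) {
  if (!inherits(signal, "multi_true_signal"))
    stop_config("'signal' must be a multi_true_signal object")
  err <- check_error_spec(err)
  if (err$model_kind == "generalized")
    stop_config("the multivariate simulator requires the shared-scalar ",
                "correlated structure (non-generalized model kinds)")
  if (err$pi_ac != 1 || err$pi_mc != 1)
    stop_config("the multivariate shared error model requires pi_ac = ",
                "pi_mc = +1")
  if (err$var_au_x != err$var_au_y || err$var_mu_x != err$var_mu_y)
    stop_config("the multivariate simulator uses one uncorrelated error ",
                "variance per component, shared by all variables")
  if (err$relative) {
    vbar <- mean(diag(signal$sigma0))
    err <- error_spec(err$model_kind,
                      var_au = c(err$var_au_x, err$var_au_y) * vbar,
                      var_mu = c(err$var_mu_x, err$var_mu_y),
                      var_ac = err$var_ac_x * vbar,
                      var_mc = err$var_mc_x)
  }
  n <- check_count(n, "n", lower = 2L)
  seed <- check_seed(seed)
  p <- signal$p

  st <- rng_streams(seed, c("signal", "au", "mu", "ac", "mc"))
  z <- draw_stream(st, "signal", function() matrix(stats::rnorm(n * p), n, p))
  L <- chol(signal$sigma0)
  x0 <- z %*% L
  x0 <- sweep(x0, 2L, signal$mu, "+")

  eau <- draw_stream(st, "au", function()
    matrix(stats::rnorm(n * p, 0, sqrt(err$var_au_x)), n, p))
  emu <- draw_stream(st, "mu", function()
    matrix(stats::rnorm(n * p, 0, sqrt(err$var_mu_x)), n, p))
  eac <- draw_stream(st, "ac", function() stats::rnorm(n, 0, sqrt(err$var_ac_x)))
  emc <- draw_stream(st, "mc", function() stats::rnorm(n, 0, sqrt(err$var_mc_x)))

  x <- x0 * (1 + emu + emc) + eau + eac
  colnames(x) <- paste0("x", seq_len(p))
  class(x) <- c("noisy_sample", class(x))
  attr(x, "signal") <- signal
  attr(x, "err") <- err
  attr(x, "seed") <- seed
  x
}

#' Sample Pearson correlation
#'
#' The standard product-moment estimator \eqn{r_N} applied to the two
#' columns of `data`. Requires at least 3 observations and non-constant
#' columns.
#'
#' @param data A numeric matrix with (at least) two columns; only the
#'   first two are used.
#' @return The sample correlation, in \eqn{[-1, 1]}.
#' @export
sample_corr <- function(data) {
  data <- unclass(data)
  if (!is.matrix(data) || ncol(data) < 2L)
    stop_config("'data' must be a matrix with at least two columns")
  if (nrow(data) < 3L)
    stop_config("need at least N = 3 observations")
  x <- data[, 1]; y <- data[, 2]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_numeric("undefined correlation: a column has zero variance")
  stats::cor(x, y)
}

#' Model-implied variance of a measured variable
#'
#' The population variance of the measured `x` (or `y`) under the error
#' model: biological variance, plus additive error variances, plus the
#' multiplicative contribution \eqn{(\sigma_0^2 + \mu_0^2)(\sigma_{mu}^2 +
#' \sigma_{mc}^2)}.
#'
#' @param signal A [true_signal()].
#' @param err An [error_spec()].
#' @param which `"x"` or `"y"`.
#' @return The implied variance (positive).
#' @export
theoretical_var <- function(signal, err, which = c("x", "y")) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  which <- match.arg(which)
  err <- resolve_error_spec(check_error_spec(err), signal)
  if (which == "x") {
    v0 <- signal$var_x; mu <- signal$mu_x
    vau <- err$var_au_x; vac <- err$var_ac_x
    vmu <- err$var_mu_x; vmc <- err$var_mc_x
  } else {
    v0 <- signal$var_y; mu <- signal$mu_y
    vau <- err$var_au_y; vac <- err$var_ac_y
    vmu <- err$var_mu_y; vmc <- err$var_mc_y
  }
  v0 + (v0 + mu^2) * (vmu + vmc) + vau + vac
}

#' Write a simulated sample with a replay sidecar
#'
#' Writes the sample as a headered CSV and a JSON sidecar recording the
#' signal, error model, `n` and seed needed for exact replay.
#'
#' @param sample A `"noisy_sample"` from one of the simulators.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_noisy_sample <- function(sample, path) {
  if (!inherits(sample, "noisy_sample"))
    stop_config("'sample' must be a noisy_sample")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: ", dir)
  utils::write.csv(as.data.frame(unclass(sample)), path, row.names = FALSE)
  sig <- attr(sample, "signal")
  err <- attr(sample, "err")
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".json")
  meta <- list(
    signal = unclass(sig)[setdiff(names(unclass(sig)), "cov_xy")],
    err = unclass(err),
    n = nrow(sample),
    seed = attr(sample, "seed"),
    multivariate = inherits(sig, "multi_true_signal"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
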