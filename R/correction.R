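# Disattenuation: inverting the bias formulas to recover the true
# correlation from an observed sample correlation, given known (externally
# supplied) error-variance components.

#' Correct an observed correlation for measurement-error bias
#'
#' Inverts the expected-correlation formula of the error model: writing
#' \eqn{c = 1 + \pi_{mc}\sigma_{mc_x}\sigma_{mc_y}},
#' \deqn{\rho_0^{corrected} = \frac{r}{A c} -
#'   \frac{\pi_{ac}\gamma_x\gamma_y +
#'         \delta_x\delta_y\pi_{mc}\sigma_{mc_x}\sigma_{mc_y}}{c},}
#' which reduces to the classical Spearman disattenuation
#' \eqn{\rho_0 = r / A} for purely uncorrelated additive error. This is the
#' exact algebraic inverse of [expected_corr()].
#'
#' The corrected value can exceed 1 in magnitude because the sampling error
#' of a disattenuated coefficient is larger than that of the raw
#' coefficient; in that case it is clipped to \eqn{\pm 1} and flagged, and
#' the raw value is preserved for diagnostics.
#'
#' @param r Observed sample correlation in \eqn{[-1, 1]}.
#' @param signal A [true_signal()] (its `rho0` is ignored) or a list with
#'   `var_x`, `var_y` and, for multiplicative/realistic corrections,
#'   `mu_x`, `mu_y`.
#' @param err An [error_spec()].
#' @return Object of class `"correction_result"`: list with
#'   `rho_corrected` (clipped to \eqn{[-1, 1]}), `clipped` (logical),
#'   `raw_value`, and `inputs_echo`.
#' @examples
#' s <- true_signal(var_x = 1, var_y = 1)
#' e <- error_spec("additive", var_au = 0.75)
#' correct_corr(0.8 / 1.75, s, e)$rho_corrected  # 0.8
#' @export
correct_corr <- function(r, signal, err) {
  r <- check_number(r, "r", lower = -1, upper = 1)
  if (!inherits(signal, "true_signal")) {
    if (!is.list(signal) || is.null(signal$var_x) || is.null(signal$var_y))
      stop_config("'signal' must be a true_signal or a list with var_x, var_y")
    signal <- true_signal(signal$mu_x %||% 0, signal$mu_y %||% 0,
                          signal$var_x, signal$var_y, rho0 = 0)
  }
  err_res <- resolve_error_spec(check_error_spec(err), signal)
  if (err_res$model_kind == "none") {
    out <- list(rho_corrected = r, clipped = FALSE, raw_value = r,
                inputs_echo = list(r = r, signal = signal, err = err_res))
    class(out) <- "correction_result"
    return(out)
  }
  A <- attenuation_coeff(signal, err_res)
  if (!is.finite(A) || A <= 0)
    stop_numeric("attenuation coefficient is zero or undefined")
  rt <- error_ratios(signal, err_res)
  smc_term <- err_res$pi_mc * sqrt(err_res$var_mc_x * err_res$var_mc_y)
  cc <- 1 + smc_term
  if (cc == 0)
    stop_numeric("pathological input: 1 + pi_mc * sigma_mc_x * sigma_mc_y = 0")
  raw <- r / (A * cc) -
    (err_res$pi_ac * rt$gamma_x * rt$gamma_y +
       rt$delta_x * rt$delta_y * smc_term) / cc
  clipped <- abs(raw) > 1
  out <- list(rho_corrected = if (clipped) sign(raw) else raw,
              clipped = clipped, raw_value = raw,
              inputs_echo = list(r = r, signal = signal, err = err_res))
  class(out) <- "correction_result"
  out
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("Corrected correlation: %.6g (raw %.6g%s)\n",
              x$rho_corrected, x$raw_value,
              if (x$clipped) ", CLIPPED" else ""))
  invisible(x)
}

#' Correct a correlation matrix element-wise
#'
#' Applies [correct_corr()] to every off-diagonal entry of a correlation
#' matrix, using each pair's means and biological variances from
#' `msignal` and the shared error components of `err` (the shared-scalar
#' correlated structure assumed by [simulate_multivariate()]).
#'
#' @param R p x p symmetric correlation matrix with unit diagonal.
#' @param msignal A [multi_true_signal()] supplying per-variable means and
#'   biological variances.
#' @param err An [error_spec()] (non-generalized, shared correlated
#'   components).
#' @return A list with `corrected` (p x p symmetric matrix, unit
#'   diagonal), `raw` (pre-clipping values), `clipped` (logical matrix)
#'   and `n_clipped`. Clipping events are never silent: they are counted
#'   in `n_clipped`.
#' @export
correct_matrix <- function(R, msignal, err) {
  R <- as.matrix(R)
  if (!inherits(msignal, "multi_true_signal"))
    stop_config("'msignal' must be a multi_true_signal object")
  p <- msignal$p
  if (!all(dim(R) == c(p, p)))
    stop_config("'R' must be ", p, " x ", p, " to match the signal")
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop_config("'R' must be symmetric with unit diagonal")
  err <- check_error_spec(err)
  if (err$model_kind == "generalized")
    stop_config("matrix correction assumes the shared-scalar correlated ",
                "structure (non-generalized model kinds)")
  if (err$relative) {
    # same resolution rule as simulate_multivariate: scale additive
    # variances by the average biological variance
    vbar <- mean(diag(msignal$sigma0))
    err <- error_spec(err$model_kind,
                      var_au = c(err$var_au_x, err$var_au_y) * vbar,
                      var_mu = c(err$var_mu_x, err$var_mu_y),
                      var_ac = err$var_ac_x * vbar,
                      var_mc = err$var_mc_x,
                      pi_ac = err$pi_ac, pi_mc = err$pi_mc)
  }
  corrected <- raw <- diag(p)
  clipped <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      res <- correct_corr(R[i, j], pair_signal(msignal, i, j), err)
      corrected[i, j] <- corrected[j, i] <- res$rho_corrected
      raw[i, j] <- raw[j, i] <- res$raw_value
      clipped[i, j] <- clipped[j, i] <- res$clipped
    }
  }
  list(corrected = corrected, raw = raw, clipped = clipped,
       n_clipped = as.integer(sum(clipped) / 2L))
}

#' Plug-in estimate of additive uncorrelated error variance from replicates
#'
#' For the purely additive uncorrelated error model, the error variance can
#' be estimated from technical replicates as the pooled within-sample
#' variance: replicates of the same biological sample differ only through
#' the additive error term. This is the only variance-component estimator
#' fully supported by the classical disattenuation literature; estimating
#' the components of the correlated or multiplicative models from data is
#' out of scope here.
#'
#' @param replicates S x R matrix: S biological samples, R technical
#'   replicates each.
#' @return The pooled within-sample variance (a single number).
#' @export
estimate_additive_error_var <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (nrow(replicates) < 2L || ncol(replicates) < 2L)
    stop_config("need at least 2 samples and 2 replicates")
  if (anyNA(replicates)) stop_config("replicates must be complete")
  mean(apply(replicates, 1L, stats::var))
}
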