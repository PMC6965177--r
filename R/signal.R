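#' True (error-free) bivariate signal
#'
#' Describes the joint law of two error-free biological quantities
#' \eqn{(x_0, y_0)}, assumed bivariate normal with means \eqn{\mu_{x_0},
#' \mu_{y_0}}, biological variances \eqn{\sigma_{x_0}^2, \sigma_{y_0}^2}
#' and true correlation \eqn{\rho_0}. The implied covariance is
#' \eqn{\sigma_{x_0 y_0} = \rho_0 \sigma_{x_0} \sigma_{y_0}}.
#'
#' @param mu_x,mu_y Signal means.
#' @param var_x,var_y Biological variances (strictly positive).
#' @param rho0 True correlation in \eqn{[-1, 1]}.
#'
#' @return An object of class `"true_signal"`: a list with fields
#'   `mu_x`, `mu_y`, `var_x`, `var_y`, `rho0` and the implied covariance
#'   `cov_xy`.
#' @examples
#' sig <- true_signal(mu_x = 100, mu_y = 100, var_x = 1, var_y = 1, rho0 = 0.8)
#' sig$cov_xy  # 0.8
#' @export
true_signal <- function(mu_x = 0, mu_y = 0, var_x = 1, var_y = 1, rho0 = 0) {
  mu_x <- check_number(mu_x, "mu_x")
  mu_y <- check_number(mu_y, "mu_y")
  var_x <- check_number(var_x, "var_x")
  var_y <- check_number(var_y, "var_y")
  if (var_x <= 0 || var_y <= 0)
    stop_config("biological variances must be strictly positive")
  rho0 <- check_number(rho0, "rho0", lower = -1, upper = 1)
  structure(
    list(mu_x = mu_x, mu_y = mu_y, var_x = var_x, var_y = var_y,
         rho0 = rho0, cov_xy = rho0 * sqrt(var_x * var_y)),
    class = "true_signal")
}

#' @export
print.true_signal <- function(x, ...) {
  cat("True bivariate signal\n")
  cat(sprintf("  mu    = (%g, %g)\n", x$mu_x, x$mu_y))
  cat(sprintf("  var   = (%g, %g)\n", x$var_x, x$var_y))
  cat(sprintf("  rho0  = %g  (cov = %g)\n", x$rho0, x$cov_xy))
  invisible(x)
}

#' True multivariate signal
#'
#' A p-variate normal error-free signal with mean vector `mu` and
#' positive-definite covariance `sigma0`. Used by the multivariate
#' simulator and the corrected-recovery experiment.
#'
#' @param mu Numeric vector of length p.
#' @param sigma0 p x p symmetric positive-definite covariance matrix.
#' @return Object of class `"multi_true_signal"` with fields `mu`,
#'   `sigma0`, `p`.
#' @export
multi_true_signal <- function(mu, sigma0) {
  if (!is.numeric(mu) || anyNA(mu) || any(!is.finite(mu)))
    stop_config("'mu' must be a finite numeric vector")
  sigma0 <- as.matrix(sigma0)
  p <- length(mu)
  if (p < 2L) stop_config("need at least p = 2 variables")
  if (!all(dim(sigma0) == c(p, p)))
    stop_config("'sigma0' must be ", p, " x ", p)
  if (anyNA(sigma0) || any(!is.finite(sigma0)))
    stop_config("'sigma0' must be finite")
  if (max(abs(sigma0 - t(sigma0))) > 1e-12)
    stop_config("'sigma0' must be symmetric (tolerance 1e-12)")
  sigma0 <- (sigma0 + t(sigma0)) / 2
  ev <- eigen(sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_config("'sigma0' must be positive definite (min eigenvalue ",
                format(min(ev)), ")")
  structure(list(mu = as.numeric(mu), sigma0 = sigma0, p = p),
            class = "multi_true_signal")
}

#' @export
print.multi_true_signal <- function(x, ...) {
  cat(sprintf("True %d-variate signal\n", x$p))
  cat("  mean range: [", min(x$mu), ",", max(x$mu), "]\n")
  r <- stats::cov2cor(x$sigma0)
  off <- r[upper.tri(r)]
  cat("  correlation range: [", round(min(off), 3), ",",
      round(max(off), 3), "]\n")
  invisible(x)
}

# Extract the marginal bivariate true signal for variable pair (i, j).
pair_signal <- function(msignal, i, j) {
  s <- msignal$sigma0
  true_signal(mu_x = msignal$mu[i], mu_y = msignal$mu[j],
              var_x = s[i, i], var_y = s[j, j],
              rho0 = s[i, j] / sqrt(s[i, i] * s[j, j]))
}
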