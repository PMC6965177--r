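# Closed-form expected correlation and attenuation under measurement error.
#
# All models are handled through one generalized expression. Writing
# s_acx = sd of the additive correlated error on x (etc.),
# xi^2 = var_au / var0, gamma = s_ac / s0, delta = mu0 / s0, the population
# correlation of the measured pair is
#
#   rho = A * [ rho0 * (1 + pi_mc * s_mcx * s_mcy)
#               + pi_ac * gamma_x * gamma_y
#               + delta_x * delta_y * pi_mc * s_mcx * s_mcy ]
#
# with attenuation A = sqrt(var_x0 * var_y0 / (var(x) * var(y))), where
# var(x), var(y) are the model-implied measured variances. The special
# models (perfectly correlated errors, purely additive or multiplicative)
# are exact reductions with pi = +/-1 and the relevant variances zeroed.

#' Error-to-signal ratios
#'
#' Computes, per variable, the dimensionless ratios that parameterize the
#' bias formulas: \eqn{\xi^2 = \sigma_{au}^2/\sigma_0^2} (uncorrelated
#' additive error ratio), \eqn{\gamma = \sigma_{ac}/\sigma_0} (correlated
#' additive error ratio) and \eqn{\delta = \mu_0/\sigma_0} (signal-to-
#' biological-variation ratio).
#'
#' @param signal A [true_signal()].
#' @param err An [error_spec()].
#' @return Object of class `"error_ratios"`: list with `xi2_x`, `xi2_y`,
#'   `gamma_x`, `gamma_y`, `delta_x`, `delta_y`.
#' @export
error_ratios <- function(signal, err) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  err <- resolve_error_spec(check_error_spec(err), signal)
  sx <- sqrt(signal$var_x); sy <- sqrt(signal$var_y)
  structure(
    list(xi2_x = err$var_au_x / signal$var_x,
         xi2_y = err$var_au_y / signal$var_y,
         gamma_x = sqrt(err$var_ac_x) / sx,
         gamma_y = sqrt(err$var_ac_y) / sy,
         delta_x = signal$mu_x / sx,
         delta_y = signal$mu_y / sy),
    class = "error_ratios")
}

#' Attenuation coefficient
#'
#' The multiplicative factor \eqn{A \in (0, 1]} by which measurement error
#' shrinks the scale of the correlation:
#' \eqn{A = \sigma_{x_0}\sigma_{y_0} / \sqrt{\mathrm{var}(x)\,
#' \mathrm{var}(y)}} with the model-implied measured variances of
#' [theoretical_var()]. Equals 1 exactly when all error variances vanish,
#' and is strictly decreasing in every error-variance component.
#'
#' @inheritParams error_ratios
#' @return A single number in `(0, 1]`.
#' @examples
#' s <- true_signal(var_x = 1, var_y = 1, rho0 = 0.8)
#' attenuation_coeff(s, error_spec("additive", var_au = 0.75))  # 1/1.75
#' @export
attenuation_coeff <- function(signal, err) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  err <- resolve_error_spec(check_error_spec(err), signal)
  vx <- theoretical_var(signal, err, "x")
  vy <- theoretical_var(signal, err, "y")
  sqrt(signal$var_x * signal$var_y / (vx * vy))
}

#' Expected correlation of the measured variables
#'
#' The large-sample limit \eqn{\rho} of the sample correlation between the
#' measured `x` and `y` under the given error model. With no error
#' \eqn{\rho = \rho_0}; with purely uncorrelated additive error the
#' classical disattenuation relation \eqn{\rho = A\rho_0} holds; correlated
#' error components add mean-dependent terms that can inflate the
#' correlation or flip its sign.
#'
#' @inheritParams error_ratios
#' @return Object of class `"expected_corr"`: list with `rho`,
#'   `attenuation`, `ratios` (an [error_ratios()] object) and
#'   `model_kind`.
#' @examples
#' s <- true_signal(var_x = 1, var_y = 1, rho0 = 0.8)
#' e <- error_spec("additive", var_au = 0.25, var_ac = 0.25)
#' expected_corr(s, e)$rho  # (0.8 + 0.25) / 1.5 = 0.7
#' @export
expected_corr <- function(signal, err) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  err0 <- check_error_spec(err)
  err <- resolve_error_spec(err0, signal)
  A <- attenuation_coeff(signal, err)
  rt <- error_ratios(signal, err)
  smc_term <- err$pi_mc * sqrt(err$var_mc_x * err$var_mc_y)
  rho <- A * (signal$rho0 * (1 + smc_term) +
                err$pi_ac * rt$gamma_x * rt$gamma_y +
                rt$delta_x * rt$delta_y * smc_term)
  structure(
    list(rho = rho, attenuation = A, ratios = rt,
         model_kind = err$model_kind, rho0 = signal$rho0),
    class = "expected_corr")
}

#' @export
print.expected_corr <- function(x, ...) {
  cat(sprintf("Expected correlation under %s error\n", x$model_kind))
  cat(sprintf("  rho0 = %.6g  ->  rho = %.6g  (attenuation A = %.6g)\n",
              x$rho0, x$rho, x$attenuation))
  invisible(x)
}

#' Expected correlation when the true correlation is null
#'
#' Evaluates the expected correlation at \eqn{\rho_0 = 0}: the spurious
#' correlation created purely by correlated measurement error, e.g.
#' \eqn{\rho = A^a \gamma_x \gamma_y} for additive error.
#'
#' @inheritParams error_ratios
#' @return A single number.
#' @export
null_corr <- function(signal, err) {
  if (!inherits(signal, "true_signal"))
    stop_config("'signal' must be a true_signal object")
  s0 <- true_signal(signal$mu_x, signal$mu_y, signal$var_x, signal$var_y,
                    rho0 = 0)
  expected_corr(s0, err)$rho
}

#' Classify the bias regime of the expected correlation
#'
#' Compares the expected correlation \eqn{\rho} with the true correlation
#' \eqn{\rho_0}, numerically at absolute tolerance `tol`:
#' `unbiased` if \eqn{|\rho - \rho_0| \le} `tol`; `sign_flipped` if both
#' are nonzero with opposite signs; otherwise `attenuated`
#' (\eqn{|\rho| < |\rho_0|}) or `inflated` (\eqn{|\rho| > |\rho_0|}).
#'
#' For additive models with correlated error and attenuation \eqn{A < 1}
#' the report also carries the limiting-surface value
#' \eqn{S = \frac{A}{1-A}\gamma_x\gamma_y} (positively correlated error) or
#' \eqn{S = \frac{A}{A-1}\gamma_x\gamma_y} (negatively correlated error):
#' the \eqn{\rho_0} value at which the bias changes direction. `surface_S`
#' is `NA` when not applicable (no correlated additive error, non-additive
#' model, or \eqn{A = 1}).
#'
#' @inheritParams error_ratios
#' @param tol Absolute comparison tolerance (default `1e-12`).
#' @return Object of class `"regime_report"`: list with `regime` (one of
#'   `"unbiased"`, `"attenuated"`, `"inflated"`, `"sign_flipped"`),
#'   `surface_S`, `rho`, `rho0`, `attenuation`.
#' @export
classify_regime <- function(signal, err, tol = 1e-12) {
  ec <- expected_corr(signal, err)
  rho <- ec$rho; rho0 <- signal$rho0
  regime <-
    if (abs(rho - rho0) <= tol) "unbiased"
    else if (rho * rho0 < 0 && abs(rho) > tol && abs(rho0) > tol) "sign_flipped"
    else if (abs(rho) < abs(rho0)) "attenuated"
    else "inflated"
  err_res <- resolve_error_spec(check_error_spec(err), signal)
  A <- ec$attenuation
  gg <- ec$ratios$gamma_x * ec$ratios$gamma_y
  surface <- NA_real_
  if (err_res$model_kind == "additive" && gg > 0 && A < 1) {
    surface <- if (err_res$pi_ac >= 0) A / (1 - A) * gg else A / (A - 1) * gg
    if (abs(rho0 - surface) <= tol) regime <- "unbiased"
  }
  structure(
    list(regime = regime, surface_S = surface, rho = rho, rho0 = rho0,
         attenuation = A),
    class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("Bias regime: %s  (rho0 = %.6g, rho = %.6g)\n",
              x$regime, x$rho0, x$rho))
  if (!is.na(x$surface_S))
    cat(sprintf("  limiting surface S = %.6g\n", x$surface_S))
  invisible(x)
}

#' Limiting surface between attenuation and inflation (symmetric case)
#'
#' For the symmetric additive error model (\eqn{\xi_x^2 = \xi_y^2 =
#' \xi^2}, \eqn{\gamma_x^2 = \gamma_y^2 = \gamma^2}), returns the
#' \eqn{\rho_0} value separating the attenuation region from the inflation
#' region. With \eqn{A = 1/(1 + \xi^2 + \gamma^2)} this is
#' \eqn{S = \frac{A}{1-A}\gamma^2 = \gamma^2/(\xi^2+\gamma^2)} for
#' positively correlated error and its negation for negatively correlated
#' error.
#'
#' @param xi2 Uncorrelated additive error ratio \eqn{\xi^2 \ge 0}.
#' @param gamma2 Correlated additive error ratio \eqn{\gamma^2 \ge 0}.
#' @param sign `"pos"` or `"neg"` error correlation.
#' @return The surface value \eqn{S}.
#' @examples
#' limiting_surface(0.75, 0.25, "pos")  # 0.25
#' @export
limiting_surface <- function(xi2, gamma2, sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  xi2 <- check_number(xi2, "xi2", lower = 0)
  gamma2 <- check_number(gamma2, "gamma2", lower = 0)
  if (xi2 == 0 && gamma2 == 0)
    stop_config("no measurement error: the limiting surface is undefined")
  s <- gamma2 / (xi2 + gamma2)
  if (sign == "neg") -s else s
}
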