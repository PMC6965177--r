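#' Measurement-error model specification
#'
#' Describes one of five structural measurement-error models for a pair of
#' measured variables \eqn{(x, y)}:
#'
#' \describe{
#'   \item{`none`}{error-free measurement, \eqn{x = x_0}.}
#'   \item{`additive`}{\eqn{x = x_0 + \epsilon_{au_x} + \epsilon_{ac}},
#'     uncorrelated plus (optionally) correlated additive noise.}
#'   \item{`multiplicative`}{\eqn{x = x_0(1 + \epsilon_{mu_x} +
#'     \epsilon_{mc})}, noise proportional to the signal.}
#'   \item{`realistic`}{both components:
#'     \eqn{x = x_0(1 + \epsilon_{mu_x} + \epsilon_{mc}) +
#'     \epsilon_{au_x} + \epsilon_{ac}}.}
#'   \item{`generalized`}{as `realistic`, but the correlated components
#'     \eqn{(\epsilon_{ac_x}, \epsilon_{ac_y})} and
#'     \eqn{(\epsilon_{mc_x}, \epsilon_{mc_y})} may have unequal variances
#'     and arbitrary error correlations \eqn{\pi_{ac}, \pi_{mc} \in [-1,1]}.}
#' }
#'
#' All error terms are zero-mean normal, mutually independent and
#' independent of the signal. For the non-generalized models the correlated
#' terms are perfectly (anti-)correlated between `x` and `y`: the sign of
#' the correlation is set by `pi_ac` / `pi_mc`, restricted to -1 or +1
#' (the `sign` shorthand sets both at once).
#'
#' @param model_kind One of `"none"`, `"additive"`, `"multiplicative"`,
#'   `"realistic"`, `"generalized"`.
#' @param var_au,var_mu Uncorrelated additive / multiplicative error
#'   variances; scalar (shared by x and y) or length-2 `c(x, y)`.
#' @param var_ac,var_mc Correlated additive / multiplicative error
#'   variances. Scalar for the non-generalized models; scalar or length-2
#'   for `"generalized"`.
#' @param pi_ac,pi_mc Correlation of the correlated error components
#'   between x and y. Must be -1 or +1 unless `model_kind =
#'   "generalized"`.
#' @param sign Convenience shorthand: `"pos"` / `"neg"` sets `pi_ac` and
#'   `pi_mc` to +1 / -1. Ignored when `pi_ac`/`pi_mc` are given.
#' @param relative If `TRUE`, the variances are interpreted as fractions
#'   of the biological variance and are resolved against a signal when the
#'   spec is used (uncorrelated components against each variable's own
#'   variance, shared correlated components against the average biological
#'   variance). Default `FALSE`: variances are absolute.
#'
#' @return Object of class `"error_spec"` with per-variable fields
#'   `var_au_x`, `var_au_y`, `var_mu_x`, `var_mu_y`, `var_ac_x`,
#'   `var_ac_y`, `var_mc_x`, `var_mc_y`, plus `pi_ac`, `pi_mc`,
#'   `model_kind`, `relative`.
#' @examples
#' error_spec("additive", var_au = 0.75)
#' error_spec("generalized", var_ac = c(0.2, 0.3), pi_ac = 0.5)
#' @export
error_spec <- function(model_kind = c("none", "additive", "multiplicative",
                                      "realistic", "generalized"),
                       var_au = 0, var_mu = 0, var_ac = 0, var_mc = 0,
                       pi_ac = NULL, pi_mc = NULL, sign = c("pos", "neg"),
                       relative = FALSE) {
  model_kind <- match.arg(model_kind)
  sign <- match.arg(sign)
  default_pi <- if (sign == "pos") 1 else -1
  pi_ac <- pi_ac %||% default_pi
  pi_mc <- pi_mc %||% default_pi

  two <- function(v, name) {
    if (!is.numeric(v) || !length(v) %in% c(1L, 2L) || anyNA(v) ||
        any(!is.finite(v)))
      stop_config("'", name, "' must be a finite numeric of length 1 or 2")
    if (any(v < 0))
      stop_config("'", name, "' must be non-negative")
    if (length(v) == 1L) c(v, v) else as.numeric(v)
  }
  var_au <- two(var_au, "var_au")
  var_mu <- two(var_mu, "var_mu")
  var_ac <- two(var_ac, "var_ac")
  var_mc <- two(var_mc, "var_mc")
  pi_ac <- check_number(pi_ac, "pi_ac", lower = -1, upper = 1)
  pi_mc <- check_number(pi_mc, "pi_mc", lower = -1, upper = 1)

  if (model_kind == "none" &&
      any(c(var_au, var_mu, var_ac, var_mc) != 0))
    stop_config("model_kind 'none' requires all error variances to be 0")
  if (model_kind == "additive" && any(c(var_mu, var_mc) != 0))
    stop_config("additive model cannot carry multiplicative variances")
  if (model_kind == "multiplicative" && any(c(var_au, var_ac) != 0))
    stop_config("multiplicative model cannot carry additive variances")
  if (model_kind != "generalized") {
    if (var_ac[1] != var_ac[2] || var_mc[1] != var_mc[2])
      stop_config("non-generalized models require equal correlated error ",
                  "variances for x and y (use model_kind = 'generalized')")
    if (!pi_ac %in% c(-1, 1) || !pi_mc %in% c(-1, 1))
      stop_config("non-generalized models require pi_ac, pi_mc in {-1, +1}")
  }

  structure(
    list(model_kind = model_kind,
         var_au_x = var_au[1], var_au_y = var_au[2],
         var_mu_x = var_mu[1], var_mu_y = var_mu[2],
         var_ac_x = var_ac[1], var_ac_y = var_ac[2],
         var_mc_x = var_mc[1], var_mc_y = var_mc[2],
         pi_ac = pi_ac, pi_mc = pi_mc, relative = isTRUE(relative)),
    class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  cat("Measurement-error model:", x$model_kind,
      if (x$relative) "(variances relative to biological variance)" else "",
      "\n")
  cat(sprintf("  additive       uncorr (%g, %g)  corr (%g, %g)  pi_ac %+g\n",
              x$var_au_x, x$var_au_y, x$var_ac_x, x$var_ac_y, x$pi_ac))
  cat(sprintf("  multiplicative uncorr (%g, %g)  corr (%g, %g)  pi_mc %+g\n",
              x$var_mu_x, x$var_mu_y, x$var_mc_x, x$var_mc_y, x$pi_mc))
  invisible(x)
}

check_error_spec <- function(err) {
  if (!inherits(err, "error_spec"))
    stop_config("'err' must be an error_spec object")
  err
}

# Resolve a relative-convention spec against a concrete signal, returning a
# spec with absolute variances. Uncorrelated components scale with their own
# variable's biological variance; shared correlated components scale with the
# average biological variance (they must stay equal across variables).
resolve_error_spec <- function(err, signal) {
  check_error_spec(err)
  if (!err$relative) return(err)
  if (inherits(signal, "true_signal")) {
    vx <- signal$var_x; vy <- signal$var_y
  } else if (inherits(signal, "multi_true_signal")) {
    v <- diag(signal$sigma0)
    vx <- vy <- mean(v)  # per-variable scaling handled by callers pairwise
  } else stop_config("unknown signal type")
  vbar <- mean(c(vx, vy))
  out <- err
  out$var_au_x <- err$var_au_x * vx
  out$var_au_y <- err$var_au_y * vy
  out$var_mu_x <- err$var_mu_x
  out$var_mu_y <- err$var_mu_y
  out$var_ac_x <- err$var_ac_x * vbar
  out$var_ac_y <- err$var_ac_y * vbar
  out$var_mc_x <- err$var_mc_x
  out$var_mc_y <- err$var_mc_y
  out$relative <- FALSE
  out
}
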