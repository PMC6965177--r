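# Enzyme-kinetics experiment: biological variability from an irreversible
# enzyme-catalyzed reaction (Michaelis-Menten mechanism), used to show how
# additive measurement error degrades correlation-network inference.
#
# State (P1, P2, P3) = (substrate, enzyme-substrate complex, product):
#   dP1/dt = -k1 P1 (ET - P2) + k_{-1} P2
#   dP2/dt = +k1 P1 (ET - P2) - k_{-1} P2 - k2 P2
#   dP3/dt = +k2 P2
# This conserves total mass P1 + P2 + P3. A variant with the second
# equation's reverse term written as -k_{-1} P1 (which breaks mass
# conservation) is available via `as_printed = TRUE` for cross-checking;
# it is not the default because it contradicts the stated mechanism.

#' Kinetic parameters for the enzyme reaction model
#'
#' @param k1,k_minus1,k2 Rate constants (association, dissociation,
#'   catalysis), arbitrary units. Defaults 30, 20, 10.
#' @param ET Total enzyme concentration. Default 1.
#' @param P1_0 Initial substrate concentration. Default 5.
#' @param t_sample Time at which the profiles are sampled. Default 0.4.
#' @return Object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k1 = 30, k_minus1 = 20, k2 = 10, ET = 1,
                           P1_0 = 5, t_sample = 0.4) {
  for (nm in c("k1", "k_minus1", "k2", "ET", "P1_0", "t_sample")) {
    v <- get(nm)
    if (check_number(v, nm) <= 0) stop_config("'", nm, "' must be positive")
  }
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, ET = ET,
                 P1_0 = P1_0, t_sample = t_sample),
            class = "kinetic_params")
}

# Adaptive Dormand-Prince 5(4) integrator, sufficient for this small
# non-stiff system. Returns the state at t_end.
ode_dp45 <- function(f, y0, t_end, rtol = 1e-8, atol = 1e-10,
                     max_steps = 100000L) {
  # Butcher tableau (Dormand & Prince 1980)
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247
  a64 <- 49 / 176; a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  # embedded 4th-order weights
  e1 <- 5179 / 57600; e3 <- 7571 / 16695; e4 <- 393 / 640
  e5 <- -92097 / 339200; e6 <- 187 / 2100; e7 <- 1 / 40

  t <- 0; y <- y0
  h <- t_end / 100
  k1v <- f(t, y)
  for (step in seq_len(max_steps)) {
    if (t >= t_end) break
    h <- min(h, t_end - t)
    k2v <- f(t + c2 * h, y + h * a21 * k1v)
    k3v <- f(t + c3 * h, y + h * (a31 * k1v + a32 * k2v))
    k4v <- f(t + c4 * h, y + h * (a41 * k1v + a42 * k2v + a43 * k3v))
    k5v <- f(t + c5 * h,
             y + h * (a51 * k1v + a52 * k2v + a53 * k3v + a54 * k4v))
    k6v <- f(t + h, y + h * (a61 * k1v + a62 * k2v + a63 * k3v +
                               a64 * k4v + a65 * k5v))
    y5 <- y + h * (b1 * k1v + b3 * k3v + b4 * k4v + b5 * k5v + b6 * k6v)
    k7v <- f(t + h, y5)
    y4 <- y + h * (e1 * k1v + e3 * k3v + e4 * k4v + e5 * k5v + e6 * k6v +
                     e7 * k7v)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1v <- k7v  # FSAL
    }
    fac <- 0.9 * if (err > 0) err^(-1 / 5) else 5
    h <- h * min(5, max(0.2, fac))
    if (!all(is.finite(y)))
      stop_numeric("ODE integration diverged")
  }
  if (t < t_end)
    stop_numeric("ODE integration failed to reach t = ", t_end)
  y
}

kinetic_rhs <- function(params, as_printed = FALSE) {
  k1 <- params$k1; km1 <- params$k_minus1; k2 <- params$k2; ET <- params$ET
  if (as_printed) {
    function(t, y) {
      v <- k1 * y[1] * (ET - y[2])
      c(-v + km1 * y[2], -km1 * y[1] + v - k2 * y[2], k2 * y[2])
    }
  } else {
    function(t, y) {
      v <- k1 * y[1] * (ET - y[2])
      c(-v + km1 * y[2], v - km1 * y[2] - k2 * y[2], k2 * y[2])
    }
  }
}

#' Concentration profiles from the enzyme-kinetics model
#'
#' Generates `n_profiles` realizations of the metabolite concentrations
#' (P1, P2, P3) at `params$t_sample`. For each profile the kinetic
#' parameters `k1`, `k_minus1`, `k2`, `ET` and the initial substrate
#' `P1_0` are independently drawn from uniform distributions
#' \eqn{U((1-\mathrm{jitter})v, (1+\mathrm{jitter})v)} around their
#' population values, emulating biological variability; the system is then
#' integrated from \eqn{(P1_0, 0, 0)}.
#'
#' @param params A [kinetic_params()].
#' @param n_profiles Number of profiles (>= 2).
#' @param jitter Fractional half-width of the uniform parameter jitter in
#'   `[0, 1)`; default 0.1.
#' @param seed Integer seed.
#' @param as_printed Integrate the non-mass-conserving variant of the
#'   system (see source); default `FALSE`.
#' @param rtol,atol Solver tolerances.
#' @return `n_profiles x 3` matrix with columns `P1`, `P2`, `P3`.
#' @export
mm_profiles <- function(params, n_profiles, jitter = 0.1, seed = 1L,
                        as_printed = FALSE, rtol = 1e-8, atol = 1e-10) {
  if (!inherits(params, "kinetic_params"))
    stop_config("'params' must be a kinetic_params object")
  n_profiles <- check_count(n_profiles, "n_profiles", lower = 2L)
  jitter <- check_number(jitter, "jitter", lower = 0, upper = 1)
  if (jitter >= 1) stop_config("'jitter' must be < 1")
  seed <- check_seed(seed)

  st <- rng_streams(seed, "kinetics")
  draws <- draw_stream(st, "kinetics", function()
    matrix(stats::runif(5L * n_profiles), n_profiles, 5L))
  pop <- c(params$k1, params$k_minus1, params$k2, params$ET, params$P1_0)
  lo <- (1 - jitter) * pop; hi <- (1 + jitter) * pop
  vals <- sweep(sweep(draws, 2L, hi - lo, "*"), 2L, lo, "+")

  out <- matrix(NA_real_, n_profiles, 3L,
                dimnames = list(NULL, c("P1", "P2", "P3")))
  for (i in seq_len(n_profiles)) {
    pi_ <- kinetic_params(vals[i, 1], vals[i, 2], vals[i, 3], vals[i, 4],
                          vals[i, 5], params$t_sample)
    y <- ode_dp45(kinetic_rhs(pi_, as_printed), c(pi_$P1_0, 0, 0),
                  pi_$t_sample, rtol = rtol, atol = atol)
    if (!as_printed && any(y < -10 * (atol + rtol * pi_$P1_0)))
      stop_numeric("negative concentration beyond solver tolerance")
    out[i, ] <- y
  }
  out
}

#' Threshold a correlation matrix into a binary association network
#'
#' Edge \eqn{A_{ij} = 1} iff \eqn{|r_{ij}| >} `threshold` (strict), for
#' \eqn{i \ne j}; the diagonal is zero.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param threshold Edge threshold, strictly between 0 and 1.
#' @return Binary adjacency matrix of the same dimension.
#' @export
corr_network <- function(R, threshold = 0.6) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop_config("'R' must be a symmetric square matrix")
  threshold <- check_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1)
    stop_config("'threshold' must be strictly between 0 and 1")
  A <- (abs(R) > threshold) * 1L
  diag(A) <- 0L
  A
}

#' Sweep additive error levels over the kinetic correlation network
#'
#' Generates one biological data matrix of `n_profiles` kinetic profiles
#' (the biological variability), then for each additive uncorrelated error
#' level (expressed as a fraction of each metabolite's biological sample
#' variance) and each of `reps` error realizations adds additive
#' uncorrelated noise plus a shared additive correlated component of
#' variance `var_ac`, computes the three pairwise correlations, and
#' averages them over the realizations. Each averaged correlation matrix
#' is thresholded into an association network.
#'
#' @param params A [kinetic_params()].
#' @param err_grid Vector of uncorrelated error levels as fractions of the
#'   biological sample variance; default 50 steps from 0 to 0.25.
#' @param var_ac Variance of the shared additive correlated error
#'   (absolute units); default 0.05.
#' @param reps Error realizations per level; default 100.
#' @param threshold Network threshold; default 0.6.
#' @param seed Integer seed.
#' @param n_profiles Number of kinetic profiles; default 100.
#' @param jitter Kinetic parameter jitter; default 0.1.
#' @return A list with `levels`, `mean_corr` (length(levels) x 3 matrix of
#'   averaged pairwise correlations r12, r13, r23), `corr0` (the
#'   error-free correlations), `networks` (list of adjacency matrices per
#'   level) and `X0` (the biological matrix).
#' @export
network_attenuation_sweep <- function(params, err_grid = seq(0, 0.25,
                                                             length.out = 50),
                                      var_ac = 0.05, reps = 100,
                                      threshold = 0.6, seed = 1L,
                                      n_profiles = 100, jitter = 0.1) {
  if (length(err_grid) < 1L) stop_config("'err_grid' must be non-empty")
  if (any(err_grid < 0)) stop_config("error levels must be non-negative")
  var_ac <- check_number(var_ac, "var_ac", lower = 0)
  reps <- check_count(reps, "reps")
  seed <- check_seed(seed)

  X0 <- mm_profiles(params, n_profiles, jitter = jitter, seed = seed)
  s2 <- apply(X0, 2L, stats::var)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  corr0 <- apply(pairs, 1L, function(ij) stats::cor(X0[, ij[1]], X0[, ij[2]]))

  st <- rng_streams(seed, c("kinetics", "noise"))  # "kinetics" consumed above
  mean_corr <- matrix(NA_real_, length(err_grid), 3L,
                      dimnames = list(NULL, c("r12", "r13", "r23")))
  networks <- vector("list", length(err_grid))
  n <- nrow(X0)
  noise <- draw_stream(st, "noise", function()
    array(stats::rnorm(length(err_grid) * reps * n * 4L),
          dim = c(n, 4L, reps, length(err_grid))))
  for (l in seq_along(err_grid)) {
    sd_au <- sqrt(err_grid[l] * s2)
    acc <- numeric(3L)
    for (r in seq_len(reps)) {
      eps <- noise[, 1:3, r, l] * rep(sd_au, each = n)
      eac <- sqrt(var_ac) * noise[, 4L, r, l]
      X <- X0 + eps + eac
      acc <- acc + apply(pairs, 1L, function(ij)
        stats::cor(X[, ij[1]], X[, ij[2]]))
    }
    mean_corr[l, ] <- acc / reps
    Rbar <- diag(3)
    Rbar[lower.tri(Rbar)] <- c(mean_corr[l, 1], mean_corr[l, 2],
                               mean_corr[l, 3])
    Rbar[upper.tri(Rbar)] <- t(Rbar)[upper.tri(Rbar)]
    networks[[l]] <- corr_network(Rbar, threshold)
  }
  list(levels = err_grid, mean_corr = mean_corr, corr0 = corr0,
       networks = networks, X0 = X0)
}
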