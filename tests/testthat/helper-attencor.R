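# Random-but-valid parameter generators for property-style tests.
# All draws use the caller's RNG state; tests wrap them in set.seed().

random_signal <- function(max_mu = 5, min_var = 0.2, max_var = 3,
                          rho_range = c(-0.9, 0.9)) {
  true_signal(mu_x = runif(1, -max_mu, max_mu),
              mu_y = runif(1, -max_mu, max_mu),
              var_x = runif(1, min_var, max_var),
              var_y = runif(1, min_var, max_var),
              rho0 = runif(1, rho_range[1], rho_range[2]))
}

random_err <- function(kind = c("none", "additive", "multiplicative",
                                "realistic", "generalized"),
                       max_add = 1, max_mult = 0.3) {
  kind <- match.arg(kind)
  sgn <- sample(c("pos", "neg"), 1)
  switch(kind,
    none = error_spec("none"),
    additive = error_spec("additive", var_au = runif(2, 0, max_add),
                          var_ac = runif(1, 0, max_add), sign = sgn),
    multiplicative = error_spec("multiplicative",
                                var_mu = runif(2, 0, max_mult),
                                var_mc = runif(1, 0, max_mult), sign = sgn),
    realistic = error_spec("realistic", var_au = runif(2, 0, max_add),
                           var_ac = runif(1, 0, max_add),
                           var_mu = runif(2, 0, max_mult),
                           var_mc = runif(1, 0, max_mult), sign = sgn),
    generalized = error_spec("generalized", var_au = runif(2, 0, max_add),
                             var_ac = runif(2, 0, max_add),
                             var_mu = runif(2, 0, max_mult),
                             var_mc = runif(2, 0, max_mult),
                             pi_ac = runif(1, -1, 1),
                             pi_mc = runif(1, -1, 1)))
}

all_kinds <- c("none", "additive", "multiplicative", "realistic",
               "generalized")

# Drop provenance attributes, keeping only the numeric matrix.
strip_sample <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
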