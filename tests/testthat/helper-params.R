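# canonical parameter set used throughout: wildtype speed 0.15, mutant speed
# 0.31, per-capita mutation rate 1e-5, drift survival 0.23
default_params <- function(d = 3) {
  macro_params(c_wt = 0.15, c_m = 0.31, mu_tilde = 1e-5, rho = 0.23, d = d)
}

random_params <- function(d = 3) {
  c_wt <- runif(1, 0.05, 1)
  macro_params(c_wt = c_wt, c_m = c_wt * runif(1, 1.05, 8),
               mu = 10^runif(1, -7, -4), d = d)
}
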