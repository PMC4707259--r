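# Independent oracles: plain closures over the reference coefficients,
# never calling the package's curve machinery.

oracle <- local({
  U_tol <- function(t) 1.09 * exp(0.171 * t) - 1.09
  RSA_tol <- function(t) 110.2 * exp(0.082 * t) - 22.2
  U_sens <- function(t) 0.64 * exp(0.150 * t) - 0.63
  RSA_sens <- function(t) 108.1 * exp(0.045 * t) - 37.4
  RE_tol <- function(t) 1.09 * 0.171 * exp(0.171 * t) / RSA_tol(t)
  RE_sens <- function(t) 0.64 * 0.150 * exp(0.150 * t) / RSA_sens(t)
  cf <- function(re, rsa, t1) {
    stats::integrate(function(x) re(x) * rsa(x), 0, t1,
                     rel.tol = 1e-11)$value
  }
  list(U_tol = U_tol, RSA_tol = RSA_tol, U_sens = U_sens,
       RSA_sens = RSA_sens, RE_tol = RE_tol, RE_sens = RE_sens, cf = cf)
})

ref_curves <- function() default_group_curves()

# a random valid efficiency curve pair (RSA positive on the window)
random_ec <- function(group = "g") {
  up <- exp_curve(runif(1, 0.3, 3), runif(1, 0.05, 0.3),
                  runif(1, 0, 0.3), role = "uptake")
  p <- runif(1, 50, 200)
  rsa <- exp_curve(p, runif(1, 0.02, 0.12), runif(1, 0, 0.8 * p),
                   role = "rsa")
  efficiency_curve(up, rsa, group)
}
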