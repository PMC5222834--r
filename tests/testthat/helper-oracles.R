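# Independent numerical oracles used across tests.

# Simpson-rule evaluation of the damped-oscillator convolution
# int_0^t exp(-a(t-u)) sin(b(t-u)) sin(w u) du  on a uniform grid
simpson_conv <- function(a, b, w, t, n = 4001) {
  if (t == 0) return(0)
  u <- seq(0, t, length.out = n)
  f <- exp(-a * (t - u)) * sin(b * (t - u)) * sin(w * u)
  h <- u[2] - u[1]
  h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, by = 2)]) +
             2 * sum(f[seq(3, n - 2, by = 2)]))
}

# affine-fit residual of s^4 U'' over an interior grid: the quasi-static
# profiles satisfy (s^4 U'')'' = 0, i.e. s^4 U'' is exactly linear in s
affine_residual <- function(s, U) {
  h <- s[2] - s[1]
  upp <- (U[-c(1, 2)] - 2 * U[-c(1, length(U))] + U[-c(length(U) - 1, length(U))]) / h^2
  si <- s[-c(1, length(s))]
  W <- si^4 * upp
  fit <- stats::lm.fit(cbind(1, si), W)
  max(abs(fit$residuals)) / diff(range(W))
}
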