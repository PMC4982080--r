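# Brute-force DerSimonian-Laird oracle, written as plain serial arithmetic
# independently of the package's vectorized implementation. Returns every
# quantity the pooled result reports.
brute_dl <- function(y, se) {
  k <- length(y)
  sw <- 0; swy <- 0
  for (i in 1:k) {
    sw <- sw + 1 / se[i]^2
    swy <- swy + y[i] / se[i]^2
  }
  y_fe <- swy / sw
  Q <- 0; sw2 <- 0
  for (i in 1:k) {
    Q <- Q + (y[i] - y_fe)^2 / se[i]^2
    sw2 <- sw2 + (1 / se[i]^2)^2
  }
  df <- k - 1
  tau2 <- 0
  if (df > 0) {
    C <- sw - sw2 / sw
    tau2 <- (Q - df) / C
    if (tau2 < 0) tau2 <- 0
  }
  swr <- 0; swry <- 0
  for (i in 1:k) {
    swr <- swr + 1 / (se[i]^2 + tau2)
    swry <- swry + y[i] / (se[i]^2 + tau2)
  }
  est <- swry / swr
  se_p <- sqrt(1 / swr)
  i2 <- NA_real_
  if (df > 0) i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(estimate = est, se = se_p,
       ci_lo = est - qnorm(0.975) * se_p, ci_hi = est + qnorm(0.975) * se_p,
       Q = Q, df = df, tau2 = tau2, i2 = i2)
}
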