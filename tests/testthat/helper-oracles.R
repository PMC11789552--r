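# Independent brute-force oracles for the windowed popgen estimators.
# Deliberately written as plain per-site loops, sharing no code with the
# package implementations.

oracle_fst <- function(p1, p2, n1, n2) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    a <- p1[i]; b <- p2[i]
    num <- num + (a - b)^2 - a * (1 - a) / (n1 - 1) - b * (1 - b) / (n2 - 1)
    den <- den + a * (1 - b) + b * (1 - a)
  }
  if (den == 0) NA_real_ else num / den
}

oracle_dxy <- function(p1, p2, l_eff) {
  s <- 0
  for (i in seq_along(p1)) s <- s + p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
  s / l_eff
}

oracle_pi <- function(p, n, l_eff) {
  s <- 0
  for (i in seq_along(p)) s <- s + 2 * p[i] * (1 - p[i]) * n / (n - 1)
  s / l_eff
}

oracle_tajd <- function(p, n) {
  s_seg <- sum(p > 0 & p < 1)
  if (s_seg == 0) return(NA_real_)
  pi_abs <- 0
  for (i in seq_along(p)) pi_abs <- pi_abs + 2 * p[i] * (1 - p[i]) * n / (n - 1)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_abs - s_seg / a1) / sqrt(e1 * s_seg + e2 * s_seg * (s_seg - 1))
}
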