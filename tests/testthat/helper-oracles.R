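# Independent oracles used across the suite.

# Matrix exponential by scaling and squaring with a Taylor series; small
# dense matrices only. Deliberately independent of the ODE solver.
expm_ss <- function(A, t) {
  M <- A * t
  s <- max(0, ceiling(log2(max(1, norm(M, "1")))))
  M <- M / 2^s
  E <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:30) {
    term <- term %*% M / i
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# Drug-free linear four-compartment tumour system (exponential regime):
# X1' = (l0 - k1) X1; Xi' = k2 X_{i-1} - k2 Xi. Rates per hour.
control_linear_oracle <- function(t_h, V0, lambda0_h, k1_h, k2_h) {
  A <- matrix(0, 4, 4)
  A[1, 1] <- lambda0_h - k1_h
  A[2, 1] <- k1_h; A[2, 2] <- -k2_h
  A[3, 2] <- k2_h; A[3, 3] <- -k2_h
  A[4, 3] <- k2_h; A[4, 4] <- -k2_h
  vapply(t_h, function(tt) sum(expm_ss(A, tt) %*% c(V0, 0, 0, 0)),
         numeric(1))
}

# Closed-form TGI under constant fractional EGFR signal (two linear ODEs).
tgi_egfr_closed_form <- function(t_h, kng_h, egfr, gamma) {
  (1 - exp(kng_h * t_h * (egfr^gamma - 1))) * 100
}

# Ishigami benchmark (a = 7, b = 0.1) and its analytic Sobol indices.
ishigami <- function(M, a = 7, b = 0.1) {
  sin(M[, 1]) + a * sin(M[, 2])^2 + b * M[, 3]^4 * sin(M[, 1])
}
ishigami_indices <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  v <- v1 + v2 + v13
  list(first = c(v1 / v, v2 / v, 0),
       total = c((v1 + v13) / v, v2 / v, v13 / v))
}

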