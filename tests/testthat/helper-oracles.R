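# independent oracles shared by the metric unit tests and the acceptance suite

oracle_states3 <- c("WAKE", "N1REM", "N2N3")

# explicit pair counting
oracle_cm <- function(t, p) {
  m <- matrix(0L, 3, 3, dimnames = list(true = oracle_states3, pred = oracle_states3))
  for (i in seq_along(t)) m[t[i], p[i]] <- m[t[i], p[i]] + 1L
  m
}

# MCC as the summed covariance of one-hot encodings
oracle_mcc <- function(t, p) {
  X <- sapply(oracle_states3, function(s) as.numeric(t == s))
  Y <- sapply(oracle_states3, function(s) as.numeric(p == s))
  sum(diag(stats::cov(X, Y))) /
    sqrt(sum(diag(stats::cov(X, X))) * sum(diag(stats::cov(Y, Y))))
}
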