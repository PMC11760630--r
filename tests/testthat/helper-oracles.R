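# Independent oracles used across test files.

# Brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m.
fdr_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- max(c(0L, which(p[o] <= q * seq_len(m) / m)))
  out <- logical(m)
  if (k > 0) out[o[seq_len(k)]] <- TRUE
  out
}

# Sums-of-squares two-factor within-subject ANOVA (each effect against its
# own subject-by-effect interaction), written from the textbook formulas.
rm_anova_oracle_2x2 <- function(y, A, B, S) {
  A <- factor(A); B <- factor(B); S <- factor(S)
  g <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, S, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  ss_a <- b * n * sum((m_a - g)^2)
  ss_b <- a * n * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - matrix(m_a, a, b) -
                      matrix(m_b, a, b, byrow = TRUE) + g)^2)
  ss_as <- b * sum((m_as - matrix(m_a, a, n) -
                      matrix(m_s, a, n, byrow = TRUE) + g)^2)
  ss_bs <- a * sum((m_bs - matrix(m_b, b, n) -
                      matrix(m_s, b, n, byrow = TRUE) + g)^2)
  res <- y
  for (i in seq_along(y)) {
    ai <- A[i]; bi <- B[i]; si <- S[i]
    res[i] <- y[i] - m_ab[ai, bi] - m_as[ai, si] - m_bs[bi, si] +
      m_a[ai] + m_b[bi] + m_s[si] - g
  }
  ss_abs <- sum(res^2)
  f_a <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) /
    (ss_abs / ((a - 1) * (b - 1) * (n - 1)))
  list(F_A = f_a, F_B = f_b, F_AB = f_ab,
       df = c(n - 1, (a - 1) * (n - 1)))
}

# epochset around a bare array, with minimal metadata
make_epochs <- function(data, srate = 250, channels = NULL, metadata = NULL) {
  n_samp <- dim(data)[3]
  times <- seq(-1, by = 1 / srate, length.out = n_samp)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (is.null(metadata))
    metadata <- tibble::tibble(trial = seq_len(dim(data)[1]), memory_load = 1)
  new_epochset(data, times, channels, srate, metadata)
}
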