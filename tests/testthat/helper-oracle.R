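# Independent oracles, kept free of the package's alignment code path.

# Brute-force affine-gap local alignment score (full dynamic programme).
# Gap of length L costs gap_open + L * gap_extend.
sw_oracle <- function(a, b, match = 1, mismatch = -4, gap_open = 1,
                      gap_extend = 2) {
  m <- nchar(a); n <- nchar(b)
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  F_ <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in 2:(m + 1L)) {
    for (j in 2:(n + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F_[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                      F_[i - 1L, j] - gap_extend)
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# bisection root of sum_ij p_i p_j exp(lambda s_ij) = 1 for match/mismatch
# scoring under uniform composition
karlin_lambda_oracle <- function(reward, penalty, p_match = 0.25,
                                 tol = 1e-12) {
  f <- function(l) p_match * exp(l * reward) + (1 - p_match) * exp(l * penalty) - 1
  lo <- 1e-9
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
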