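# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they verify.

# Global alignment score with affine gaps (Gotoh, plain R): a gap of
# length L costs open + (L - 1) * ext.
nw_affine_score <- function(a, b, match = 1, mis = -1, open = 4, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + (j - 1) * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mis
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force local alignment: best global score over every pair of
# substrings (the empty alignment scores 0). O(n^2 m^2) substring pairs.
brute_local_score <- function(a, b, ...) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, nw_affine_score(sa, substr(b, j1, j2), ...))
    }
  }
  best
}

# Exact two-sided Wilcoxon signed-rank p by raw enumeration of all 2^n
# sign assignments (average ranks for tied |differences|); two-sided tail
# is the symmetric one: P(|W - mean| >= |w_obs - mean|).
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

# Random DNA string helper for property-style tests.
rand_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
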