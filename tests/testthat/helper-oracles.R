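# Independent oracles for the statistical primitives, implemented from the
# textbook definitions only (no shared code with the package internals).

`%||%` <- function(x, y) if (is.null(x)) y else x

# Benjamini-Hochberg step-up, from the definition: sort p ascending, compute
# p_(i) * n / i, enforce monotonicity from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of the
# probability mass function (K successes in the urn, N total, n drawn).
hyper_upper_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  i <- max(0L, k):min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Two-sided Pearson correlation p-value from the exact t transform.
pearson_p_oracle <- function(r, n) {
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

# Matrix rank by Gaussian elimination with partial pivoting.
rank_oracle <- function(M, tol = 1e-9) {
  M <- as.matrix(M) * 1.0
  r <- 0L
  for (j in seq_len(ncol(M))) {
    if (nrow(M) == 0L) break
    piv <- which.max(abs(M[, j]))
    if (abs(M[piv, j]) < tol) next
    r <- r + 1L
    row <- M[piv, ] / M[piv, j]
    M <- M[-piv, , drop = FALSE]
    if (nrow(M) > 0L) M <- M - outer(M[, j], row)
  }
  r
}

# Planted bilinear system with exclusive targets per TF (identifiable by
# construction); returns the signed structure, true factors and noisy data.
make_planted_nca <- function(G, L, S, seed, noise_sd = 0, n_exclusive = 5L) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(G))
  tfs <- sprintf("T%02d", seq_len(L))
  A <- matrix(0, G, L, dimnames = list(genes, tfs))
  excl <- split(seq_len(n_exclusive * L), rep(seq_len(L), each = n_exclusive))
  pool <- (n_exclusive * L + 1L):G
  for (l in seq_len(L)) {
    extra <- max(0L, round(G / L) - n_exclusive)
    tg <- c(excl[[l]], if (extra > 0) sample(pool, extra))
    A[tg, l] <- sample(c(-1, 1), length(tg), TRUE) * runif(length(tg), 0.5, 1.5)
  }
  P <- matrix(rnorm(L * S), L, S,
              dimnames = list(tfs, sprintf("c%d", seq_len(S))))
  X <- A %*% P + matrix(rnorm(G * S, 0, noise_sd), G, S)
  dimnames(X) <- list(genes, colnames(P))
  list(A = A, P = P, X = X)
}

# Per-TF least-squares scale alignment of a factor matrix onto a reference
# (NCA activities are identified only up to per-TF sign/scale).
align_rows <- function(Pb, Pref) {
  for (l in seq_len(nrow(Pb))) {
    lam <- sum(Pb[l, ] * Pref[l, ]) / sum(Pb[l, ]^2)
    Pb[l, ] <- lam * Pb[l, ]
  }
  Pb
}

quiet_pipeline <- function(...) {
  suppressMessages(suppressWarnings(run_pipeline(...)))
}
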