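# Shared fixtures and small utilities for the test suite.

region_fixture <- function() load_fixture("region_evaluation")

# Orthogonal-Procrustes root-mean-square distance between two centred
# configurations (rotation/reflection allowed, no scaling).
procrustes_rms <- function(x, y) {
  x <- sweep(as.matrix(x), 2, colMeans(x))
  y <- sweep(as.matrix(y), 2, colMeans(y))
  s <- svd(crossprod(y, x))
  r <- s$v %*% t(s$u)
  sqrt(mean(rowSums((x %*% r - y)^2)))
}

# Uncorrected concordance coefficient, used to check the tie-corrected
# form collapses to it on tie-free matrices.
kendall_w_uncorrected <- function(ratings) {
  m <- nrow(ratings)
  n <- ncol(ratings)
  ranks <- t(apply(ratings, 1, rank))
  r_i <- colSums(ranks)
  12 * sum((r_i - m * (n + 1) / 2)^2) / (m^2 * (n^3 - n))
}

# A tiny deterministic score matrix with an obvious gradient.
toy_scores <- function() {
  m <- rbind(low = c(1, 2, 1, 2),
             mid = c(3, 4, 3, 4),
             high = c(6, 5, 6, 5))
  colnames(m) <- paste0("A", 1:4)
  m
}

fast_config <- function(...) rapbeef_config(n_restarts = 2L, ...)
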