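# Minimal deterministic FastICA, deflation scheme with tanh nonlinearity.
#
# Components are extracted one at a time in decreasing order of
# non-Gaussianity. On EEG with ocular artifacts the blink/saccade
# components are strongly non-Gaussian and converge in a handful of
# iterations; once the remaining subspace is indistinguishable from
# Gaussian noise the one-unit iteration stops converging, and extraction
# ends there (a rotation of a Gaussian subspace is unidentifiable and
# irrelevant for artifact removal). The unmixing matrix is estimated on an
# evenly spaced subsample and is deterministic given the seed.

fastica_decompose <- function(X, n_comp = nrow(X), seed = 1L,
                              max_iter = 200, tol = 1e-4,
                              max_est_cols = 30000L) {
  nch <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  est_idx <- if (n > max_est_cols)
    unique(round(seq(1, n, length.out = max_est_cols))) else seq_len(n)
  Xe <- Xc[, est_idx, drop = FALSE]
  cv <- tcrossprod(Xe) / (ncol(Xe) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  r <- sum(pos)
  K <- diag(1 / sqrt(eg$values[seq_len(r)]), r) %*%
    t(eg$vectors[, seq_len(r), drop = FALSE])         # whitening (r x nch)
  K_inv <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(r)]), r)              # unwhitening (nch x r)
  Z <- K %*% Xe
  m <- ncol(Z)
  set.seed(seed)
  n_comp <- min(n_comp, r)
  W <- matrix(0, 0, r)
  iters <- integer(0)
  for (comp in seq_len(n_comp)) {
    w <- rnorm(r)
    if (nrow(W)) w <- w - t(W) %*% (W %*% w)
    w <- w / sqrt(sum(w^2))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- drop(crossprod(w, Z))
      g <- tanh(wz)
      w1 <- drop(Z %*% g) / m - mean(1 - g^2) * w
      if (nrow(W)) w1 <- w1 - drop(t(W) %*% (W %*% w1))
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) break
      w1 <- w1 / nrm
      delta <- abs(1 - abs(sum(w1 * w)))
      w <- drop(w1)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) break
    W <- rbind(W, w)
    iters <- c(iters, it)
  }
  list(unmixing = if (nrow(W)) W %*% K else matrix(0, 0, nch),
       backproject = K_inv %*% t(W),   # nch x n_extracted
       center = mu, n_comp = nrow(W), converged = nrow(W) > 0,
       iterations = iters, est_idx = est_idx)
}
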