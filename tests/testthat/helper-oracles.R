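# Independent reference implementations (loops and first principles only).
# These are deliberately naive: they exist to check the package's vectorized
# code paths, so they must never share code with them.

# direct-DFT band power of one epoch, single channel: loop over windows and
# band bins, plain sums
oracle_band_power <- function(x, rate, band, win_ms = 500, step_ms = 250,
                              spacing = 0.125) {
  win <- round(win_ms / 1000 * rate)
  step <- round(step_ms / 1000 * rate)
  w <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / (win - 1)))
  starts <- seq(1, length(x) - win + 1, by = step)
  pad <- round(rate / spacing)
  freqs <- (0:(pad %/% 2)) * spacing
  sel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + win - 1)] * w
    pw <- numeric(length(sel))
    for (j in seq_along(sel)) {
      f <- freqs[sel[j]]
      re <- sum(seg * cos(2 * pi * f * (0:(win - 1)) / rate))
      im <- sum(seg * sin(2 * pi * f * (0:(win - 1)) / rate))
      pw[j] <- (re^2 + im^2) * 2 / (rate * sum(w^2))
    }
    acc <- acc + mean(pw)
  }
  acc / length(starts)
}

# one-factor repeated-measures ANOVA from explicit sums of squares
oracle_rm_anova1 <- function(Y) {   # Y: subjects x levels
  N <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_a <- 0
  for (a in seq_len(k)) ss_a <- ss_a + N * (mean(Y[, a]) - gm)^2
  ss_err <- 0
  for (s in seq_len(N)) for (a in seq_len(k))
    ss_err <- ss_err + (Y[s, a] - mean(Y[s, ]) - mean(Y[, a]) + gm)^2
  Fv <- (ss_a / (k - 1)) / (ss_err / ((N - 1) * (k - 1)))
  list(F = Fv, p = pf(Fv, k - 1, (N - 1) * (k - 1), lower.tail = FALSE),
       eta_p2 = ss_a / (ss_a + ss_err))
}

# Holm step-down, spelled out
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg, spelled out
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_along(o)) {
    rank <- m - i + 1
    running <- min(running, m / rank * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Cousineau-Morey SEM by loops
oracle_ws_sem <- function(Y) {  # subjects x conditions
  N <- nrow(Y); M <- ncol(Y)
  Yn <- Y
  for (s in seq_len(N)) Yn[s, ] <- Y[s, ] - mean(Y[s, ]) + mean(Y)
  sem <- numeric(M)
  for (c in seq_len(M)) sem[c] <- sd(Yn[, c]) / sqrt(N)
  sem * sqrt(M / (M - 1))
}

# rmcorr via R's own ANCOVA machinery (independent code path)
oracle_rmcorr <- function(subject, x, y) {
  fit <- stats::lm(y ~ factor(subject) + x)
  a <- stats::anova(fit)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  df <- a["Residuals", "Df"]
  list(r = r, df = df,
       p = 2 * pt(abs(r * sqrt(df / (1 - r^2))), df, lower.tail = FALSE))
}

# exact sign-flip permutation p for one channel, full enumeration
oracle_signflip_p <- function(d) {
  n <- length(d)
  tstat <- function(v) mean(v) / (sd(v) / sqrt(n))
  t_obs <- abs(tstat(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  hits <- 0
  for (i in seq_len(nrow(signs))) {
    if (abs(tstat(signs[i, ] * d)) >= t_obs) hits <- hits + 1
  }
  hits / nrow(signs)
}

# loop-based linear interpolation with sentinel propagation
oracle_upsample <- function(x, r_in, r_out, sentinel = 0) {
  n <- length(x)
  t_src <- (seq_len(n) - 1) / r_in
  n_out <- floor(t_src[n] * r_out) + 1
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    t <- (i - 1) / r_out
    lo <- max(1, min(n - 1, findInterval(t, t_src)))
    hi <- lo + 1
    if (x[lo] == sentinel || x[hi] == sentinel) { out[i] <- sentinel; next }
    u <- (t - t_src[lo]) / (t_src[hi] - t_src[lo])
    out[i] <- (1 - u) * x[lo] + u * x[hi]
  }
  out
}

# tiny session config used by several recovery tests (about 100 s)
quick_sim_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_paragraphs = 5, paragraph_s = 5, ...)
}

random_recording <- function(nch = 3, ns = 25, rate = 100) {
  recording(matrix(rnorm(nch * ns) * 10^sample(-3:3, 1), nch, ns), rate,
            paste0("ch", seq_len(nch)),
            units = sample(c("uV", "px", "au"), nch, replace = TRUE))
}
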