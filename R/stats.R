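# The statistical layer: within-subject ANOVA with Greenhouse-Geisser
# correction and partial eta squared, Holm-corrected paired post hocs,
# subject-level sign-flip permutation tests with Benjamini-Hochberg FDR
# over electrodes, repeated-measures correlation, and Cousineau-Morey
# within-subject standard errors.

# orthonormal contrasts orthogonal to the unit vector (k x (k-1))
orth_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Greenhouse-Geisser epsilon for an effect with orthonormal contrast
# matrix M (cells x df), from the subject x cells covariance S
gg_epsilon <- function(S, M) {
  E <- t(M) %*% S %*% M
  df <- ncol(M)
  eps <- sum(diag(E))^2 / (df * sum(E * E))
  min(max(eps, 1 / df), 1)
}

#' Repeated-measures ANOVA (1 or 2 within-subject factors)
#'
#' Univariate within-subject ANOVA on a complete balanced design. Reports,
#' per effect, the F statistic, degrees of freedom, uncorrected p,
#' Greenhouse-Geisser epsilon (from the covariance of the within-subject
#' contrast scores), the GG-corrected p (from epsilon-scaled dfs), and
#' partial eta squared `SS_effect / (SS_effect + SS_error)`. A
#' `sphericity_flag` marks effects with epsilon below 0.75, where the
#' corrected p is the one to trust.
#'
#' @param data data.frame in long format
#' @param dv,subject column names of the value and subject id
#' @param within character vector of 1 or 2 within-factor column names
#' @return data.frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`, `gg_epsilon`, `p_gg`, `eta_p2`, `sphericity_flag`,
#'   `degenerate`
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = "condition") {
  stopifnot(length(within) %in% 1:2)
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  levs <- lapply(within, function(w) levels(data[[w]]))
  if (any(lengths(levs) < 2)) stop("every factor needs >= 2 levels")
  N <- nlevels(data[[subject]])
  if (N < 3) stop("need >= 3 subjects")
  cells <- Reduce(function(a, b) as.vector(outer(a, b, paste, sep = ".")),
                  rev(levs))
  cell_of <- interaction(rev(data[within]), sep = ".", lex.order = FALSE)
  tab <- table(data[[subject]], cell_of)
  if (any(tab != 1)) stop("design must be complete and balanced (one value per cell)")
  # wide subject x cells matrix, cells varying first over factor 2
  Y <- matrix(NA_real_, N, length(cells),
              dimnames = list(levels(data[[subject]]), cells))
  Y[cbind(as.integer(data[[subject]]), match(as.character(cell_of), cells))] <-
    data[[dv]]
  S <- stats::cov(Y)

  one_effect <- function(name, M, ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff; ms_err <- ss_err / df_err
    degenerate <- ss_err <= .Machine$double.eps * max(1, abs(ss_eff))
    Fv <- if (degenerate) NA_real_ else ms_eff / ms_err
    p <- if (degenerate) NA_real_ else pf(Fv, df_eff, df_err, lower.tail = FALSE)
    eps <- gg_epsilon(S, M)
    p_gg <- if (degenerate) NA_real_ else
      pf(Fv, eps * df_eff, eps * df_err, lower.tail = FALSE)
    data.frame(effect = name, F = Fv, df1 = df_eff, df2 = df_err, p = p,
               gg_epsilon = eps, p_gg = p_gg,
               eta_p2 = if (degenerate) NA_real_ else ss_eff / (ss_eff + ss_err),
               sphericity_flag = eps < 0.75, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }

  gm <- mean(Y)
  m_s <- rowMeans(Y)
  if (length(within) == 1) {
    k <- length(levs[[1]])
    m_a <- colMeans(Y)
    ss_a <- N * sum((m_a - gm)^2)
    resid <- sweep(sweep(Y, 1, m_s), 2, m_a) + gm
    ss_err <- sum(resid^2)
    M <- orth_contrasts(k)
    return(one_effect(within[1], M, ss_a, k - 1, ss_err, (N - 1) * (k - 1)))
  }
  a <- length(levs[[1]]); b <- length(levs[[2]])
  # Y columns ordered with factor 2 varying fastest
  arr <- array(Y, dim = c(N, b, a))
  m_i <- apply(arr, 3, mean)          # A margins
  m_j <- apply(arr, 2, mean)          # B margins
  m_ij <- t(apply(arr, c(3, 2), mean))  # b x a -> store as [j, i]
  m_si <- apply(arr, c(1, 3), mean)   # N x a
  m_sj <- apply(arr, c(1, 2), mean)   # N x b
  ss_A <- N * b * sum((m_i - gm)^2)
  ss_AS <- b * sum((sweep(sweep(m_si, 1, m_s), 2, m_i) + gm)^2)
  ss_B <- N * a * sum((m_j - gm)^2)
  ss_BS <- a * sum((sweep(sweep(m_sj, 1, m_s), 2, m_j) + gm)^2)
  ss_AB <- N * sum((sweep(sweep(m_ij, 2, m_i), 1, m_j) + gm)^2)
  resid <- array(0, dim = dim(arr))
  for (s in seq_len(N)) for (j in seq_len(b)) for (i in seq_len(a))
    resid[s, j, i] <- arr[s, j, i] - m_si[s, i] - m_sj[s, j] - m_ij[j, i] +
      m_s[s] + m_i[i] + m_j[j] - gm
  ss_ABS <- sum(resid^2)
  Ca <- orth_contrasts(a); Cb <- orth_contrasts(b)
  jb <- matrix(rep(1 / sqrt(b), b)); ja <- matrix(rep(1 / sqrt(a), a))
  M_A <- Ca %x% jb; M_B <- ja %x% Cb; M_AB <- Ca %x% Cb
  rbind(
    one_effect(within[1], M_A, ss_A, a - 1, ss_AS, (N - 1) * (a - 1)),
    one_effect(within[2], M_B, ss_B, b - 1, ss_BS, (N - 1) * (b - 1)),
    one_effect(paste(within, collapse = ":"), M_AB, ss_AB,
               (a - 1) * (b - 1), ss_ABS, (N - 1) * (a - 1) * (b - 1)))
}

#' Paired post hoc t-tests with Holm correction
#'
#' Two-tailed paired t-tests over all level pairs of a within-subject
#' factor, with Bonferroni-Holm step-down adjustment (monotone, capped at
#' 1). Pairs with zero-variance differences are flagged and excluded from
#' the adjustment.
#'
#' @inheritParams rm_anova
#' @param correction p-adjustment method (default `"holm"`)
#' @return data.frame: `level1`, `level2`, `t`, `df`, `p`, `p_adj`,
#'   `zero_variance`
#' @export
posthoc_paired_t <- function(data, dv = "value", subject = "subject",
                             within = "condition", correction = "holm") {
  data[[subject]] <- factor(data[[subject]])
  f <- factor(data[[within]])
  levs <- levels(f)
  pairs <- utils::combn(levs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    l1 <- pairs[1, i]; l2 <- pairs[2, i]
    x <- data[[dv]][f == l1][order(data[[subject]][f == l1])]
    y <- data[[dv]][f == l2][order(data[[subject]][f == l2])]
    d <- x - y
    n <- length(d)
    if (sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(level1 = l1, level2 = l2, t = 0, df = n - 1, p = 1,
                          zero_variance = FALSE))
      return(data.frame(level1 = l1, level2 = l2, t = NA_real_, df = n - 1,
                        p = NA_real_, zero_variance = TRUE))
    }
    tv <- mean(d) / (sd(d) / sqrt(n))
    data.frame(level1 = l1, level2 = l2, t = tv, df = n - 1,
               p = 2 * pt(abs(tv), n - 1, lower.tail = FALSE),
               zero_variance = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = correction)
  out
}

#' Subject-level sign-flip permutation test with FDR over channels
#'
#' Paired two-sided test per channel: the permutation distribution of the
#' paired t statistic under subject-level sign flips of the paired
#' differences. With `2^N <= n_perm` all flips are enumerated exactly
#' (with a warning); otherwise `n_perm` random flips give
#' `p = (1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm)`. Raw p-values are
#' Benjamini-Hochberg adjusted across channels; the significance mask is
#' `q < alpha`.
#'
#' @param values_A,values_B numeric subject x channel matrices (paired)
#' @param n_perm number of permutations (>= 999 recommended)
#' @param seed RNG seed (required: permutation draws must be reproducible)
#' @param alpha mask level
#' @return data.frame of class `"topo_test"`: `channel`, `t`, `p`, `q`,
#'   `significant`; attribute `exact` says whether flips were enumerated
#' @export
permutation_topo_test <- function(values_A, values_B, n_perm = 1999, seed,
                                  alpha = 0.05) {
  if (missing(seed)) stop("seed is required")
  A <- as.matrix(values_A); B <- as.matrix(values_B)
  stopifnot(identical(dim(A), dim(B)))
  D <- A - B
  N <- nrow(D); nch <- ncol(D)
  t_of <- function(sgn) {
    # sgn: flips x N; returns flips x channels matrix of t statistics
    m <- (sgn %*% D) / N
    ssq <- matrix(colSums(D^2), nrow(sgn), nch, byrow = TRUE)
    v <- pmax(ssq - N * m^2, 0) / (N - 1)
    tt <- m / sqrt(v / N)
    # zero-variance differences: t = 0 when the mean is 0 too (A == B)
    tt[v == 0] <- sign(m[v == 0]) * ifelse(m[v == 0] == 0, 0, Inf)
    tt
  }
  t_obs <- as.vector(t_of(matrix(1, 1, N)))
  exact <- 2^N <= n_perm
  if (exact) {
    warning("2^", N, " <= n_perm; enumerating all sign flips exactly")
    sgn <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
    tp <- abs(t_of(sgn))
    p <- colMeans(sweep(tp, 2, abs(t_obs), `>=`))
  } else {
    set.seed(seed)
    sgn <- matrix(sample(c(-1, 1), n_perm * N, replace = TRUE), n_perm, N)
    tp <- abs(t_of(sgn))
    p <- (1 + colSums(sweep(tp, 2, abs(t_obs), `>=`))) / (1 + n_perm)
  }
  q <- p.adjust(p, method = "BH")
  out <- data.frame(
    channel = colnames(A) %||% paste0("ch", seq_len(nch)),
    t = t_obs, p = p, q = q, significant = q < alpha,
    stringsAsFactors = FALSE)
  attr(out, "exact") <- exact
  class(out) <- c("topo_test", "data.frame")
  out
}

#' Repeated-measures correlation
#'
#' The common within-subject linear association between two variables,
#' estimated by analysis of covariance: both variables are centered within
#' subject, a common slope is fit, and
#' `r = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))` with
#' `df = N_obs - n_subjects - 1`. The p-value comes from the t transform
#' of r at that df; the 95% CI from the Fisher z transform with standard
#' error `1 / sqrt(df - 1)`.
#'
#' @param subject subject ids
#' @param x,y numeric vectors
#' @return list of class `"rmcorr_result"`: `r`, `df`, `p`, `ci95`,
#'   `slope`
#' @export
rmcorr <- function(subject, x, y) {
  subject <- factor(subject)
  stopifnot(length(x) == length(y), length(x) == length(subject))
  ok <- complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- droplevels(subject[ok])
  if (any(table(subject) < 2)) stop("need >= 2 observations per subject")
  if (nlevels(subject) < 2) stop("need >= 2 subjects")
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero within-subject variance in x")
  if (sum(yc^2) == 0) stop("zero within-subject variance in y")
  slope <- sum(xc * yc) / sxx
  fit <- slope * xc
  ss_m <- sum(fit^2)
  ss_e <- sum((yc - fit)^2)
  r <- sign(slope) * sqrt(ss_m / (ss_m + ss_e))
  df <- as.integer(length(x) - nlevels(subject) - 1)
  if (df < 1) stop("not enough observations for inference (df < 1)")
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  ci <- if (df > 1) {
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    hw <- stats::qnorm(0.975) / sqrt(df - 1)
    tanh(c(z - hw, z + hw))
  } else c(NA_real_, NA_real_)
  structure(list(r = r, df = df, p = p, ci95 = ci, slope = slope),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr r = %.3f, df = %d, p = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$r, x$df, x$p, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Within-subject (Cousineau-Morey) standard errors
#'
#' Subject means are removed and the grand mean restored
#' (`y' = y - m_subject + grand_mean`), per-condition standard errors of
#' the normalized values are computed, and the Morey bias correction
#' `sqrt(M / (M - 1))` for M conditions is applied.
#'
#' @inheritParams rm_anova
#' @return named numeric vector of per-condition SEMs
#' @export
within_subject_sem <- function(data, dv = "value", subject = "subject",
                               within = "condition") {
  s <- factor(data[[subject]]); w <- factor(data[[within]])
  M <- nlevels(w)
  if (M < 2) stop("need >= 2 conditions")
  yp <- data[[dv]] - ave(data[[dv]], s) + mean(data[[dv]])
  sem <- tapply(yp, w, function(v) sd(v) / sqrt(length(v)))
  setNames(as.numeric(sem) * sqrt(M / (M - 1)), names(sem))
}
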