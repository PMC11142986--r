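rand_table <- function(N, k, effect = 0) {
  d <- expand.grid(subject = seq_len(N), condition = letters[seq_len(k)])
  d$value <- rnorm(nrow(d)) + rep(rnorm(N), k) +
    effect * as.integer(d$condition)
  d
}

test_that("rm_anova matches the first-principles SS oracle on random tables", {
  set.seed(21)
  for (i in 1:10) {
    N <- sample(5:12, 1); k <- sample(3:5, 1)
    d <- rand_table(N, k, effect = runif(1, 0, 1))
    got <- rm_anova(d)
    Y <- matrix(d$value[order(d$condition, d$subject)], N, k)
    ref <- oracle_rm_anova1(Y)
    expect_equal(got$F, ref$F, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
    expect_equal(got$eta_p2, ref$eta_p2, tolerance = 1e-10)
    expect_gte(got$gg_epsilon, 1 / (k - 1))
    expect_lte(got$gg_epsilon, 1)
  }
})

test_that("rm_anova flags degenerate data and epsilon approaches 1 under CS", {
  d <- expand.grid(subject = 1:6, condition = letters[1:4])
  d$value <- 3
  expect_true(rm_anova(d)$degenerate)
  # compound-symmetric data: epsilon close to 1 for large N
  set.seed(22)
  N <- 300
  d <- expand.grid(subject = seq_len(N), condition = letters[1:4])
  d$value <- rep(rnorm(N), 4) + rnorm(nrow(d))
  expect_gt(rm_anova(d)$gg_epsilon, 0.95)
  expect_error(rm_anova(rand_table(2, 3)), ">= 3 subjects")
  d_bad <- rand_table(5, 3)[-1, ]
  expect_error(rm_anova(d_bad), "balanced")
})

test_that("two-factor rm_anova agrees with building blocks", {
  # the interaction of additive data is exactly zero
  set.seed(23)
  N <- 8
  d <- expand.grid(subject = 1:N, DP = letters[1:4], load = c("lo", "hi"))
  d$value <- rep(rnorm(N), 8) + as.integer(d$DP) + 2 * (d$load == "hi") +
    rnorm(nrow(d), sd = 0.4)
  got <- rm_anova(d, within = c("DP", "load"))
  expect_equal(got$effect, c("DP", "load", "DP:load"))
  # the main effect of DP equals a one-factor ANOVA on load-averaged data
  agg <- aggregate(value ~ subject + DP, d, mean)
  one <- rm_anova(agg, within = "DP")
  # SS scale differs by the number of load levels, F is identical
  expect_equal(got$F[1], one$F, tolerance = 1e-10)
  expect_equal(got$gg_epsilon[1], one$gg_epsilon, tolerance = 1e-10)
})

test_that("posthoc_paired_t: Holm arithmetic, degenerate cases, pair count", {
  # raw p = (0.01, 0.04) with m = 2 -> adjusted (0.02, 0.04)
  expect_equal(oracle_holm(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  d <- rand_table(6, 4)
  ph <- posthoc_paired_t(d)
  expect_equal(nrow(ph), 6)  # 4 choose 2
  expect_true(all(ph$p_adj >= ph$p - 1e-15))
  # identical conditions -> t = 0, p = 1 (exactly representable values so
  # the +1 shift below stays exact in floating point)
  d2 <- expand.grid(subject = 1:5, condition = c("a", "b"))
  d2$value <- rep(c(1.5, 2, 3, 4.5, 7), 2)
  ph2 <- posthoc_paired_t(d2)
  expect_equal(ph2$t, 0)
  expect_equal(ph2$p, 1)
  # constant nonzero difference -> flagged, excluded from adjustment
  d3 <- d2; d3$value[d3$condition == "b"] <- d3$value[d3$condition == "b"] + 1
  expect_true(posthoc_paired_t(d3)$zero_variance)
})

test_that("Holm and BH adjusted p-values match the loop oracles (property)", {
  set.seed(24)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "holm"), oracle_holm(p), tolerance = 1e-12)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    # monotone and >= raw
    expect_true(all(p.adjust(p, "holm") >= p - 1e-15))
    expect_true(all(p.adjust(p, "BH") >= p - 1e-15))
  }
})

test_that("permutation_topo_test: identical inputs, exact enumeration, BH mask", {
  set.seed(25)
  A <- matrix(rnorm(6 * 5), 6, dimnames = list(NULL, paste0("ch", 1:5)))
  out <- suppressWarnings(permutation_topo_test(A, A, n_perm = 999, seed = 1))
  expect_true(all(out$p == 1))
  expect_false(any(out$significant))
  # N = 4, one channel: p equals full enumeration oracle
  D <- matrix(c(0.3, 1.2, 0.8, 0.5), 4, 1)
  B <- matrix(0, 4, 1)
  out <- suppressWarnings(permutation_topo_test(D, B, n_perm = 999, seed = 1))
  expect_true(attr(out, "exact"))
  expect_equal(out$p, oracle_signflip_p(D[, 1]))
  # q >= p elementwise; mask invariant under channel permutation
  set.seed(26)
  A <- matrix(rnorm(12 * 8), 12); B <- matrix(rnorm(12 * 8), 12)
  o1 <- permutation_topo_test(A, B, n_perm = 999, seed = 3)
  expect_true(all(o1$q >= o1$p - 1e-15))
  perm <- sample(8)
  o2 <- permutation_topo_test(A[, perm], B[, perm], n_perm = 999, seed = 3)
  expect_equal(o2$significant, o1$significant[perm])
  expect_error(permutation_topo_test(A, B, n_perm = 99), "seed")
})

test_that("rmcorr: perfect within-subject relation, oracle, null behavior", {
  # y = 2x within every subject, distinct offsets -> r = 1
  d <- expand.grid(subject = 1:4, obs = 1:5)
  d$x <- rnorm(nrow(d))
  d$y <- 2 * d$x + 10 * as.integer(d$subject)
  r <- rmcorr(d$subject, d$x, d$y)
  expect_equal(r$r, 1, tolerance = 1e-12)
  # 3 subjects x 3 points vs the ANCOVA oracle
  set.seed(27)
  s <- rep(1:3, each = 3)
  x <- rnorm(9); y <- 0.5 * x + rnorm(9, sd = 0.5) + s
  got <- rmcorr(s, x, y)
  ref <- oracle_rmcorr(s, x, y)
  expect_equal(got$r, ref$r, tolerance = 1e-10)
  expect_equal(got$df, ref$df)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  # independent x, y: |r| < 0.3 with high probability at N=32, k=4
  set.seed(28)
  s <- rep(1:32, each = 4)
  rs <- replicate(20, rmcorr(s, rnorm(128), rnorm(128))$r)
  expect_true(mean(abs(rs) < 0.3) >= 0.95)
  # bounded in [-1, 1] for arbitrary inputs (property)
  for (i in 1:25) {
    s <- rep(seq_len(sample(2:6, 1)), each = sample(2:5, 1))
    r <- rmcorr(s, rnorm(length(s)), rnorm(length(s)))$r
    expect_true(abs(r) <= 1)
  }
  expect_error(rmcorr(rep(1:3, each = 2), rep(1, 6), rnorm(6)),
               "zero within-subject variance")
})

test_that("within_subject_sem removes offsets and matches the loop oracle", {
  # subjects differing only by an offset: SEM = 0
  d <- expand.grid(subject = 1:5, condition = letters[1:3])
  prof <- c(a = 1, b = 2, c = 4)
  d$value <- prof[d$condition] + 10 * as.integer(d$subject)
  expect_equal(unname(within_subject_sem(d)), c(0, 0, 0))
  # M = 2: SEM = s/sqrt(N) * sqrt(2) on normalized values
  set.seed(29)
  d <- expand.grid(subject = 1:8, condition = c("a", "b"))
  d$value <- rnorm(16)
  Y <- matrix(d$value[order(d$condition, d$subject)], 8, 2)
  expect_equal(unname(within_subject_sem(d)), oracle_ws_sem(Y))
  Yn <- Y - rowMeans(Y) + mean(Y)
  expect_equal(unname(within_subject_sem(d))[1],
               sd(Yn[, 1]) / sqrt(8) * sqrt(2))
  expect_error(within_subject_sem(d[d$condition == "a", ]), ">= 2 conditions")
})
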