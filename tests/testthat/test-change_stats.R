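test_that("change_stat reproduces the closed-form Welch computation", {
  x0 <- c(10, 11, 12, 13); x1 <- c(12, 13, 14, 15)
  cs <- change_stat(x0, x1)
  w <- welch_hand(x0, x1)
  expect_equal(cs$mean_change, w$diff)
  expect_equal(cs$t_stat, w$t)
  expect_equal(cs$df, w$df)
  expect_equal(c(cs$ci_low, cs$ci_high), w$ci)
  expect_equal(cs$p_value, w$p)
  expect_equal(cs$percent_change, 100 * w$diff / mean(x0))
  set.seed(9)
  for (k in 1:10) {
    a <- rnorm(6, 10, 2); b <- rnorm(8, 12, 3)
    cs <- change_stat(a, b, conf = 0.9)
    w <- welch_hand(a, b, conf = 0.9)
    expect_equal(c(cs$ci_low, cs$ci_high), w$ci)
    expect_equal(cs$df, w$df)
  }
})

test_that("change_stat handles identical and degenerate groups per convention", {
  same <- change_stat(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$mean_change, 0)
  expect_equal(same$hedges_g, 0)
  # identical constants: zero change, p = 1 by convention
  flat <- change_stat(c(5, 5), c(5, 5))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$hedges_g, 0)
  expect_error(change_stat(c(0, 0), c(1, 1)), "degenerate")
  expect_error(change_stat(1, c(1, 2)), ">= 2")
})

test_that("Hedges' g matches the small-sample-corrected formula", {
  expect_equal(hedges_g(c(1, 2, 3), c(3, 4, 5)), 1.6)  # J = 0.8, d = 2
  set.seed(21)
  x0 <- rnorm(5); x1 <- rnorm(7, 1)
  expect_equal(hedges_g(x0, x1), -hedges_g(x1, x0))
  expect_equal(hedges_g(x0, x0), 0)
  expect_error(hedges_g(c(2, 2), c(3, 3)), "zero")
})

test_that("method_contrast returns ESM - FD and honours pairing", {
  esm <- c(1.2, 0.8, 0.4, 0.9, 0.2, 0.4)
  fd <- c(-3.1, -3.9, -3.5, -3.2, -3.8, -3.7)
  un <- method_contrast(esm, fd)
  expect_equal(un$diff, mean(esm) - mean(fd))
  w <- welch_hand(fd, esm)
  expect_equal(c(un$ci_low, un$ci_high), w$ci)

  pa <- method_contrast(esm, fd, paired = TRUE)
  d <- esm - fd
  expect_equal(pa$t_stat, mean(d) / (sd(d) / sqrt(6)))
  expect_equal(pa$df, 5)
  expect_equal(pa$ci_low, mean(d) - qt(0.975, 5) * sd(d) / sqrt(6))
  expect_error(method_contrast(esm, fd[-1], paired = TRUE), "equal-length")

  eq <- method_contrast(c(1, 1, 1), c(1, 1, 1))
  expect_equal(eq$diff, 0)
  expect_equal(eq$hedges_g, 0)
  # invariance to a common additive shift
  sh <- method_contrast(esm + 10, fd + 10)
  expect_equal(sh$diff, un$diff)
})

test_that("required sample size follows the noncentral-t power condition", {
  # vanishing noise needs only the minimum group size
  expect_equal(required_sample_size(1e-6, 0.10), 2)
  expect_error(required_sample_size(0.3, 0), "undetectable")
  # monotone in cv, antitone in detectable change
  n_seq <- sapply(c(0.1, 0.2, 0.3, 0.5), required_sample_size,
                  rel_change = 0.1)
  expect_true(all(diff(n_seq) > 0))
  n_rel <- sapply(c(0.05, 0.1, 0.2, 0.4), function(r)
    required_sample_size(0.3, r))
  expect_true(all(diff(n_rel) < 0))
  # cross-check against the independent power solver in stats
  for (cv in c(0.2, 0.3, 0.45)) {
    ref <- ceiling(power.t.test(delta = 0.10, sd = cv, sig.level = 0.05,
                                power = 0.8)$n)
    expect_lte(abs(required_sample_size(cv, 0.10) - ref), 1)
  }
  # and against a brute-force simulation at the solved n
  n_star <- required_sample_size(0.3, 0.10)
  expect_equal(n_star, 143)
  set.seed(4)
  reps <- 4000
  x0 <- matrix(rnorm(n_star * reps, 1, 0.3), n_star)
  x1 <- matrix(rnorm(n_star * reps, 1.1, 0.3), n_star)
  se <- sqrt(2 * ((colSums(x0^2) - colSums(x0)^2 / n_star) / (n_star - 1) +
                    (colSums(x1^2) - colSums(x1)^2 / n_star) / (n_star - 1)) /
               (2 * n_star))
  tt <- (colMeans(x1) - colMeans(x0)) / se
  pw <- mean(abs(tt) > qt(0.975, 2 * n_star - 2))
  expect_gt(pw, 0.8 - 2.5 * sqrt(0.8 * 0.2 / reps))
})

test_that("Welch confidence intervals achieve nominal coverage at n = 6", {
  # coverage computed with the closed form change_stat is verified against
  set.seed(31)
  reps <- 10000; n <- 6; mu0 <- 10; mu1 <- 12
  cover <- logical(reps)
  x0 <- matrix(rnorm(n * reps, mu0, 2), n)
  x1 <- matrix(rnorm(n * reps, mu1, 2), n)
  v0 <- (colSums(x0^2) - colSums(x0)^2 / n) / (n - 1)
  v1 <- (colSums(x1^2) - colSums(x1)^2 / n) / (n - 1)
  se <- sqrt(v0 / n + v1 / n)
  df <- se^4 / ((v0 / n)^2 / (n - 1) + (v1 / n)^2 / (n - 1))
  diff <- colMeans(x1) - colMeans(x0)
  tcrit <- qt(0.975, df)
  cover <- (diff - tcrit * se) <= (mu1 - mu0) & (mu1 - mu0) <= (diff + tcrit * se)
  # allow ~0.5pp for the Satterthwaite approximation (slightly conservative
  # at n = 6) on top of two Monte-Carlo standard errors
  expect_lt(abs(mean(cover) - 0.95), 0.005 + 2 * sqrt(0.95 * 0.05 / reps))
})

test_that("tabulated change statistics mirror per-group change_stat calls", {
  ps <- make_profile_set(n_plots = 5, bd_mult = 0.9, conc_mult = 1.3,
                         jitter = 0.05, seed = 13)
  tab <- profile_change_table(ps, "bd_g_cm3")
  expect_equal(nrow(tab), 3)
  sub <- ps[ps$depth_top_cm == 0, ]
  direct <- change_stat(sub$bd_g_cm3[sub$time == "t0"],
                        sub$bd_g_cm3[sub$time == "t1"])
  expect_equal(tab$mean_change[tab$layer_top_cm == 0], direct$mean_change)
  expect_equal(tab$hedges_g[tab$layer_top_cm == 0], direct$hedges_g)

  st <- stocks_pipeline(ps, extrapolate = TRUE)
  stab <- stock_change_table(st, "FD")
  fd0 <- st[st$method == "FD" & st$layer_top_cm == 0, ]
  dstat <- change_stat(fd0$stock_MgC_ha[fd0$time == "t0"],
                       fd0$stock_MgC_ha[fd0$time == "t1"])
  expect_equal(stab$mean_change[stab$layer_top_cm == 0], dstat$mean_change)

  ctab <- contrast_table(st)
  expect_equal(ctab$diff,
               ctab$mean_esm_change - ctab$mean_fd_change, tolerance = 1e-12)
})
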