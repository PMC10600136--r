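fake_suite <- function(coefficients) {
  structure(list(counts = rep(1L, 100L), coefficients = coefficients,
                 scheme = "GA", frame_rate = 1.8),
            class = "adjacency_suite")
}

test_that("adjacency correlations and the 153 pairings", {
  a <- rnorm(100)
  expect_equal(adjacency_correlation(a, 2 * a), 1)
  expect_equal(adjacency_correlation(a, -a + 3), -1)
  expect_error(adjacency_correlation(c(1, NA, NA, NA), c(1, 2, NA, NA)),
               "at least 3")
  sim <- generate_hb_series(sim_config(n_frames = 100, n_voxels = 30, seed = 9))
  tab <- correlation_table(adjacency_suite(sim$unaffected))
  expect_equal(nrow(tab), 153L)
  expect_equal(choose(18, 2), 153)
  expect_true(all(abs(tab$r) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("class extrema summarize the six classes", {
  cls <- decode_transition(1:100)$class_m
  ce <- class_extrema(rnorm(100), as.numeric(cls))
  expect_equal(nrow(ce), 6L)
  expect_equal(ce$class_m, 0:5)
  expect_equal(ce$n_types, c(10L, 20L, 20L, 20L, 20L, 10L))
  expect_equal(ce$max_abs_y, as.numeric(0:5))

  # saturating flux in classes 3-5: maxima non-decreasing then flat
  flux <- pmin(cls, 3) + 0.001 * seq_len(100) / 100
  ce2 <- class_extrema(rnorm(100), flux)
  expect_true(all(diff(ce2$max_abs_y[1:4]) > 0))
  expect_lt(diff(range(ce2$max_abs_y[4:6])), 0.01)
})

test_that("sign-reversal table detects an injected attenuation", {
  set.seed(15)
  rc <- reversal_category(1:100, "total")
  cn <- c("prob", "dwell_pre", "dwell_post",
          paste0(rep(c("mu_pre_", "mu_post_", "flux_"), 5),
                 rep(c("deoxy", "exc", "oxy", "sat", "total"), each = 3)))
  mk <- function(atten) {
    m <- matrix(1 + rnorm(1800, sd = 0.05), 100, 18,
                dimnames = list(NULL, cn))
    m[rc == 1L, ] <- m[rc == 1L, ] * atten
    fake_suite(m)
  }
  # identical categories: no difference
  flat <- fake_suite(matrix(1, 100, 18, dimnames = list(NULL, cn)))
  res0 <- sign_reversal_table(list(T = flat, N = flat))
  expect_equal(res0$summary$mean0, res0$summary$mean1)
  expect_true(all(res0$summary$p_category == 1))
  expect_true(all(res0$between$p_paired == 1))

  # injected 0.5 attenuation on reversal types is recovered
  res <- sign_reversal_table(list(T = mk(0.5), N = mk(0.5)))
  ratio <- res$summary$mean1 / res$summary$mean0
  expect_true(all(abs(ratio - 0.5) < 0.1))
  expect_true(all(res$summary$p_category < 0.01))
})

test_that("t-prime scores standardize against the reference", {
  set.seed(16)
  x <- rnorm(100, 2, 3)
  tp <- tprime_scores(x, x)
  expect_equal(mean(tp), 0, tolerance = 1e-12)
  expect_equal(sd(tp), 1, tolerance = 1e-12)
  ref <- rnorm(100)
  expect_equal(tprime_scores(ref + 2, ref), tprime_scores(ref, ref) + 2 / sd(ref))
  expect_equal(tprime_scores(x, ref), (x - mean(ref)) / sd(ref))
  expect_error(tprime_scores(x, rep(1, 100)), "zero")
})

test_that("vector amplitudes are Euclidean norms", {
  expect_equal(vector_amplitude(3, 4, 0), 5)
  expect_equal(vector_amplitude(0, 0, 0), 0)
  a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
  expect_equal(vector_amplitude(a, b, c), vector_amplitude(c, a, b))
  expect_true(is.na(vector_amplitude(NA, 1, 1)))
})

test_that("t-prime / amplitude pipeline is scale-invariant", {
  set.seed(17)
  xs <- replicate(3, rnorm(100), simplify = FALSE)
  rs <- replicate(3, rnorm(100), simplify = FALSE)
  amp1 <- vector_amplitude(tprime_scores(xs[[1]], rs[[1]]),
                           tprime_scores(xs[[2]], rs[[2]]),
                           tprime_scores(xs[[3]], rs[[3]]))
  amp2 <- vector_amplitude(tprime_scores(7 * xs[[1]], 7 * rs[[1]]),
                           tprime_scores(7 * xs[[2]], 7 * rs[[2]]),
                           tprime_scores(7 * xs[[3]], 7 * rs[[3]]))
  expect_equal(amp1, amp2, tolerance = 1e-12)
})

test_that("Lineweaver-Burk identity is exact on Michaelis-Menten data", {
  vmax <- 2; km <- 0.5
  P <- seq(0.2, 5, length.out = 20)
  y <- vmax * P / (km + P)
  fit <- lineweaver_burk(P, y)
  expect_equal(fit$slope, km / vmax, tolerance = 1e-10)
  expect_equal(fit$intercept, 1 / vmax, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_equal(fit$vmax, vmax, tolerance = 1e-8)
  expect_equal(fit$km, km, tolerance = 1e-8)

  flat <- lineweaver_burk(P, rep(2, 20))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("noisy Michaelis-Menten parameters are recovered within 10%", {
  vmax <- 2; km <- 0.5
  errs <- t(vapply(1:100, function(seed) {
    set.seed(seed)
    P <- runif(50, 0.1, 5)
    y <- vmax * P / (km + P) * (1 + rnorm(50, sd = 0.05))
    fit <- lineweaver_burk(P, y)
    c(abs(fit$vmax - vmax) / vmax, abs(fit$km - km) / km)
  }, c(0, 0)))
  expect_lt(mean(errs[, 1L]), 0.10)
  expect_lt(mean(errs[, 2L]), 0.10)
})

test_that("exclusion filters are reproducible and logged", {
  set.seed(18)
  P <- runif(100, 0.1, 5)
  y <- 2 * P / (0.5 + P) * (1 + rnorm(100, sd = 0.05))
  ex <- list(x_max = 2.5, y_min = 0.6)
  f1 <- lineweaver_burk(P, y, transform = "log10-reciprocal", exclude = ex)
  f2 <- lineweaver_burk(P, y, transform = "log10-reciprocal", exclude = ex)
  expect_equal(f1$n, f2$n)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$n + f1$n_dropped, 100L)
  expect_error(lineweaver_burk(c(1, 2), c(1, 1)), "fewer than 3")
})

test_that("regression comparisons behave symmetrically", {
  set.seed(19)
  x <- runif(40, 0.5, 4)
  y1 <- 1 + 1 * x + rnorm(40, sd = 0.01)
  y2 <- 1 + 2 * x + rnorm(40, sd = 0.01)
  # feed through lineweaver_burk by inverting the transform: use y = 1/line
  f1 <- lineweaver_burk(1 / x, 1 / y1)
  f1b <- lineweaver_burk(1 / x, 1 / y1)
  f2 <- lineweaver_burk(1 / x, 1 / y2)
  same <- compare_regressions(f1, f1b)
  expect_gt(same$p_slope, 0.99)
  expect_gt(same$p_intercept, 0.99)
  diff <- compare_regressions(f1, f2)
  expect_lt(diff$p_slope, 1e-3)
  rev <- compare_regressions(f2, f1)
  expect_equal(diff$p_slope, rev$p_slope)
  expect_equal(diff$p_intercept, rev$p_intercept)
})

test_that("rank-order categories follow the magnitude orderings", {
  expect_equal(rank_order_category(3, 2, 1), "1")
  expect_equal(rank_order_category(3, 1, 2), "2")
  expect_equal(rank_order_category(2, 3, 1), "3")
  expect_equal(rank_order_category(-1, 3, 2), "4")
  expect_equal(rank_order_category(1, 2, 5), "other")
  expect_equal(rank_order_category(2, 1, 5), "other")
  # ties resolved by precedence total > sat > dwell
  expect_equal(rank_order_category(1, 1, 0.5), "1")
  expect_true(is.na(rank_order_category(NA, 1, 1)))
})

test_that("marker-group tests recover an injected group effect", {
  set.seed(20)
  cls <- decode_transition(1:100)$class_m
  base <- runif(100, 2, 4)
  mk_subject <- function(eff) base * eff * (1 + rnorm(100, sd = 0.10))
  amp <- rbind(t(vapply(1:10, function(i) mk_subject(1.2), numeric(100))),
               t(vapply(1:10, function(i) mk_subject(1.0), numeric(100))))
  marker <- rep(c(TRUE, FALSE), each = 10)
  cats <- rank_order_category(rnorm(100), rnorm(100), rnorm(100) * 0.1)
  res <- marker_group_tests(amp, marker, cats)
  all35 <- res[res$subset == "all_classes_3_5", ]
  expect_equal(all35$n_types, 50L)
  expect_gt(all35$mean_pos, all35$mean_neg)
  expect_lt(all35$p, 0.05)
  expect_true("p_bh" %in% names(res))
})
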