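test_that("transition indexing follows the synchronous definition", {
  S <- matrix(c(3L, 7L), 2, 1)
  expect_equal(as.vector(transition_index(S)), 27L)
  expect_equal(decode_transition(27)$s1, 3L)
  expect_equal(decode_transition(27)$s2, 7L)
  # self-transitions are counted
  expect_equal(as.vector(transition_index(matrix(c(1L, 1L), 2, 1))), 1L)
  # all ordered pairs produce 100 distinct types
  pairs <- expand.grid(s1 = 1:10, s2 = 1:10)
  ks <- 10L * (pairs$s1 - 1L) + pairs$s2
  expect_equal(sort(unique(ks)), 1:100)
  expect_error(transition_index(matrix(c(0L, 1L), 2, 1)), "1..10")
})

test_that("counts and probabilities: examples, conservation, oracle", {
  T1 <- transition_index(matrix(c(1L, 1L, 1L), 3, 1))
  c1 <- transition_counts(T1)
  expect_equal(c1[1L], 2L)
  expect_equal(sum(c1), 2L)
  expect_equal(transition_probabilities(c1)[1L], 100)

  set.seed(50)
  S <- matrix(sample.int(10L, 50 * 20, replace = TRUE), 50, 20)
  cts <- transition_counts(transition_index(S))
  expect_equal(cts, oracle_counts(S))
  expect_equal(sum(cts), 49L * 20L)
  expect_equal(sum(transition_probabilities(cts)), 100)
  expect_error(transition_counts(integer(0)), "empty")
})

test_that("dwell-time examples match the run rules", {
  # 1 -> 2 after dwelling 3 frames in state 1
  d <- dwell_times(matrix(c(1L, 1L, 1L, 2L), 4, 1), frame_rate = 1.8)
  expect_equal(d$tau_pre[2L], 3 / 1.8)
  # post-dwell of that occurrence is undefined (last step)
  expect_equal(d$tau_post[2L], 0)

  # [2,2]: one self occurrence; neither dwell is evaluable (first and last step)
  d2 <- dwell_times(matrix(c(2L, 2L), 2, 1), frame_rate = 1)
  expect_equal(d2$counts[12L], 1L)
  expect_equal(d2$tau_pre[12L], 0)
  expect_equal(d2$tau_post[12L], 0)

  # constant run: one max contribution (no double counting), count 4
  d3 <- dwell_times(matrix(rep(5L, 5), 5, 1), frame_rate = 1)
  k <- 11L * 5L - 10L
  expect_equal(d3$counts[k], 4L)
  expect_equal(d3$tau_pre[k], 4 / 4)      # single contribution of n1 = 4
  expect_equal(d3$tau_post[k], 4 / 4)
  expect_true(all(is.na(d3$tau_pre[-k])))
})

test_that("dwell times equal the brute-force oracle on random matrices", {
  for (seed in 1:200) {
    S <- random_state_matrix(seed)
    got <- dwell_times(S, frame_rate = 1.8)
    want <- oracle_dwell(S, frame_rate = 1.8)
    expect_equal(got$counts, want$counts)
    expect_equal(got$tau_pre, want$tau_pre, tolerance = 1e-12)
    expect_equal(got$tau_post, want$tau_post, tolerance = 1e-12)
  }
})

test_that("dwell times depend only on states, not amplitudes", {
  set.seed(60)
  S <- random_state_matrix(60, max_nt = 30)
  expect_equal(dwell_times(S), dwell_times(S))   # deterministic
  # (amplitudes never enter the dwell computation: API takes only S)
  expect_named(dwell_times(S), c("tau_pre", "tau_post", "counts"))
})

test_that("component statistics: constant field and GA flux identity", {
  set.seed(70)
  S <- random_state_matrix(70, max_nt = 12)
  T <- transition_index(S)
  X0 <- matrix(4.2, nrow(S), ncol(S))
  st <- component_transition_stats(X0, T)
  occ <- transition_counts(T) > 0
  expect_equal(st$mu_pre[occ], rep(4.2, sum(occ)))
  expect_equal(st$mu_post[occ], rep(4.2, sum(occ)))
  expect_equal(st$flux[occ], rep(0, sum(occ)))
  expect_true(all(is.na(st$mu_pre[!occ])))

  X <- matrix(rnorm(length(S)), nrow(S), ncol(S))
  ga <- component_transition_stats(X, T, "GA")
  expect_equal(ga$flux[occ], (ga$mu_post - ga$mu_pre)[occ], tolerance = 1e-12)
})

test_that("all three averaging schemes match their oracles", {
  for (seed in 1:40) {
    S <- random_state_matrix(seed + 1000L)
    X <- matrix(rnorm(length(S)), nrow(S), ncol(S))
    T <- transition_index(S)
    for (scheme in c("GA", "TMSM", "SMTM")) {
      got <- component_transition_stats(X, T, scheme)
      want <- oracle_component_stats(X, S, scheme)
      expect_equal(got$mu_pre, want$mu_pre, tolerance = 1e-12)
      expect_equal(got$mu_post, want$mu_post, tolerance = 1e-12)
      expect_equal(got$flux, want$flux, tolerance = 1e-12)
    }
  }
})

test_that("scheme equivalences in degenerate limits", {
  set.seed(80)
  # single voxel: GA == TMSM
  S <- matrix(sample.int(10L, 30, replace = TRUE), 30, 1)
  X <- matrix(rnorm(30), 30, 1)
  T <- transition_index(S)
  ga <- component_transition_stats(X, T, "GA")
  tm <- component_transition_stats(X, T, "TMSM")
  expect_equal(ga, tm, tolerance = 1e-12)
  # single time step: GA == SMTM
  S2 <- matrix(sample.int(10L, 2 * 40, replace = TRUE), 2, 40)
  X2 <- matrix(rnorm(80), 2, 40)
  T2 <- transition_index(S2)
  expect_equal(component_transition_stats(X2, T2, "GA"),
               component_transition_stats(X2, T2, "SMTM"), tolerance = 1e-12)
})

test_that("adjacency suite is internally consistent", {
  sim <- generate_hb_series(sim_config(n_frames = 120, n_voxels = 40, seed = 5))
  suite <- adjacency_suite(sim$unaffected)
  expect_s3_class(suite, "adjacency_suite")
  expect_equal(ncol(suite$coefficients), 18L)     # 3 state + 15 component
  expect_equal(sum(suite$coefficients[, "prob"]), 100, tolerance = 1e-12)
  expect_equal(suite$coefficients[, "prob"],
               transition_probabilities(suite$counts), ignore_attr = TRUE)
  expect_equal(sum(suite$counts), (120L - 1L) * 40L)
  # missing types are NA, never zero
  miss <- suite$counts == 0L
  if (any(miss)) {
    expect_true(all(is.na(suite$coefficients[miss, "dwell_pre"])))
    expect_true(all(is.na(suite$coefficients[miss, "flux_total"])))
  }
  # group mean of identical subjects equals the single suite
  gm <- suite_group_mean(list(suite, suite, suite))
  expect_equal(gm$coefficients, suite$coefficients, tolerance = 1e-12)

  m <- as_adjacency_matrix(suite, "prob")
  expect_equal(dim(m), c(10L, 10L))
  expect_equal(m[3, 7], suite$coefficients[27L, "prob"], ignore_attr = TRUE)

  lg <- suite_long(suite, "s1", "L")
  expect_equal(nrow(lg), 1800L)
  expect_equal(lg$value[lg$coefficient_class == "prob"][27L], m[3, 7],
               ignore_attr = TRUE)
})

test_that("long-format TSV round-trips", {
  sim <- generate_hb_series(sim_config(n_frames = 80, n_voxels = 20, seed = 6))
  suite <- adjacency_suite(sim$affected)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_suite_long(suite, path, subject = "s7", breast = "T")
  back <- read_suite_long(path)
  expect_length(back, 1L)
  expect_equal(back[[1L]]$coefficients[, "prob"],
               suite$coefficients[, "prob"], ignore_attr = TRUE)
  expect_equal(back[[1L]]$counts, suite$counts)
})
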