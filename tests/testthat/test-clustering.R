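test_that("init_centers draws distinct records, reproducibly", {
  ps <- rand_pointset(100, 3, seed = 1)
  cs <- init_centers(ps, 3, seed = 9)
  expect_equal(nrow(cs$centers), 3)
  expect_equal(anyDuplicated(cs$init_idx), 0)
  # every center is an actual record
  for (r in 1:3) {
    expect_true(any(apply(ps$coords, 1, function(x) all(x == cs$centers[r, ]))))
  }
  expect_identical(init_centers(ps, 3, seed = 9)$centers, cs$centers)
  # k = N exhausts the data: centers are a permutation of the records
  cs <- init_centers(ps, 100, seed = 2)
  expect_identical(sort(cs$init_idx), 1:100)
  expect_error(init_centers(ps, 101), "exceed")
  expect_error(init_centers(ps, 0), "k")
})

test_that("lloyd converges to the exact solution on trivially separated data", {
  ps <- point_set(rbind(c(0, 0), c(2, 0)))
  res <- lloyd_kmeans(ps, run_config(k = 2, method = "lloyd", seed = 1))
  expect_equal(sse(ps, res$assignments, res$centers), 0)
  expect_setequal(res$assignments, c(1, 2))
  # k = 1: the center is the coordinate-wise mean
  ps <- rand_pointset(50, 4, seed = 3)
  res <- lloyd_kmeans(ps, run_config(k = 1, method = "lloyd", seed = 1))
  expect_equal(unname(res$centers[1, ]), unname(colMeans(ps$coords)))
})

test_that("lloyd recovers the sample means of two well-separated blobs", {
  set.seed(8)
  X <- rbind(matrix(stats::rnorm(400, 0), 200, 2),
             matrix(stats::rnorm(400, 20), 200, 2))
  ps <- point_set(X)
  res <- lloyd_kmeans(ps, run_config(k = 2, method = "lloyd", seed = 4))
  m1 <- colMeans(X[1:200, ])
  m2 <- colMeans(X[201:400, ])
  err <- min(max(abs(res$centers - rbind(m1, m2))),
             max(abs(res$centers - rbind(m2, m1))))
  expect_lt(err, 0.5)
})

test_that("lloyd MSE trace is non-increasing", {
  for (case in 1:20) {
    ps <- rand_pointset(120, 2, seed = 200 + case)
    res <- lloyd_kmeans(ps, run_config(k = 4, method = "lloyd", seed = case))
    expect_true(all(diff(res$mse_trace) <= 1e-10 * res$mse_trace[1]))
  }
})

test_that("the MacQueen running-mean update follows the 1/n recurrence", {
  # a center that has won one record (its initializer at 0) absorbs (2)
  up <- feskmeans:::macqueen_update(0, 2, wins = 1)
  expect_equal(up$center, 1)
  expect_equal(up$wins, 2)
  # a record equal to the center leaves it unchanged
  up <- feskmeans:::macqueen_update(c(3, 4), c(3, 4), wins = 5)
  expect_equal(up$center, c(3, 4))
  # after one pass over records won by a single center, the center is the
  # running mean of initializer plus presentations
  ps <- point_set(matrix(c(0, 3, 6), 3, 1))
  res <- macqueen_kmeans(ps, run_config(k = 1, method = "macqueen",
                                        seed = 1, max_iter = 1))
  init <- unname(ps$coords[res$init_idx, 1])
  expect_equal(unname(res$centers[1, 1]),
               (init + 0 + 3 + 6) / 4)
})

test_that("macqueen and lloyd agree on perfectly separated blobs", {
  g <- separated_blobs(2, 150, seed = 1, spread = 1, box = c(0, 60))
  la <- lloyd_kmeans(g$points, run_config(k = 2, method = "lloyd", seed = 7))
  mq <- macqueen_kmeans(g$points, run_config(k = 2, method = "macqueen",
                                             seed = 7))
  expect_gte(perm_agreement(mq$assignments, la$assignments), 1)
})

test_that("the Mashor schedule decays exactly as eta / exp(1/sqrt(k + t))", {
  st <- mashor_eta_update(list(eta = 1, iter = 1, cluster_count = 10))
  expect_equal(st$eta, exp(-1 / sqrt(11)), tolerance = 1e-12)
  expect_equal(st$iter, 2L)
  expect_error(mashor_eta_update(list(eta = 0, iter = 1, cluster_count = 2)),
               "positive")
  # strict decrease, positivity, and slowing decay
  st <- list(eta = 0.6, iter = 1, cluster_count = 5)
  ratios <- numeric(30)
  for (i in 1:30) {
    nxt <- mashor_eta_update(st)
    expect_gt(nxt$eta, 0)
    expect_lt(nxt$eta, st$eta)
    ratios[i] <- nxt$eta / st$eta
    st <- nxt
  }
  expect_true(all(diff(ratios) > 0))   # decay factor climbs toward 1
})

test_that("the FES center step is center + eta * (point - center)", {
  expect_equal(fes_update_center(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_equal(fes_update_center(c(1, 1), c(9, 9), 1), c(9, 9))
  expect_equal(fes_update_center(c(1, 1), c(9, 9), 0), c(1, 1))
  expect_error(fes_update_center(c(1, 1), c(9, 9, 9), 0.5), "dimension")
  expect_error(fes_update_center(c(1, 1), c(9, 9), 1.5), "eta")
})

test_that("fes terminates after one epoch when epsilon dwarfs the data", {
  ps <- rand_pointset(60, 2, seed = 5)
  res <- fes_kmeans(ps, run_config(k = 3, seed = 2, epsilon = 1e6))
  expect_equal(res$n_iter, 1)
  expect_equal(res$reason, "center_change")
  expect_true(res$converged)
})

test_that("fes eta trace starts at eta0 and decreases strictly", {
  ps <- rand_pointset(200, 2, seed = 6)
  res <- fes_kmeans(ps, run_config(k = 4, eta0 = 0.6, seed = 3,
                                   epsilon = 1e-12, max_iter = 15))
  expect_equal(res$eta_trace[1], 0.6)
  expect_true(all(diff(res$eta_trace) < 0))
  expect_true(all(res$eta_trace > 0))
  expect_equal(res$eta_trace[2], 0.6 * exp(-1 / sqrt(4 + 1)),
               tolerance = 1e-12)
  expect_equal(length(res$mse_trace), res$n_iter)
  expect_true(all(res$assignments >= 1 & res$assignments <= 4))
})

test_that("the tree-accelerated FES path equals the brute-force sequential variant", {
  for (case in 1:6) {
    ps <- rand_pointset(120, 1 + case %% 3, seed = 300 + case)
    cfg <- run_config(k = 2 + case %% 4, seed = case, max_iter = 8,
                      shuffle = case %% 2 == 0)
    got <- fes_kmeans(ps, cfg)
    want <- fes_brute(ps, cfg)
    expect_identical(got$assignments, want$assignments)
    expect_identical(got$centers, want$centers)
    expect_identical(got$eta_trace, want$eta_trace)
    expect_identical(got$reason, want$reason)
  }
})

test_that("dead centers are reported, and reseeding relocates them", {
  # a far-away center that owns nothing stays dead without reseeding
  X <- rbind(matrix(stats::rnorm(100, 0, .1), 50, 2),
             matrix(stats::rnorm(100, 10, .1), 50, 2))
  lab <- rep(c(1L, 2L), each = 50)
  C <- rbind(c(0, 0), c(10, 10), c(100, 100))
  moved <- feskmeans:::reseed_dead_centers(X, C, lab, dead = 3L)
  # the relocated center is a data point
  expect_true(any(apply(X, 1, function(x) all(x == moved[3, ]))))
  ps <- point_set(X)
  res <- fes_kmeans(ps, run_config(k = 2, seed = 1))
  expect_length(res$dead_centers, 0)
  res <- fes_kmeans(ps, run_config(k = 2, seed = 1, reseed_dead = TRUE))
  expect_s3_class(res, "feskm_result")
})

test_that("run_config validates its fields", {
  expect_error(run_config(k = 2, eta0 = 0), "eta0")
  expect_error(run_config(k = 2, eta0 = 1.2), "eta0")
  expect_error(run_config(k = 2, epsilon = -1), "epsilon")
  expect_error(run_config(k = 0), "k")
  expect_error(run_config(k = 2, max_iter = 0), "max_iter")
})
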