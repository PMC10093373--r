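test_that("configuration invariants are enforced", {
  expect_error(hgso_config(population_size = 10, n_clusters = 3),
               class = "dermhgso_invalid_argument")
  expect_error(hgso_config(C1 = 0.3, C2 = 0.2),
               class = "dermhgso_invalid_argument")
  expect_error(hgso_config(population_size = 3),
               class = "dermhgso_invalid_argument")
  expect_error(search_bounds(c(0, 1), c(1, 1)),
               class = "dermhgso_invalid_argument")
})

test_that("initialization follows the stated constants and clustering rule", {
  b <- search_bounds(c(0, 0), c(1, 1))
  cfg <- hgso_config(population_size = 8, n_clusters = 2, max_iter = 10)
  # degenerate stub: every uniform draw = 0.5
  u <- list(pos = matrix(0.5, 8, 2), H = c(0.5, 0.5), C = c(0.5, 0.5),
            P = rep(0.5, 8))
  st <- initialize_population(b, cfg, u = u)
  expect_equal(st$H, c(0.025, 0.025))       # l1 * 0.5
  expect_equal(st$C, c(0.005, 0.005))       # l3 * 0.5
  expect_equal(st$P, rep(50, 8))            # l2 * 0.5
  expect_equal(st$S, 1 * 0.025 * rep(50, 8))
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_equal(st$cluster, rep(1:2, each = 4))

  # random init: one H per cluster, shared within
  st2 <- withr::with_seed(1, initialize_population(b, cfg))
  expect_equal(length(unique(st2$H)), 2L)
  st3 <- withr::with_seed(1, initialize_population(b, cfg))
  expect_identical(st2, st3)
})

test_that("ranking selects per-cluster and global minima with index ties", {
  fit <- c(3, 1, 2, 5, 0, 9)
  cl <- rep(1:2, each = 3)
  r <- rank_and_select_best(fit, cl)
  expect_equal(r$cluster_best_index, c(2L, 5L))
  expect_equal(r$best_index, 5L)

  # single cluster: cluster best == global best
  r1 <- rank_and_select_best(fit, rep(1L, 6))
  expect_equal(r1$cluster_best_index, r1$best_index)

  # ties broken by lowest agent index
  r2 <- rank_and_select_best(c(2, 1, 1, 1), rep(1L, 4))
  expect_equal(r2$best_index, 2L)
  expect_error(rank_and_select_best(c(1, NA), c(1, 1)),
               class = "dermhgso_invalid_argument")
})

test_that("Henry coefficient anneals as the formula dictates", {
  cfg <- hgso_config(population_size = 4, n_clusters = 1, max_iter = 50)
  # strictly decreasing for positive exponent constants
  H <- 0.025
  for (t in 1:50) {
    H2 <- update_henry_coefficient(H, 0.005, t, cfg)
    expect_lt(H2, H)
    H <- H2
  }
  # C = 0 leaves H unchanged
  expect_equal(update_henry_coefficient(0.025, 0, 10, cfg), 0.025)
  # direct evaluation at t = max_iter: T = exp(-1)
  got <- update_henry_coefficient(0.025, 0.005, 50, cfg)
  expect_equal(got, 0.025 * exp(-0.005 * (exp(1) - 1 / 298)), tolerance = 1e-15)
  expect_error(update_henry_coefficient(0.025, 0.005, 51, cfg),
               class = "dermhgso_invalid_argument")
})

test_that("solubility is the Henry-law product and scales linearly in K", {
  cfg <- hgso_config(population_size = 4, n_clusters = 1)
  expect_equal(update_solubility(0.025, 50, 1L, cfg), 1.25)
  expect_equal(update_solubility(0.025, 0, 1L, cfg), 0)
  cfg5 <- hgso_config(population_size = 4, n_clusters = 1, K = 5)
  expect_equal(update_solubility(0.025, 50, 1L, cfg5),
               5 * update_solubility(0.025, 50, 1L, cfg))
})

test_that("position updates fix points and zero-draw behaviour", {
  b <- search_bounds(c(-5, -5), c(5, 5))
  cfg <- hgso_config(population_size = 4, n_clusters = 1, max_iter = 10)
  st <- initialize_population(b, cfg, u = list(
    pos = matrix(0.5, 4, 2), H = 0.5, C = 0.5, P = rep(0.5, 4)))
  st$fitness <- c(1, 2, 3, 4)
  bests <- rank_and_select_best(st$fitness, st$cluster)

  # r = 0 leaves every position unchanged
  r0 <- list(F = rep(1, 4), r1 = matrix(0, 4, 2), r2 = matrix(0, 4, 2))
  st0 <- update_positions(st, bests, st$positions[1, ], st$fitness[1], b, cfg,
                          rand = r0)
  expect_equal(st0$positions, st$positions)

  # an agent sitting at its cluster best with S * X_best = X is a fixed point
  stf <- st
  stf$S <- rep(1, 4)
  stf$positions <- matrix(0, 4, 2)   # X_best = X = 0, S * X_best - X = 0
  rnd <- list(F = rep(1, 4), r1 = matrix(0.5, 4, 2), r2 = matrix(0.5, 4, 2))
  stf2 <- update_positions(stf, bests, c(0, 0), stf$fitness[1], b, cfg,
                           rand = rnd)
  expect_equal(stf2$positions, stf$positions)

  # updates are clipped to the bounds
  stc <- st
  stc$S <- rep(100, 4)
  stc2 <- update_positions(stc, bests, c(5, 5), 0, b, cfg, rand = rnd)
  expect_true(all(stc2$positions >= -5 & stc2$positions <= 5))
})

test_that("one stubbed position update matches hand arithmetic", {
  b <- search_bounds(c(-5, -5), c(5, 5))
  cfg <- hgso_config(population_size = 4, n_clusters = 1, max_iter = 10,
                     beta = 1, alpha = 1, epsilon = 0.05)
  positions <- matrix(c(1, -1,
                        2, 2,
                        -3, 0,
                        4, -4), 4, 2, byrow = TRUE)
  st <- initialize_population(b, cfg, u = list(
    pos = matrix(0.5, 4, 2), H = 0.5, C = 0.5, P = rep(0.5, 4)))
  st$positions <- positions
  st$fitness <- c(2, 8, 1, 9)   # best agent 3
  st$S <- rep(1.25, 4)
  bests <- rank_and_select_best(st$fitness, st$cluster)
  best_pos <- positions[3, ]; best_fit <- 1
  rnd <- list(F = c(1, -1, 1, 1), r1 = matrix(0.5, 4, 2),
              r2 = matrix(0.5, 4, 2))
  got <- update_positions(st, bests, best_pos, best_fit, b, cfg, rand = rnd)

  # independent scalar computation of the two-term update
  expected <- positions
  for (i in 1:4) {
    gam <- 1 * exp(-(best_fit + 0.05) / (st$fitness[i] + 0.05))
    for (j in 1:2) {
      step <- rnd$F[i] * 0.5 * gam * (positions[3, j] - positions[i, j]) +
        rnd$F[i] * 0.5 * 1 * (1.25 * best_pos[j] - positions[i, j])
      expected[i, j] <- min(max(positions[i, j] + step, -5), 5)
    }
  }
  expect_equal(got$positions, expected, tolerance = 1e-12)
})

test_that("worst-agent count respects the sampling band and rounding", {
  cfg <- hgso_config(population_size = 30, n_clusters = 5)
  expect_equal(count_worst_agents(30, cfg, u = 0.5), 4L)  # 4.5 rounds half-even
  expect_equal(count_worst_agents(30, cfg, u = 0), 3L)
  expect_equal(count_worst_agents(30, cfg, u = 1), 6L)
  for (i in 1:50) {
    nw <- count_worst_agents(30, cfg)
    expect_gte(nw, 3L); expect_lte(nw, 6L)
  }
})

test_that("only the worst agents are re-seeded", {
  b <- search_bounds(c(0, 0), c(1, 1))
  cfg <- hgso_config(population_size = 4, n_clusters = 1)
  st <- initialize_population(b, cfg, u = list(
    pos = matrix(0.25, 4, 2), H = 0.5, C = 0.5, P = rep(0.5, 4)))
  st$fitness <- c(5, 1, 9, 2)

  st0 <- reinitialize_worst(st, 0, b)
  expect_equal(st0$positions, st$positions)

  st2 <- reinitialize_worst(st, 2, b, u = matrix(0.9, 2, 2))
  expect_equal(sort(attr(st2, "reseeded")), c(1L, 3L))   # fitness 5 and 9
  expect_equal(st2$positions[c(1, 3), ], matrix(0.9, 2, 2))
  expect_equal(st2$positions[c(2, 4), ], st$positions[c(2, 4), ])
  expect_true(all(is.na(st2$fitness[c(1, 3)])))

  stall <- reinitialize_worst(st, 4, b)
  expect_true(all(stall$positions >= 0 & stall$positions <= 1))
  expect_error(reinitialize_worst(st, 5, b), class = "dermhgso_invalid_argument")
})

test_that("the optimizer loop is deterministic with a monotone record", {
  b <- search_bounds(c(-5, -5), c(5, 5))
  cfg <- hgso_config(population_size = 10, n_clusters = 2, max_iter = 25,
                     seed = 7)
  res <- hgso_minimize(sphere_fn, b, cfg)
  expect_equal(nrow(res$history), 25L)
  expect_true(all(diff(res$history$best_fitness) <= 0))
  res2 <- hgso_minimize(sphere_fn, b, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$best_position, res2$best_position)

  # constant objective: the record equals the constant from iteration 1
  resc <- hgso_minimize(function(x) 3.5, b,
                        hgso_config(population_size = 8, n_clusters = 2,
                                    max_iter = 5, seed = 1))
  expect_equal(resc$history$best_fitness, rep(3.5, 5))
  expect_equal(resc$best_fitness, 3.5)

  expect_error(
    hgso_minimize(function(x) NaN, b,
                  hgso_config(population_size = 4, n_clusters = 1,
                              max_iter = 2, seed = 1)),
    class = "dermhgso_evaluation_error")
})

test_that("positions stay inside the bounds after a full run", {
  b <- search_bounds(c(-2, 0), c(3, 1))
  res <- hgso_minimize(sphere_fn, b,
                       hgso_config(population_size = 8, n_clusters = 2,
                                   max_iter = 15, seed = 3))
  expect_true(all(res$best_position >= b$lower & res$best_position <= b$upper))
})

test_that("hyperparameter decoding rounds, exponentiates and round-trips", {
  sp <- hyperparameter_space()
  expect_equal(decode_position(c(-2, 4.7, 30, 0.5), sp)$batch_size, 5L)
  expect_equal(decode_position(c(-4, 10, 30, 0.5), sp)$lr0, 1e-4)
  dec <- decode_position(c(-2, 8, 30.4, 0.31), sp)
  expect_equal(dec$lr0, 1e-2)
  expect_equal(dec$epochs, 30L)
  expect_equal(dec$dropout, 0.31)

  # round-trip identity on a representable grid
  for (lr in c(1e-4, 1e-3, 1e-2)) {
    for (bsz in c(2L, 16L, 64L)) {
      s <- list(lr0 = lr, batch_size = bsz, epochs = 25L, dropout = 0.4)
      expect_equal(decode_position(encode_settings(s, sp), sp), s)
    }
  }
  expect_error(decode_position(c(0, 4, 30, 0.5), sp),
               class = "dermhgso_invalid_argument")
  expect_error(decode_position(c(-2, 4, 30), sp),
               class = "dermhgso_invalid_argument")
})

test_that("misclassification percentage is the literal error rate", {
  expect_equal(misclassification_rate(rep(1, 10), c(rep(1, 8), 0, 0)), 20)
  expect_equal(misclassification_rate(1:5, 1:5), 0)
  expect_equal(misclassification_rate(rep(0, 4), rep(1, 4)), 100)
  expect_error(misclassification_rate(1:3, 1:4),
               class = "dermhgso_invalid_argument")
})
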