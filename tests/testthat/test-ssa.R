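test_that("the convergence coefficient follows its schedule", {
  expect_identical(compute_c1(0, 50), 2)
  expect_equal(compute_c1(50, 50), 2 * exp(-16))
  expect_equal(compute_c1(50, 50), 2.2508e-7, tolerance = 1e-4)
  expect_equal(compute_c1(25, 50), 2 * exp(-4))
  expect_equal(compute_c1(25, 50), 3.6631e-2, tolerance = 1e-4)
  tgrid <- seq(0, 100)
  expect_true(all(diff(compute_c1(tgrid, 100)) < 0))
  expect_error(compute_c1(1, 0), "positive")
})

test_that("leader update matches hand evaluation and clamps to bounds", {
  sp1 <- search_space("x", 0, 10)
  # c1 = 0 collapses both branches onto the food source
  expect_equal(update_leader(5, sp1, 0, c2 = 0.7, c3 = 0.1), 5)
  expect_equal(update_leader(5, sp1, 0, c2 = 0.7, c3 = 0.9), 5)
  # first branch: 5 + 0.5 * (10 * 0.5 + 0) = 7.5
  expect_equal(update_leader(5, sp1, 0.5, c2 = 0.5, c3 = 0.2), 7.5)
  # second branch: 5 - 1 * (10 * 1 + 0) = -5, clamped to lower bound 0
  expect_equal(update_leader(5, sp1, 1, c2 = 1, c3 = 0.7), 0)
  expect_error(update_leader(c(1, 2), sp1, 1), "mismatch")
})

test_that("follower chain averages sequentially toward the predecessor", {
  same <- matrix(2, nrow = 4, ncol = 3)
  expect_equal(update_followers(same), same)
  expect_equal(update_followers(matrix(c(0, 2), ncol = 1)),
               matrix(c(0, 1), ncol = 1))
  expect_equal(update_followers(matrix(c(0, 2, 4), ncol = 1)),
               matrix(c(0, 1, 2.5), ncol = 1))
  # simultaneous variant uses pre-update neighbors
  expect_equal(update_followers(matrix(c(0, 2, 4), ncol = 1),
                                sequential = FALSE),
               matrix(c(0, 1, 3), ncol = 1))
  expect_error(update_followers(matrix(1, 1, 2)), "at least 2")
})

test_that("position decoding rounds integers half away from zero within bounds", {
  rf <- rf_search_space()
  low <- decode_position(rf$lower, rf)
  expect_identical(low, list(n_estimators = 50L, max_depth = 3L,
                             min_samples_split = 2L, min_samples_leaf = 1L))
  xg <- xgb_search_space()
  lowx <- decode_position(xg$lower, xg)
  expect_equal(lowx, list(n_estimators = 50L, max_depth = 3L,
                          learning_rate = 0.01, gamma = 0,
                          min_child_weight = 1L))
  expect_equal(decode_position(c(250.6, 10, 5, 5), rf)$n_estimators, 251L)
  expect_equal(round_half_up(c(2.5, -2.5, 250.6)), c(3, -3, 251))
  expect_error(decode_position(c(1, 2), rf), "match")
})

test_that("the swarm solves benchmark problems across seeds", {
  sp2 <- search_space(c("x", "y"), -5, 5)
  for (s in 1:10) {
    res <- ssa_optimize(function(p) sum(p^2), sp2, n_salps = 20,
                        n_iter = 100, seed = s)
    expect_lt(res$best_fitness, 1e-3)
    expect_true(all(diff(res$trace$best_fitness) <= 0))
  }
  sp1 <- search_space("x", 0, 10)
  res1 <- ssa_optimize(function(p) abs(p - 3), sp1, n_salps = 10,
                       n_iter = 50, seed = 1)
  expect_lt(abs(res1$best_position[["x"]] - 3), 0.1)
})

test_that("elitism and bound safety hold for every evaluated position", {
  sp <- search_space(c("a", "b"), c(-2, 0), c(3, 1))
  seen <- list()
  fitness <- function(p) {
    seen[[length(seen) + 1]] <<- p
    (p[1] - 1)^2 + 5 * (p[2] - 0.3)^2
  }
  res <- ssa_optimize(fitness, sp, n_salps = 8, n_iter = 25, seed = 4)
  mat <- do.call(rbind, seen)
  expect_equal(nrow(mat), res$n_evaluations)
  expect_true(all(mat[, 1] >= -2 & mat[, 1] <= 3))
  expect_true(all(mat[, 2] >= 0 & mat[, 2] <= 1))
  fits <- apply(mat, 1, function(p) (p[1] - 1)^2 + 5 * (p[2] - 0.3)^2)
  expect_equal(res$best_fitness, min(fits))
  expect_equal(res$trace$best_fitness[res$n_iter], min(fits))
})

test_that("leader steps shrink from exploration to exploitation", {
  sp <- search_space(c("x", "y"), -5, 5)
  wins <- 0L
  for (s in 1:10) {
    leader_pos <- list()
    fitness <- function(p) sum(p^2)
    # record the leader (first salp) each iteration via a wrapped fitness
    i <- 0L
    rec_fitness <- function(p) {
      i <<- i + 1L
      if (i %% 12 == 1) leader_pos[[length(leader_pos) + 1]] <<- p
      fitness(p)
    }
    res <- ssa_optimize(rec_fitness, sp, n_salps = 12, n_iter = 60, seed = s)
    steps <- sapply(2:length(leader_pos), function(j) {
      sqrt(sum((leader_pos[[j]] - leader_pos[[j - 1]])^2))
    })
    early <- mean(steps[1:12]); late <- mean(steps[(length(steps) - 11):length(steps)])
    wins <- wins + (early > late)
  }
  expect_gte(wins, 8)
})

test_that("an erroring fitness aborts with iteration and position context", {
  sp <- search_space("x", 0, 1)
  expect_error(
    ssa_optimize(function(p) stop("boom"), sp, n_salps = 2, n_iter = 1,
                 seed = 1),
    "iteration 1")
  expect_error(ssa_optimize(function(p) 0, sp, n_salps = 1, n_iter = 5), "at least 2")
  expect_error(search_space("x", 1, 1), "lower < upper")
})
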