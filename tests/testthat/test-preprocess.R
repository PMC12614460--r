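test_that("stratified split reproduces largest-remainder sizes and is a partition", {
  co <- generate_cohort(seed = 1)
  sp <- split_cohort(co, seed = 3)
  expect_equal(lengths(sp), c(train = 495L, validation = 124L, test = 155L))

  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_len(774))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$validation, sp$test), 0)

  # per-partition event prevalence within one case of global
  prev <- mean(co$rupture)
  for (part in sp) {
    expect_lte(abs(sum(co$rupture[part]) - length(part) * prev), 1)
  }

  expect_identical(unclass(split_cohort(co, seed = 3)), unclass(sp))
  expect_false(identical(split_cohort(co, seed = 4)$train, sp$train))
  expect_error(split_cohort(co, fractions = c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("largest-remainder allocation matches hand arithmetic", {
  expect_equal(largest_remainder(774, c(0.64, 0.16, 0.20)),
               c(495L, 124L, 155L))
  expect_equal(largest_remainder(10, c(0.8, 0.1, 0.1)), c(8L, 1L, 1L))
  small <- make_noise_cohort(n = 10, prevalence = 0.3, seed = 1)
  sp <- split_cohort(small, fractions = c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(unname(lengths(sp)), c(8L, 1L, 1L))
})

test_that("chained imputation completes data without touching observed cells", {
  complete <- make_blobs(seed = 2)
  expect_identical(impute_chained(complete), complete)

  # correlated pair: imputation should track the observed distribution
  withr::local_seed(7)
  n <- 400
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.8^2) * rnorm(n)
  tb <- tibble::tibble(a = a, b = b)
  holes <- sample(n, 80)
  tb$b[holes] <- NA
  done <- impute_chained(tb, n_cycles = 10, seed = 1)
  expect_false(anyNA(done))
  expect_identical(done$a, tb$a)
  expect_identical(done$b[-holes], tb$b[-holes])
  se <- sd(b[-holes]) / sqrt(length(holes))
  expect_lt(abs(mean(done$b[holes]) - mean(b[-holes])), 3 * se)

  # binary column imputed by logistic draw stays 0/1
  tb2 <- tibble::tibble(x = rnorm(200), z = as.integer(rnorm(200) > 0))
  tb2$z[sample(200, 40)] <- NA
  done2 <- impute_chained(tb2, seed = 2)
  expect_true(all(done2$z %in% c(0L, 1L)))

  all_na <- tibble::tibble(a = rnorm(5), b = rep(NA_real_, 5))
  expect_error(impute_chained(all_na), "zero observed")
})

test_that("feature screening follows the normality and expected-count rules", {
  withr::local_seed(5)
  n <- 495
  y <- rep(c(0L, 1L), c(464, 31))
  train <- tibble::tibble(
    sep_cont = ifelse(y == 1, rnorm(n, 10), rnorm(n, 0)),   # disjoint supports
    norm_null = rnorm(n),                                    # normal, no effect
    skew_null = rexp(n),                                     # non-normal, no effect
    null_bin = rep(rep(c(0, 1), c(1, 1)), length.out = n),
    rare_bin = c(rep(0, 464), rep(c(1, 0), c(4, 27))),       # 0/464 vs 4/31
    rupture = y)
  res <- screen_features(train)

  expect_true(res$selected[res$variable == "sep_cont"])
  expect_lt(res$p_value[res$variable == "sep_cont"], 0.05)
  expect_equal(res$test[res$variable == "norm_null"], "t")
  expect_equal(res$test[res$variable == "skew_null"], "mann_whitney")
  expect_equal(res$test[res$variable == "rare_bin"], "fisher")
  expect_lt(res$p_value[res$variable == "rare_bin"], 0.05)

  # identical group proportions: no association
  bal <- tibble::tibble(x = rep(c(0, 1), 40),
                        rupture = rep(c(0L, 1L), each = 40))
  bal$x <- rep(c(0, 1), 40)  # 50% in both groups
  resb <- screen_features(bal)
  expect_equal(resb$p_value, 1, tolerance = 1e-8)
  expect_false(resb$selected)

  const <- tibble::tibble(c1 = rep(1, 40), x = rnorm(40),
                          rupture = rep(c(0L, 1L), 20))
  expect_warning(resc <- screen_features(const), "constant")
  expect_equal(resc$p_value[resc$variable == "c1"], 1)
  expect_false(resc$selected[resc$variable == "c1"])

  # top_k keeps only the k smallest p-values among the selected
  res_k <- screen_features(train, top_k = 1)
  expect_equal(sum(res_k$selected), 1)
  expect_equal(res_k$variable[res_k$selected], "sep_cont")
})

test_that("screening holds its nominal type-I rate on null cohorts", {
  selected <- logical(0)
  for (s in seq_len(200)) {
    co <- make_noise_cohort(n = 80, prevalence = 0.4, p = 8, seed = s)
    res <- screen_features(co)
    selected <- c(selected, res$selected)
  }
  rate <- mean(selected)
  se <- sqrt(0.05 * 0.95 / length(selected))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("SMOTE balances classes with convex in-hull synthetic rows", {
  withr::local_seed(3)
  train <- make_noise_cohort(n = 495, prevalence = 31 / 495, p = 3, seed = 3)
  out <- apply_smote(train, seed = 1)
  expect_equal(sum(out$rupture == 1), 464)
  expect_equal(sum(out$rupture == 0), 464)
  # original rows preserved verbatim at the top
  expect_identical(out[seq_len(495), ], train)
  # synthetic rows stay coordinate-wise inside the minority range
  minority <- train[train$rupture == 1, c("f1", "f2", "f3")]
  synth <- out[-seq_len(495), c("f1", "f2", "f3")]
  for (v in names(minority)) {
    expect_true(all(synth[[v]] >= min(minority[[v]]) - 1e-12))
    expect_true(all(synth[[v]] <= max(minority[[v]]) + 1e-12))
  }

  balanced <- make_blobs(n0 = 20, n1 = 20, seed = 1)
  expect_identical(apply_smote(balanced), balanced)
  tiny <- make_noise_cohort(n = 40, prevalence = 0.1, seed = 1)
  expect_error(apply_smote(tiny, k_neighbors = 5), "k_neighbors")
})

test_that("SMOTE binary features take the nearer parent's value", {
  withr::local_seed(8)
  train <- tibble::tibble(cont = c(rnorm(80), rnorm(20, 3)),
                          bin = c(rbinom(80, 1, 0.5), rbinom(20, 1, 0.5)),
                          rupture = rep(c(0L, 1L), c(80, 20)))
  out <- apply_smote(train, seed = 2)
  expect_true(all(out$bin %in% c(0, 1)))
})

test_that("standardization is fitted on train only", {
  train <- make_blobs(seed = 1)
  test <- make_blobs(seed = 99, sep = 5)
  std <- standardize(train, test)
  tr <- std$partitions[[1]]
  for (v in c("f1", "f2")) {
    expect_lt(abs(mean(tr[[v]])), 1e-8)
    expect_lt(abs(sd(tr[[v]]) - 1), 1e-8)
  }
  te <- std$partitions[[2]]
  expect_gt(max(abs(colMeans(te[, c("f1", "f2")]))), 0.01)

  # leakage audit: refitting on test yields different parameters
  std_test <- standardize(test)
  expect_false(isTRUE(all.equal(std$params$center, std_test$params$center)))

  degen <- tibble::tibble(f1 = rep(2, 10), rupture = rep(c(0L, 1L), 5))
  expect_warning(stdz <- standardize(degen), "Zero-variance")
  expect_equal(stdz$params$scale, 1)
})

test_that("the leakage audit accepts clean splits and rejects contaminated ones", {
  co <- generate_cohort(seed = 1)
  sp <- split_cohort(co, seed = 1)
  expect_true(audit_leakage(sp, list(screening = sp$train, scaler = sp$train,
                                     smote = sp$train)))
  expect_error(audit_leakage(sp, list(scaler = c(sp$train, sp$test[1]))),
               "test-partition")
  expect_error(audit_leakage(sp, list(scaler = sp$validation)),
               "outside the training")
  broken <- sp
  broken$train <- broken$train[-1]
  expect_error(audit_leakage(broken), "partition")
})
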