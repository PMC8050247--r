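test_that("sigmoid is correct, symmetric and overflow-safe", {
  expect_identical(sigmoid(0), 0.5)
  z <- c(-20, -3, -0.5, 0.1, 2, 15)
  expect_equal(sigmoid(-z), 1 - sigmoid(z))
  expect_equal(sigmoid(3), 1 / (1 + exp(-3)))
  expect_true(sigmoid(1000) > 1 - 1e-12 && sigmoid(1000) <= 1)
  expect_true(sigmoid(-1000) >= 0 && sigmoid(-1000) < 1e-12)
  expect_false(any(is.nan(sigmoid(c(-1e6, 1e6)))))
})

test_that("cross-entropy matches the closed form and validates its domain", {
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(0, 0.5), log(2))
  expect_equal(cross_entropy(1, 0.9), -log(0.9))
  # monotone decrease to 0 as yhat -> y
  yh <- c(0.5, 0.9, 0.99, 0.999999)
  expect_true(all(diff(cross_entropy(rep(1, 4), yh)) < 0))
  expect_lt(cross_entropy(1, 1 - 1e-13), 1e-11)
  expect_error(cross_entropy(1, 1.2), "\\[0, 1\\]")
  expect_error(cross_entropy(1, -0.1), "\\[0, 1\\]")
  expect_error(cross_entropy(0.5, 0.5), "binary")
})

test_that("balanced problem weights split loss mass equally between classes", {
  lib <- fm_from(matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), 4, 2))
  prob <- decomposition_problem(lib, c(1, 0, 1, 0))
  expect_equal(sum(prob$weights), 2)
  expect_equal(sum(prob$weights[prob$c == 1]), 1)
  # constant c collapses to one class, flagged degenerate
  p1 <- decomposition_problem(lib, c(1, 1, 1, 1))
  expect_true(p1$degenerate)
  expect_equal(sum(p1$weights), 1)
  expect_error(decomposition_problem(lib, c(1, 0, 2, 0)), "binary")
  expect_error(decomposition_problem(lib, c(1, 0)), "length")
})

test_that("objective at zero equals 2*log(2) and is linear in lambda", {
  set.seed(12)
  for (i in 1:5) {
    prob <- random_small_problem(100 + i, n_features = 12, n_ing = 3)
    d <- ncol(prob$D)
    expect_equal(decomposition_objective(numeric(d), prob),
                 2 * log(2), tolerance = 1e-13)
    x <- rnorm(d)
    p2 <- prob; p2$lambda <- 2 * prob$lambda
    expect_equal(decomposition_objective(x, p2) -
                   decomposition_objective(x, prob),
                 prob$lambda * sum(abs(x)))
  }
  prob <- random_small_problem(1)
  expect_error(decomposition_objective(numeric(5), prob), "one entry per")
})

test_that("solutions above lambda_max are exactly zero", {
  for (s in 1:8) {
    prob <- random_small_problem(200 + s, n_features = 18, n_ing = 4)
    lmax <- lambda_max(prob)
    prob$lambda <- lmax * 1.000001
    expect_identical(unname(solve_fixed_lambda(prob)), numeric(4))
    # just below, the solution moves
    prob$lambda <- lmax * 0.9
    expect_gt(max(abs(solve_fixed_lambda(prob))), 0)
  }
})

test_that("solver matches the exhaustive grid-search oracle on small problems", {
  for (s in 1:6) {
    prob <- random_small_problem(300 + s, n_features = 12, n_ing = 2)
    x <- solve_fixed_lambda(prob)
    fhat <- decomposition_objective(x, prob)
    fstar <- grid_oracle_min(prob)
    expect_lte(fhat, fstar + 1e-3)
    # 0 is feasible, so the solution can never beat it by less than 0
    expect_lte(fhat, decomposition_objective(numeric(2), prob) + 1e-12)
  }
})

test_that("solver agrees with glmnet as an independent weighted-lasso solver", {
  skip_if_not_installed("glmnet")
  # Eq-equivalence: the balanced decomposition is a weighted L1 logistic
  # regression without intercept; glmnet minimizes
  # (1/sum(w)) sum w_i CE_i + lambda ||x||_1 after weight normalization,
  # so lambda_glmnet = lambda_ours / sum(w) with sum(w) = 2.
  for (s in 1:4) {
    prob <- random_small_problem(400 + s, n_features = 20, n_ing = 4,
                                 lambda = 0.05)
    g <- suppressWarnings(
      glmnet::glmnet(prob$D, prob$c, family = "binomial",
                     weights = prob$weights, alpha = 1,
                     lambda = prob$lambda / 2, intercept = FALSE,
                     standardize = FALSE, thresh = 1e-14))
    xg <- as.numeric(g$beta)
    xm <- unname(solve_fixed_lambda(prob))
    fg <- decomposition_objective(xg, prob)
    fm <- decomposition_objective(xm, prob)
    expect_lte(fm, fg + 1e-5)         # ours is at least as good
    expect_equal(xm, xg, tolerance = 5e-3)
  }
})

test_that("disjoint two-ingredient toy attributes the sample to the true ingredient", {
  v <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L), 4, 2)
  lib <- fm_from(v, sids = c("ing1", "ing2"))
  prob <- decomposition_problem(lib, c(1, 1, 0, 0), lambda = 0.05)
  # unconstrained: the true ingredient is positive, the absent one is
  # pushed negative (its features must be explained away); verified
  # against the grid oracle
  x <- solve_fixed_lambda(prob)
  expect_gt(x[["ing1"]], 0.1)
  expect_lt(x[["ing2"]], 0)
  expect_gt(x[["ing1"]], x[["ing2"]])
  expect_lte(decomposition_objective(unname(x), prob),
             grid_oracle_min(prob) + 1e-3)
  # nonnegative abundance mode: the absent ingredient is exactly zero
  xn <- solve_fixed_lambda(prob, nonneg = TRUE)
  expect_gt(xn[["ing1"]], 0.1)
  expect_identical(xn[["ing2"]], 0)
})

test_that("lambda path lands on the target support for exact unions", {
  lib <- make_library(200, 10, 12, overlap = 0, seed = 6)
  cx <- make_complex(lib, 5, seed = 7)
  prob <- decomposition_problem(lib, cx$sample)
  res <- lambda_path_to_k(prob, k = 5)
  expect_setequal(res$selected, cx$truth$true_ingredients)
  expect_equal(res$nonzero_count, 5L)
  expect_false(res$fallback)
  # selection ordered by descending abundance then ID
  ab <- res$x[res$selected]
  expect_true(all(diff(ab) <= 0))
  # path log: support size weakly non-increasing in lambda
  pl <- res$path_log[order(res$path_log$lambda), ]
  expect_true(all(diff(pl$nonzero_count) <= 0))

  # single ingredient profile, k = 1
  cx1 <- make_complex(lib, 1, seed = 8)
  res1 <- lambda_path_to_k(decomposition_problem(lib, cx1$sample), k = 1)
  expect_identical(res1$selected, cx1$truth$true_ingredients)

  expect_error(lambda_path_to_k(prob, k = 11), "exceeds")
  expect_error(lambda_path_to_k(prob, k = 0), "positive")
})

test_that("all-zero samples decompose to the degenerate empty result", {
  lib <- make_library(100, 8, 10, seed = 4)
  zero <- stats::setNames(integer(100), feature_ids(lib))
  res <- predict_ingredients(lib, zero, k = 3)
  expect_true(res$degenerate)
  expect_length(res$selected, 0)
  expect_true(all(res$x == 0))
})

test_that("all-zero appended rows act only through the class reweighting", {
  # Appending features absent from both the sample (c = 0) and every
  # ingredient profile keeps the weight mass at 2 and contributes a
  # constant log(2)-per-row term; the minimizer therefore equals that of
  # the original rows under the enlarged zero-class weight.
  prob <- random_small_problem(55, n_features = 14, n_ing = 3, lambda = 0.04)
  lib2 <- fm_from(rbind(prob$D, matrix(0L, 6, 3)),
                  fids = sprintf("f%d", 1:20),
                  sids = colnames(prob$D))
  prob2 <- decomposition_problem(lib2, c(prob$c, rep(0, 6)),
                                 lambda = prob$lambda)
  expect_equal(sum(prob2$weights), 2)
  x2 <- solve_fixed_lambda(prob2)
  # reference: original problem with its zero-class rows reweighted to
  # the enlarged class size
  prob_rw <- prob
  n0_new <- sum(prob$c == 0) + 6
  prob_rw$weights[prob$c == 0] <- 1 / n0_new
  x_rw <- solve_fixed_lambda(prob_rw)
  expect_equal(unname(x2), unname(x_rw), tolerance = 1e-6)
  # and the objectives differ by exactly the constant 6*log(2)/n0_new
  expect_equal(decomposition_objective(unname(x2), prob2) -
                 (decomposition_objective(unname(x2), prob_rw) +
                    6 * log(2) / n0_new), 0, tolerance = 1e-12)
})

test_that("prediction is deterministic and tolerant of unknown sample features", {
  lib <- make_library(150, 8, 10, overlap = 0.1, seed = 13)
  cx <- make_complex(lib, 3, dropout = 0.1, spurious = 0.02, seed = 14)
  r1 <- predict_ingredients(lib, cx$sample, k = 3)
  r2 <- predict_ingredients(lib, cx$sample, k = 3)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$selected, r2$selected)
  # extra features unknown to the library: alignment zero-fills library rows
  extra <- stats::setNames(c(cx$sample, 1L, 1L),
                           c(names(cx$sample), "Fnew1", "Fnew2"))
  r3 <- predict_ingredients(lib, extra, k = 3)
  expect_length(r3$selected, 3)
})

test_that("nonnegative mode never returns negative abundances", {
  prob <- random_small_problem(77, n_features = 16, n_ing = 4, lambda = 0.02)
  x <- solve_fixed_lambda(prob, nonneg = TRUE)
  expect_true(all(x >= 0))
  res <- lambda_path_to_k(prob, k = 2, nonneg = TRUE)
  expect_true(all(res$x >= 0))
})

test_that("overlap score counts the intersection", {
  expect_equal(overlap_score(letters[1:5], letters[1:5]), 5)
  expect_equal(overlap_score(letters[1:5], LETTERS[1:5]), 0)
  expect_equal(overlap_score(c("a", "b", "c", "d", "e"), c("c", "e", "f")), 2)
  expect_error(overlap_score(character(0), "a"), "empty")
})

test_that("random baseline is seeded, uniform and matches its analytic mean", {
  lib <- make_library(100, 20, 5, seed = 1)
  expect_setequal(random_baseline(lib, k = 20, seed = 3), sample_ids(lib))
  expect_identical(random_baseline(lib, k = 5, seed = 9),
                   random_baseline(lib, k = 5, seed = 9))
  expect_error(random_baseline(lib, k = 21, seed = 1), "exceeds")
  # hypergeometric mean k*m/n over many seeds
  annot <- sample_ids(lib)[1:8]
  ov <- vapply(1:400, function(s)
    overlap_score(random_baseline(lib, k = 5, seed = s), annot), numeric(1))
  expect_lt(abs(mean(ov) - 5 * 8 / 20), 3 * sd(ov) / sqrt(400))
  # baseline leaves the global RNG state alone
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(random_baseline(lib, k = 5, seed = 7))
  expect_identical(rnorm(1), before)
})
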