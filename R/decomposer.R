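#' Numerically stable logistic sigmoid
#'
#' `sigmoid(z) = 1 / (1 + exp(-z))`, the link that converts the linear
#' combination of ingredient profiles into a detection probability.
#' Computed without overflow for arbitrarily large `|z|`.
#'
#' @param z numeric vector.
#' @return Values in `(0, 1)` (saturating to exactly 0/1 only at double
#'   precision limits); `sigmoid(0) == 0.5` and
#'   `sigmoid(-z) == 1 - sigmoid(z)`.
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(z)] <- NA_real_
  out
}

#' Binary cross-entropy
#'
#' `-y*log(yhat) - (1-y)*log(1-yhat)` between a binary observation and a
#' predicted probability. `yhat` is clamped to `[1e-12, 1 - 1e-12]` so the
#' value stays finite at the boundary; values outside `[0, 1]` are an
#' error.
#'
#' @param y 0/1 vector.
#' @param yhat predicted probabilities in `[0, 1]`.
#' @return Nonnegative numeric vector, elementwise.
#' @export
cross_entropy <- function(y, yhat) {
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("y must be binary (0/1)")
  if (any(is.na(yhat)) || any(yhat < 0) || any(yhat > 1))
    stop("yhat must lie in [0, 1]")
  yhat <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
  -y * log(yhat) - (1 - y) * log(1 - yhat)
}

#' Set up a balanced decomposition problem
#'
#' Pairs a raw-ingredient reference library `D` (features x candidate
#' ingredients) with a complex sample's binary profile `c` and computes the
#' balance weights: each row t gets weight `1/b_t` where `b_t` is the
#' number of entries of `c` sharing the value `c_t`. Present and absent
#' features thus contribute equal total loss mass (sum of weights is 2
#' when `c` has both values), which stops the typically vast majority of
#' absent features from dominating the fit. A constant `c` (all 0 or all
#' 1) collapses to a single class (weight mass 1) and is flagged
#' degenerate.
#'
#' @param library a [feature_matrix()]: columns are candidate raw
#'   ingredients.
#' @param sample binary vector of length `nrow(library)` (or a one-column
#'   `feature_matrix` on the same feature axis).
#' @param lambda nonnegative L1 penalty weight.
#' @return An object of class `decomposition_problem` with elements `D`,
#'   `c`, `weights`, `lambda`, `degenerate`.
#' @export
decomposition_problem <- function(library, sample, lambda = 0) {
  validate_feature_matrix(library)
  if (inherits(sample, "feature_matrix")) {
    if (ncol(sample$values) != 1L)
      stop("sample must be a single column")
    if (!identical(sample$feature_ids, library$feature_ids))
      stop("sample and library feature axes differ; run align_features() first")
    sample <- drop(sample$values)
  }
  cvec <- as.numeric(sample)
  if (length(cvec) != nrow(library$values))
    stop("sample length does not match library feature count")
  if (!all(cvec %in% c(0, 1))) stop("sample must be binary (0/1)")
  if (lambda < 0) stop("lambda must be nonnegative")
  n1 <- sum(cvec == 1)
  n0 <- sum(cvec == 0)
  w <- ifelse(cvec == 1, 1 / max(n1, 1), 1 / max(n0, 1))
  structure(list(D = library$values, c = cvec, weights = w,
                 ingredient_ids = library$sample_ids,
                 lambda = lambda, degenerate = (n1 == 0 || n0 == 0)),
            class = "decomposition_problem")
}

#' Balanced decomposition objective
#'
#' Evaluates
#' `sum_t CE(c_t, sigmoid((D x)_t)) / b_t + lambda * sum_i |x_i|`
#' at a given abundance vector. At `x = 0` with a mixed-value `c` every
#' predicted probability is 0.5, so the value is exactly `2 * log(2)`.
#'
#' @param x abundance vector, one entry per candidate ingredient.
#' @param problem a [decomposition_problem()].
#' @return Scalar objective value.
#' @export
decomposition_objective <- function(x, problem) {
  stopifnot(inherits(problem, "decomposition_problem"))
  if (length(x) != ncol(problem$D))
    stop("x must have one entry per candidate ingredient")
  a <- drop(problem$D %*% x)
  sum(problem$weights * .ce_linear(a, problem$c)) +
    problem$lambda * sum(abs(x))
}

#' Critical penalty weight above which the solution is exactly zero
#'
#' From the L1 optimality condition at the origin: 0 minimizes the
#' objective iff `lambda >= max_i |g_i|` where `g = D' (w * (0.5 - c))` is
#' the gradient of the balanced cross-entropy term at `x = 0` (in the
#' nonnegative mode, iff `lambda >= max_i(-g_i)`).
#'
#' @param problem a [decomposition_problem()].
#' @param nonneg use the nonnegative-abundance optimality condition.
#' @return The critical `lambda_max`.
#' @export
lambda_max <- function(problem, nonneg = FALSE) {
  stopifnot(inherits(problem, "decomposition_problem"))
  g <- drop(crossprod(problem$D, problem$weights * (0.5 - problem$c)))
  if (nonneg) max(c(-g, 0)) else max(abs(g))
}

#' Solve the balanced decomposition at a fixed penalty
#'
#' Minimizes the convex objective of [decomposition_objective()] by
#' proximal gradient descent with momentum. Deterministic: identical
#' inputs give identical output.
#'
#' @param problem a [decomposition_problem()] (its `lambda` is used).
#' @param tol relative objective-change convergence tolerance.
#' @param nonneg constrain abundances to be nonnegative.
#' @param x0 optional warm-start vector.
#' @param max_iter iteration cap; non-convergence raises an error of class
#'   `metsum_no_convergence` carrying the best iterate.
#' @return Named abundance vector over candidate ingredients.
#' @export
solve_fixed_lambda <- function(problem, tol = 1e-10, nonneg = FALSE,
                               x0 = NULL, max_iter = 20000L) {
  stopifnot(inherits(problem, "decomposition_problem"))
  fit <- fit_weighted_logistic(problem$D, problem$c, problem$weights,
                               lambda = problem$lambda, penalty = "l1",
                               intercept = FALSE, nonneg = nonneg,
                               x0 = x0, tol = tol, max_iter = max_iter)
  stats::setNames(fit$x, problem$ingredient_ids)
}

.nonzero_idx <- function(x) {
  thr <- 1e-6 * max(1, max(abs(x)))
  which(abs(x) > thr)
}

.rank_selected <- function(x, idx, ids) {
  ord <- order(-x[idx], ids[idx], method = "radix")
  ids[idx][ord]
}

#' Regularization-path search for a target support size
#'
#' Sweeps the L1 penalty until the minimizer has exactly `k` nonzero
#' abundances — the support-size stopping rule for picking the `k` most
#' likely raw ingredients. The search starts at the analytic
#' [lambda_max()] (where the solution is exactly zero), descends
#' geometrically (factor 0.8) until at least `k` coefficients are active,
#' then bisects between the bracketing penalties to land on exactly `k`
#' (at most 60 bisection steps). Solves are warm-started along the path;
#' convexity makes the warm start a speed-up only. If the active-set size
#' jumps over `k` between consecutive penalties, the documented fallback
#' applies: the visited solution with the smallest support of size >= `k`
#' is ranked by coefficient and truncated to `k`, and the result is
#' flagged `fallback`.
#'
#' A numerically "nonzero" coefficient is one with
#' `|x_i| > 1e-6 * max(1, max_j |x_j|)`. An all-zero sample is degenerate:
#' the solution is 0 for every positive penalty, and the result carries an
#' empty selection with `degenerate = TRUE`.
#'
#' @param problem a [decomposition_problem()].
#' @param k target number of ingredients (default 5).
#' @param nonneg constrain abundances to be nonnegative.
#' @param tol per-solve convergence tolerance.
#' @return An object of class `decomposition_result`: abundance vector
#'   `x`, `selected` ingredient IDs (descending coefficient, ties by ID),
#'   `lambda_used`, `objective_value`, `nonzero_count`, `path_log` (a data
#'   frame of every `(lambda, nonzero_count)` visited), and flags
#'   `fallback` / `degenerate`.
#' @export
lambda_path_to_k <- function(problem, k = 5L, nonneg = FALSE, tol = 1e-10) {
  stopifnot(inherits(problem, "decomposition_problem"))
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  n_ing <- ncol(problem$D)
  if (k > n_ing)
    stop(sprintf("k = %d exceeds the %d candidate ingredients", k, n_ing))
  ids <- problem$ingredient_ids
  mk_problem <- function(lam) { p <- problem; p$lambda <- lam; p }
  log_lam <- numeric(0); log_cnt <- integer(0)
  sols <- list()
  solve_at <- function(lam, x0) {
    x <- solve_fixed_lambda(mk_problem(lam), tol = tol, nonneg = nonneg,
                            x0 = x0)
    cnt <- length(.nonzero_idx(x))
    log_lam <<- c(log_lam, lam); log_cnt <<- c(log_cnt, cnt)
    sols[[length(sols) + 1L]] <<- list(lambda = lam, x = x, count = cnt)
    cnt
  }
  finish <- function(entry, fallback, degenerate = FALSE) {
    x <- entry$x
    idx <- .nonzero_idx(x)
    if (fallback && length(idx) > k) {
      sel <- .rank_selected(x, idx, ids)[seq_len(k)]
    } else {
      sel <- .rank_selected(x, idx, ids)
    }
    structure(list(
      x = x, selected = sel, lambda_used = entry$lambda,
      objective_value = decomposition_objective(x, mk_problem(entry$lambda)),
      nonzero_count = entry$count,
      path_log = data.frame(lambda = log_lam, nonzero_count = log_cnt),
      fallback = fallback, degenerate = degenerate),
      class = "decomposition_result")
  }

  lmax <- lambda_max(problem, nonneg = nonneg)
  if (problem$degenerate && all(problem$c == 0)) {
    lam0 <- max(lmax, 1e-8)
    log_lam <- lam0; log_cnt <- 0L
    return(finish(list(lambda = lam0, x = stats::setNames(numeric(n_ing), ids),
                       count = 0L), fallback = FALSE, degenerate = TRUE))
  }
  # at lmax the solution is exactly 0 (optimality condition); record it
  log_lam <- lmax; log_cnt <- 0L
  sols[[1]] <- list(lambda = lmax, x = stats::setNames(numeric(n_ing), ids),
                    count = 0L)
  lam <- lmax
  x_warm <- numeric(n_ing)
  cnt <- 0L
  max_desc <- 200L
  for (i in seq_len(max_desc)) {
    lam <- lam * 0.8
    cnt <- solve_at(lam, x_warm)
    x_warm <- sols[[length(sols)]]$x
    if (cnt >= k) break
  }
  if (cnt < k)
    return(finish(sols[[length(sols)]], fallback = TRUE,
                  degenerate = problem$degenerate))
  if (cnt == k)
    return(finish(sols[[length(sols)]], fallback = FALSE,
                  degenerate = problem$degenerate))
  # bracket: lam (count > k) .. lam/0.8 (count < k); geometric bisection
  lo <- sols[[length(sols)]]                  # smaller lambda, count > k
  hi_lam <- lam / 0.8
  best_ge_k <- lo
  for (i in seq_len(60L)) {
    mid <- sqrt(lo$lambda * hi_lam)
    cnt <- solve_at(mid, lo$x)
    entry <- sols[[length(sols)]]
    if (cnt == k)
      return(finish(entry, fallback = FALSE, degenerate = problem$degenerate))
    if (cnt > k) {
      lo <- entry
      if (cnt < best_ge_k$count) best_ge_k <- entry
    } else {
      hi_lam <- mid
    }
  }
  finish(best_ge_k, fallback = TRUE, degenerate = problem$degenerate)
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(
    "decomposition_result: %d selected (lambda = %.4g, objective = %.4g%s%s)\n",
    length(x$selected), x$lambda_used, x$objective_value,
    if (isTRUE(x$fallback)) ", fallback" else "",
    if (isTRUE(x$degenerate)) ", degenerate" else ""))
  if (length(x$selected)) {
    tab <- data.frame(ingredient = x$selected,
                      abundance = unname(x$x[x$selected]))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Predict the most likely raw ingredients of a complex sample
#'
#' End-to-end decomposition: aligns the sample onto the library's feature
#' axis (features unknown to the library are carried as zero-filled
#' library rows), computes balance weights, and runs the
#' [regularization-path search][lambda_path_to_k] for the `k` ingredients
#' whose union of profiles best explains the sample.
#'
#' @param library raw-ingredient [feature_matrix()].
#' @param sample binary named vector (names = feature IDs) or a one-column
#'   `feature_matrix`.
#' @param k number of ingredients to report (default 5).
#' @param nonneg constrain abundances to be nonnegative rather than
#'   fitting the unconstrained objective.
#' @param tol per-solve convergence tolerance.
#' @return A `decomposition_result` (see [lambda_path_to_k()]).
#' @export
predict_ingredients <- function(library, sample, k = 5L, nonneg = FALSE,
                                tol = 1e-10) {
  validate_feature_matrix(library)
  if (!inherits(sample, "feature_matrix")) {
    v <- as.matrix(as.numeric(sample))
    if (is.null(names(sample)))
      stop("sample must be a named vector or a feature_matrix")
    sample <- feature_matrix(v, feature_ids = names(sample),
                             sample_ids = "query")
  }
  al <- align_features(library, sample)
  problem <- decomposition_problem(al$reference, al$query)
  lambda_path_to_k(problem, k = k, nonneg = nonneg, tol = tol)
}

#' Overlap between predicted and annotated ingredient sets
#'
#' The benchmark score for ingredient detection: the number of predicted
#' ingredients that appear in the annotated ingredient list,
#' `|predicted intersect annotated|`.
#'
#' @param predicted character vector of predicted ingredient IDs
#'   (nonempty).
#' @param annotated character vector of annotated ingredient IDs.
#' @return Integer in `[0, length(predicted)]`.
#' @export
overlap_score <- function(predicted, annotated) {
  if (length(predicted) == 0L) stop("predicted set is empty")
  length(intersect(predicted, annotated))
}

#' Random-ingredient baseline predictor
#'
#' Draws `k` ingredient IDs uniformly without replacement — the null
#' predictor against which decomposition overlap is judged. Against a
#' fixed annotation of size m from a library of n ingredients its expected
#' overlap is the hypergeometric mean `k*m/n`. Uses a private RNG stream;
#' the caller's random state is untouched.
#'
#' @param library raw-ingredient [feature_matrix()].
#' @param k number of ingredients to draw.
#' @param seed integer seed (same seed, same draw).
#' @return Character vector of `k` ingredient IDs.
#' @export
random_baseline <- function(library, k = 5L, seed) {
  validate_feature_matrix(library)
  ids <- library$sample_ids
  if (k > length(ids))
    stop(sprintf("k = %d exceeds the %d library ingredients", k, length(ids)))
  with_local_seed(seed, sample(ids, k))
}

# Evaluate `expr` under `seed` without disturbing the global RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
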