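# Weighted penalized logistic solver shared by the classifier and the
# decomposer. Minimizes
#
#     sum_t w_t * CE(y_t, sigmoid((A x)_t + b))  +  penalty(x)
#
# with penalty lambda*||x||_1 (prox step) or lambda*||x||_2^2 (smooth),
# optional unpenalized intercept b, and optional nonnegativity on x.
# FISTA with adaptive restart; the loss is convex so any accumulation
# point is a global minimizer. Deterministic: no randomized initialization.

# Stable log(1 + exp(a)) - y*a == CE(y, sigmoid(a))
.ce_linear <- function(a, y) {
  pmax(a, 0) - y * a + log1p(exp(-abs(a)))
}

.smooth_value <- function(A, y, w, x, b) {
  a <- drop(A %*% x) + b
  sum(w * .ce_linear(a, y))
}

.smooth_grad <- function(A, y, w, x, b) {
  a <- drop(A %*% x) + b
  r <- w * (sigmoid(a) - y)
  list(gx = drop(crossprod(A, r)), gb = sum(r))
}

# Largest squared singular value of diag(sqrt(w)) %*% [A | 1] via power
# iteration (deterministic start); Lipschitz constant of the gradient of
# the weighted logistic loss is this / 4.
.lipschitz <- function(A, w, intercept) {
  p <- ncol(A) + as.integer(intercept)
  v <- rep(1 / sqrt(p), p)
  mv <- function(v) {
    a <- drop(A %*% v[seq_len(ncol(A))])
    if (intercept) a <- a + v[p]
    wa <- w * a
    out <- drop(crossprod(A, wa))
    if (intercept) out <- c(out, sum(wa))
    out
  }
  s <- 0
  for (i in 1:100) {
    v2 <- mv(v)
    s2 <- sqrt(sum(v2^2))
    if (s2 == 0) return(1e-12)
    v2 <- v2 / s2
    if (abs(s2 - s) <= 1e-10 * max(1, s)) { s <- s2; break }
    s <- s2
    v <- v2
  }
  max(s, 1e-12) / 4
}

.prox_l1 <- function(x, thr, nonneg) {
  if (nonneg) pmax(x - thr, 0) else sign(x) * pmax(abs(x) - thr, 0)
}

# Core fit. Returns list(x, intercept, objective, converged, iter).
fit_weighted_logistic <- function(A, y, w, lambda, penalty = c("l1", "l2"),
                                  intercept = FALSE, nonneg = FALSE,
                                  x0 = NULL, b0 = 0,
                                  tol = 1e-10, max_iter = 20000L,
                                  on_fail = c("error", "warn")) {
  penalty <- match.arg(penalty)
  on_fail <- match.arg(on_fail)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  p <- ncol(A)
  stopifnot(length(y) == nrow(A), length(w) == nrow(A), all(w > 0),
            lambda >= 0)
  x <- if (is.null(x0)) numeric(p) else as.numeric(x0)
  b <- b0
  l2 <- penalty == "l2"
  L <- .lipschitz(A, w, intercept) + if (l2) 2 * lambda else 0
  step <- 1 / L
  obj <- function(x, b) {
    .smooth_value(A, y, w, x, b) +
      if (l2) lambda * sum(x^2) else lambda * sum(abs(x))
  }
  fx <- obj(x, b)
  zx <- x; zb <- b; tk <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- .smooth_grad(A, y, w, zx, zb)
    if (l2) g$gx <- g$gx + 2 * lambda * zx
    xn <- zx - step * g$gx
    xn <- if (l2) { if (nonneg) pmax(xn, 0) else xn }
          else .prox_l1(xn, step * lambda, nonneg)
    bn <- if (intercept) zb - step * g$gb else b
    fn <- obj(xn, bn)
    if (fn > fx) {              # adaptive restart: drop momentum
      tk <- 1
      zx <- x; zb <- b
      g <- .smooth_grad(A, y, w, zx, zb)
      if (l2) g$gx <- g$gx + 2 * lambda * zx
      xn <- zx - step * g$gx
      xn <- if (l2) { if (nonneg) pmax(xn, 0) else xn }
            else .prox_l1(xn, step * lambda, nonneg)
      bn <- if (intercept) zb - step * g$gb else b
      fn <- obj(xn, bn)
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zx <- xn + ((tk - 1) / tn) * (xn - x)
    zb <- bn + ((tk - 1) / tn) * (bn - b)
    tk <- tn
    drel <- abs(fx - fn) / max(1, abs(fn))
    x <- xn; b <- bn
    if (drel < tol && it > 1L) { fx <- fn; converged <- TRUE; break }
    fx <- fn
  }
  if (!converged) {
    msg <- sprintf(
      "solver did not reach relative tolerance %g in %d iterations (last relative change %g)",
      tol, max_iter, abs(fx - fn) / max(1, abs(fn)))
    if (on_fail == "error") {
      cond <- structure(
        class = c("metsum_no_convergence", "error", "condition"),
        list(message = msg, call = sys.call(-1),
             best = list(x = x, intercept = b, objective = fx)))
      stop(cond)
    }
    warning(msg)
  }
  list(x = stats::setNames(x, colnames(A)), intercept = b,
       objective = fx, converged = converged, iter = it)
}
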