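# Shared fixture builders and the independent grid-search oracle.

# Small binary feature matrix from a plain matrix with default IDs.
fm_from <- function(m, fids = NULL, sids = NULL) {
  if (is.null(fids)) fids <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(sids)) sids <- sprintf("s%d", seq_len(ncol(m)))
  feature_matrix(m, feature_ids = fids, sample_ids = sids)
}

# Linearly separable toy cohort: each class marked by one exclusive,
# always-present feature.
toy_separable <- function(n_per_class = 10) {
  n <- 2 * n_per_class
  v <- matrix(0L, 3, n)
  v[1, seq_len(n_per_class)] <- 1L                   # class A marker
  v[2, n_per_class + seq_len(n_per_class)] <- 1L     # class B marker
  X <- fm_from(v, fids = c("fa", "fb", "fnull"))
  pheno <- phenotype_table(data.frame(
    sample_id = sample_ids(X),
    label = rep(c("A", "B"), each = n_per_class),
    dataset_id = "DS1", stringsAsFactors = FALSE))
  list(X = X, pheno = pheno)
}

# Exhaustive grid-search oracle for the balanced decomposition objective:
# the minimum of the objective over x in [-3, 3]^d at step `step`,
# evaluated in chunks to bound memory. Independent of the solver.
grid_oracle_min <- function(problem, step = 0.05, lim = 3, chunk = 2e5) {
  d <- ncol(problem$D)
  ax <- seq(-lim, lim, by = step)
  n_ax <- length(ax)
  total <- n_ax^d
  best <- Inf
  start <- 1
  while (start <= total) {
    idx <- start:min(start + chunk - 1, total)
    # decode mixed-radix indices into grid coordinates (d x |idx|)
    G <- matrix(0, d, length(idx))
    rem <- idx - 1
    for (j in seq_len(d)) {
      G[j, ] <- ax[(rem %% n_ax) + 1]
      rem <- rem %/% n_ax
    }
    A <- problem$D %*% G                       # T x |idx|
    ce <- pmax(A, 0) - problem$c * A + log1p(exp(-abs(A)))
    vals <- colSums(problem$weights * ce) + problem$lambda * colSums(abs(G))
    best <- min(best, min(vals))
    start <- start + chunk
  }
  best
}

# Random small decomposition problem for oracle comparisons.
random_small_problem <- function(seed, n_features = 15, n_ing = 2,
                                 lambda = NULL) {
  set.seed(seed)
  v <- matrix(rbinom(n_features * n_ing, 1, 0.4), n_features, n_ing)
  # ensure no all-zero ingredient column and a mixed-value c
  for (j in seq_len(n_ing)) if (sum(v[, j]) == 0) v[sample(n_features, 1), j] <- 1L
  cvec <- rbinom(n_features, 1, 0.4)
  if (all(cvec == 0)) cvec[1] <- 1L
  if (all(cvec == 1)) cvec[1] <- 0L
  lib <- fm_from(v, sids = sprintf("ing%d", seq_len(n_ing)))
  if (is.null(lambda)) lambda <- runif(1, 0.01, 0.3)
  decomposition_problem(lib, cvec, lambda = lambda)
}
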