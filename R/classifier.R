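#' Class-balance weights
#'
#' Each sample t gets weight `1/b_t`, where `b_t` is the number of training
#' samples sharing its label. Every class then contributes total weight
#' exactly 1 to the training loss, so a phenotype with 90% healthy
#' controls cannot be fit by predicting the majority class.
#'
#' @param labels character or factor vector of class labels (nonempty).
#' @return Numeric vector of per-sample weights; attribute `"counts"`
#'   carries the per-class multiplicities.
#' @export
compute_class_weights <- function(labels) {
  if (length(labels) == 0L) stop("empty label vector")
  labels <- as.character(labels)
  b <- table(labels)
  w <- 1 / as.numeric(b[labels])
  attr(w, "counts") <- b
  w
}

#' Balanced-loss objective of a classifier parameter point
#'
#' Evaluates the class-balanced one-vs-rest logistic loss
#' `sum_t CE(1[y_t = c], sigmoid(score_c(x_t))) / b_t` summed over classes,
#' plus the penalty, at arbitrary coefficients. Because the weights are the
#' inverse class multiplicities, duplicating every sample of one class m
#' times leaves the value unchanged — the loss depends on class
#' distributions, not class sizes.
#'
#' @param coefficients features x classes matrix (rownames = feature IDs,
#'   colnames = class labels).
#' @param intercepts per-class numeric vector.
#' @param X a [feature_matrix()].
#' @param labels per-sample class labels (in `colnames(coefficients)`).
#' @param penalty `"l1"` or `"l2"`.
#' @param strength penalty weight.
#' @return Scalar objective value.
#' @export
balanced_objective <- function(coefficients, intercepts, X, labels,
                               penalty = c("l1", "l2"), strength = 0) {
  penalty <- match.arg(penalty)
  validate_feature_matrix(X)
  stopifnot(nrow(coefficients) == nrow(X$values),
            length(labels) == ncol(X$values))
  w <- compute_class_weights(labels)
  classes <- colnames(coefficients)
  loss <- 0
  for (j in seq_along(classes)) {
    a <- drop(crossprod(X$values, coefficients[, j])) + intercepts[j]
    yj <- as.numeric(labels == classes[j])
    loss <- loss + sum(w * .ce_linear(a, yj))
  }
  pen <- if (penalty == "l1") sum(abs(coefficients))
         else sum(coefficients^2)
  loss + strength * pen
}

#' Train a balanced sparse logistic phenotype classifier
#'
#' Fits one-vs-rest penalized logistic regression with the per-sample
#' balance weights of [compute_class_weights()] applied inside every
#' binary subproblem, so each phenotype class carries equal loss mass.
#' The L1 penalty (default) drives most coefficients to exactly zero,
#' which keeps the model interpretable: the few surviving features are the
#' candidate biomarkers, and can be audited for protocol artifacts (see
#' [rank_biomarkers()] and [remove_and_retrain()]). An L2 option is
#' provided for settings where raw accuracy matters more than sparsity.
#'
#' `strength = "auto"` selects the penalty weight by stratified
#' cross-validated balanced accuracy over a geometric grid (deterministic
#' given `seed`).
#'
#' @param X features x samples [feature_matrix()].
#' @param pheno a [phenotype_table()] covering exactly `sample_ids(X)`
#'   (any order).
#' @param penalty `"l1"` (sparse, interpretable; default) or `"l2"`.
#' @param strength positive penalty weight, or `"auto"`.
#' @param tol solver relative-objective convergence tolerance.
#' @param max_iter solver iteration cap.
#' @param cv_folds,seed cross-validation settings used when
#'   `strength = "auto"`.
#' @return An object of class `balanced_logistic`: `class_labels`,
#'   `coefficients` (features x classes), `intercepts`, `penalty`,
#'   `strength`, `removed_features`, `feature_ids`.
#' @export
train_classifier <- function(X, pheno, penalty = c("l1", "l2"),
                             strength = 0.01, tol = 1e-10,
                             max_iter = 20000L, cv_folds = 5L, seed = 1L) {
  penalty <- match.arg(penalty)
  validate_feature_matrix(X)
  if (!inherits(pheno, "phenotype_table")) pheno <- phenotype_table(pheno)
  if (!setequal(pheno$sample_id, X$sample_ids))
    stop("sample IDs of the feature matrix and phenotype table differ")
  labels <- pheno$label[match(X$sample_ids, pheno$sample_id)]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  if (identical(strength, "auto"))
    strength <- .select_strength(X, labels, penalty, cv_folds, seed, tol)
  if (!is.numeric(strength) || strength <= 0)
    stop("strength must be a positive scalar or \"auto\"")
  fit <- .fit_ovr(X$values, labels, classes, penalty, strength, tol, max_iter)
  structure(list(class_labels = classes,
                 coefficients = fit$coefficients,
                 intercepts = fit$intercepts,
                 penalty = penalty, strength = strength,
                 removed_features = character(0),
                 feature_ids = X$feature_ids,
                 settings = list(tol = tol, max_iter = max_iter)),
            class = "balanced_logistic")
}

# one-vs-rest fits sharing the multiclass balance weights
.fit_ovr <- function(values, labels, classes, penalty, strength, tol,
                     max_iter) {
  w <- compute_class_weights(labels)
  A <- t(values)                     # samples x features
  coefs <- matrix(0, nrow(values), length(classes),
                  dimnames = list(rownames(values), classes))
  ints <- stats::setNames(numeric(length(classes)), classes)
  for (j in seq_along(classes)) {
    yj <- as.numeric(labels == classes[j])
    f <- fit_weighted_logistic(A, yj, w, lambda = strength,
                               penalty = penalty, intercept = TRUE,
                               tol = tol, max_iter = max_iter,
                               on_fail = "warn")
    coefs[, j] <- f$x
    ints[j] <- f$intercept
  }
  list(coefficients = coefs, intercepts = ints)
}

.select_strength <- function(X, labels, penalty, cv_folds, seed, tol) {
  classes <- sort(unique(labels))
  grid <- 10^seq(-3, 0, length.out = 7)
  folds <- with_local_seed(seed, {
    f <- integer(length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  bal_acc <- function(truth, pred) {
    mean(vapply(unique(truth),
                function(cl) mean(pred[truth == cl] == cl), numeric(1)))
  }
  score <- vapply(grid, function(s) {
    accs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (length(unique(labels[tr])) < 2L || !any(!tr)) return(NA_real_)
      fit <- .fit_ovr(X$values[, tr, drop = FALSE], labels[tr],
                      sort(unique(labels[tr])), penalty, s, tol,
                      max_iter = 5000L)
      sc <- crossprod(X$values[, !tr, drop = FALSE], fit$coefficients)
      sc <- sweep(sc, 2, fit$intercepts, "+")
      pred <- colnames(sc)[max.col(sc, ties.method = "first")]
      bal_acc(labels[!tr], pred)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(score)]     # ties: smallest strength (first index)
}

#' Predict phenotype labels
#'
#' Aligns the query matrix onto the model's retained feature set (features
#' the model never saw are dropped; model features absent from the query
#' are zero-filled, i.e. treated as not detected), computes per-class
#' linear scores and returns the argmax label per sample. Score ties break
#' deterministically to the earliest class in vocabulary order.
#'
#' @param object a trained `balanced_logistic` model.
#' @param X a [feature_matrix()] of query samples.
#' @param type `"label"` (default) or `"score"` (classes x samples score
#'   matrix).
#' @param ... unused.
#' @return Character label vector named by sample, or the score matrix.
#' @export
predict.balanced_logistic <- function(object, X, type = c("label", "score"),
                                      ...) {
  type <- match.arg(type)
  validate_feature_matrix(X)
  feats <- rownames(object$coefficients)
  v <- matrix(0L, length(feats), ncol(X$values),
              dimnames = list(feats, X$sample_ids))
  shared <- intersect(feats, X$feature_ids)
  v[shared, ] <- X$values[shared, , drop = FALSE]
  scores <- crossprod(object$coefficients, v)          # classes x samples
  scores <- sweep(scores, 1, object$intercepts, "+")
  if (type == "score") return(scores)
  idx <- max.col(t(scores), ties.method = "first")
  stats::setNames(object$class_labels[idx], X$sample_ids)
}

#' Classification accuracy
#'
#' Fraction of samples whose predicted label exactly matches the truth.
#'
#' @param predicted,truth label vectors of equal positive length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty label vectors")
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  mean(as.character(predicted) == as.character(truth))
}

#' Rank candidate biomarkers by coefficient magnitude
#'
#' For each class, lists the top-k features by `|coefficient|` in
#' descending order (ties broken by feature ID). Large-magnitude
#' coefficients are the features the sparse model relies on — genuine
#' biology or, when a feature tracks an acquisition protocol (an internal
#' standard spiked under one protocol only), a batch artifact. Features
#' reported only because `k` exceeds the number of nonzero coefficients
#' are flagged `uninformative`; IDs passed in `suspected` (e.g. known
#' internal standards) are flagged as suspected artifacts.
#'
#' @param model a trained `balanced_logistic`.
#' @param k positive number of features per class.
#' @param suspected character vector of feature IDs to flag.
#' @return An object of class `biomarker_report` whose `table` is a data
#'   frame with columns `feature_id`, `class_label`, `coefficient`,
#'   `rank`, `uninformative`, `suspected_artifact`.
#' @export
rank_biomarkers <- function(model, k, suspected = character(0)) {
  stopifnot(inherits(model, "balanced_logistic"))
  if (k <= 0) stop("k must be positive")
  rows <- lapply(model$class_labels, function(cl) {
    co <- model$coefficients[, cl]
    ord <- order(-abs(co), names(co), method = "radix")
    top <- ord[seq_len(min(k, length(ord)))]
    data.frame(feature_id = names(co)[top], class_label = cl,
               coefficient = unname(co[top]),
               rank = seq_along(top),
               uninformative = unname(co[top]) == 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$suspected_artifact <- tab$feature_id %in% suspected
  structure(list(table = tab, k = as.integer(k)), class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("biomarker_report: top %d features per class\n", x$k))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Remove artifact features and retrain
#'
#' The artifact-audit loop: when top-ranked biomarkers turn out to be
#' internal standards or other protocol-specific signals, they are removed
#' and the model is retrained on the reduced matrix with the identical
#' penalty and strength. Blocklisted IDs absent from the matrix raise a
#' warning, not an error; removing every feature is an error. With an
#' empty blocklist the result reproduces a fresh [train_classifier()] run
#' bit for bit (the solver is deterministic).
#'
#' @param model a trained `balanced_logistic` (supplies penalty, strength
#'   and solver settings; its `removed_features` are carried forward).
#' @param X,pheno the training data.
#' @param blocklist character vector of feature IDs to exclude.
#' @return A retrained `balanced_logistic` whose `removed_features`
#'   contains the blocklist and any previously removed IDs.
#' @export
remove_and_retrain <- function(model, X, pheno, blocklist) {
  stopifnot(inherits(model, "balanced_logistic"))
  validate_feature_matrix(X)
  blocklist <- as.character(blocklist)
  unknown <- setdiff(blocklist, X$feature_ids)
  if (length(unknown))
    warning("blocklisted feature(s) not in matrix: ",
            paste(unknown, collapse = ", "))
  drop_ids <- union(model$removed_features, blocklist)
  keep <- setdiff(X$feature_ids, drop_ids)
  if (length(keep) == 0L) stop("blocklist removes every feature")
  Xr <- feature_matrix(X$values[keep, , drop = FALSE],
                       feature_ids = keep, sample_ids = X$sample_ids)
  m <- train_classifier(Xr, pheno, penalty = model$penalty,
                        strength = model$strength,
                        tol = model$settings$tol,
                        max_iter = model$settings$max_iter)
  m$removed_features <- sort(drop_ids)
  m
}

#' Serialize a trained classifier to JSON
#'
#' @param model a `balanced_logistic`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "balanced_logistic"))
  payload <- list(class_labels = model$class_labels,
                  feature_ids = rownames(model$coefficients),
                  coefficients = unclass(as.data.frame(model$coefficients)),
                  intercepts = as.list(model$intercepts),
                  penalty = model$penalty, strength = model$strength,
                  removed_features = model$removed_features,
                  settings = model$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a classifier written by [write_model()]
#'
#' @param path JSON path.
#' @return The `balanced_logistic` model.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- do.call(cbind, p$coefficients)
  rownames(co) <- p$feature_ids
  structure(list(class_labels = p$class_labels,
                 coefficients = co,
                 intercepts = unlist(p$intercepts),
                 penalty = p$penalty, strength = p$strength,
                 removed_features = as.character(p$removed_features),
                 feature_ids = p$feature_ids,
                 settings = p$settings),
            class = "balanced_logistic")
}

#' @export
print.balanced_logistic <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "balanced_logistic: %d classes, %d features (%d nonzero coefs, %.1f%%), penalty %s @ %g\n",
    length(x$class_labels), nrow(x$coefficients), nz,
    100 * nz / length(x$coefficients), x$penalty, x$strength))
  if (length(x$removed_features))
    cat("removed features:", paste(x$removed_features, collapse = ", "), "\n")
  invisible(x)
}
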