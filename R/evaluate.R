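#' Summarize decomposition performance over a set of samples
#'
#' Computes the per-sample [overlap_score()] between predicted and
#' annotated ingredient sets, its mean, and (optionally) the mean overlap
#' of the seeded [random_baseline()] predictor against the same
#' annotations — the null contrast that establishes the predictions carry
#' signal.
#'
#' @param results list of `decomposition_result` objects (or character
#'   vectors of predicted IDs).
#' @param truths list of the matching annotations: `make_complex()` truth
#'   lists or character vectors of annotated IDs.
#' @param library optional [feature_matrix()]; when given, the random
#'   baseline is computed with `baseline_seeds`.
#' @param baseline_seeds integer seeds, one baseline draw per sample
#'   (recycled).
#' @param k baseline prediction size.
#' @return A list: `mean_overlap`, `per_sample` (data frame with columns
#'   `sample`, `annotated`, `predicted`, `overlap`), and when a library is
#'   supplied `baseline_mean_overlap`.
#' @export
evaluate_decomposition <- function(results, truths, library = NULL,
                                   baseline_seeds = NULL, k = 5L) {
  if (length(results) == 0L) stop("empty result list")
  if (length(results) != length(truths))
    stop("results and truths lengths differ")
  pred <- lapply(results, function(r)
    if (inherits(r, "decomposition_result")) r$selected else as.character(r))
  annot <- lapply(truths, function(t)
    if (is.list(t) && !is.null(t$true_ingredients)) t$true_ingredients
    else as.character(t))
  ov <- mapply(overlap_score, pred, annot)
  per <- data.frame(
    sample = if (!is.null(names(results))) names(results)
             else paste0("sample", seq_along(results)),
    annotated = vapply(annot, paste, "", collapse = ","),
    predicted = vapply(pred, paste, "", collapse = ","),
    overlap = as.integer(ov), stringsAsFactors = FALSE)
  out <- list(mean_overlap = mean(ov), per_sample = per)
  if (!is.null(library)) {
    if (is.null(baseline_seeds)) baseline_seeds <- seq_along(results)
    seeds <- rep_len(baseline_seeds, length(results))
    bl <- mapply(function(s, a)
      overlap_score(random_baseline(library, k = k, seed = s), a),
      seeds, annot)
    out$baseline_mean_overlap <- mean(bl)
  }
  out
}

#' Summarize classification performance
#'
#' Predicts labels for a test cohort and reports overall accuracy plus a
#' confusion matrix with truth as rows and predictions as columns; row
#' sums equal the per-class test sizes (counts are conserved).
#'
#' @param model a trained `balanced_logistic`.
#' @param X test [feature_matrix()].
#' @param pheno matching [phenotype_table()].
#' @return A list: `accuracy`, `confusion` (truth x prediction table),
#'   `predicted` (named label vector).
#' @export
evaluate_classification <- function(model, X, pheno) {
  stopifnot(inherits(model, "balanced_logistic"))
  validate_feature_matrix(X)
  if (!inherits(pheno, "phenotype_table")) pheno <- phenotype_table(pheno)
  if (!setequal(pheno$sample_id, X$sample_ids))
    stop("sample IDs of the feature matrix and phenotype table differ")
  truth <- pheno$label[match(X$sample_ids, pheno$sample_id)]
  pred <- predict(model, X)
  lev <- sort(union(truth, model$class_labels))
  conf <- table(truth = factor(truth, levels = lev),
                predicted = factor(pred, levels = lev))
  list(accuracy = accuracy(pred, truth), confusion = conf, predicted = pred)
}
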