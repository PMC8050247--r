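#' Generate a synthetic raw-ingredient reference library
#'
#' Builds a binary features x ingredients matrix in which every ingredient
#' profile has exactly `support_size` detected features. A fraction
#' `overlap` of each support is drawn from a pool shared by all
#' ingredients — emulating molecules common across foods — and the rest is
#' ingredient-exclusive, so any two supports share `round(overlap *
#' support_size)` features. `overlap = 0` gives pairwise-disjoint supports
#' (the fully identifiable case); raising it stresses the decomposer's
#' ability to attribute shared molecules. Feature positions are permuted
#' under `seed`; the same seed reproduces the matrix bit for bit.
#'
#' @param n_features total feature-universe size.
#' @param n_ingredients number of ingredient columns.
#' @param support_size detected features per ingredient.
#' @param overlap shared fraction of each support, in `[0, 1)`.
#' @param seed integer seed.
#' @return A [feature_matrix()] with feature IDs `F000001, ...` and
#'   ingredient IDs `ING001, ...`.
#' @export
make_library <- function(n_features, n_ingredients, support_size,
                         overlap = 0, seed = 1L) {
  stopifnot(n_features >= 1, n_ingredients >= 1, support_size >= 1,
            overlap >= 0, overlap < 1)
  m_shared <- round(overlap * support_size)
  m_excl <- support_size - m_shared
  if (m_shared + n_ingredients * m_excl > n_features)
    stop(sprintf(
      "infeasible: %d shared + %d x %d exclusive features exceed universe of %d",
      m_shared, n_ingredients, m_excl, n_features))
  with_local_seed(seed, {
    perm <- sample.int(n_features)
    fids <- sprintf("F%06d", seq_len(n_features))
    iids <- sprintf("ING%03d", seq_len(n_ingredients))
    v <- matrix(0L, n_features, n_ingredients, dimnames = list(fids, iids))
    shared <- perm[seq_len(m_shared)]
    pos <- m_shared
    for (j in seq_len(n_ingredients)) {
      excl <- perm[pos + seq_len(m_excl)]
      pos <- pos + m_excl
      v[c(shared, excl), j] <- 1L
    }
    feature_matrix(v)
  })
}

#' Generate a complex sample as a noisy union of ingredient profiles
#'
#' Implements the union model of mixtures: the binary profile of a
#' complex sample is (nearly) the union of its ingredients' profiles.
#' `k` ingredients are chosen uniformly, their supports are unioned, then
#' measurement noise is applied — each 1 drops to 0 with probability
#' `dropout` (missed detection) and each 0 flips to 1 with probability
#' `spurious` (contaminant / misclustered spectrum).
#'
#' @param library a [make_library()] output (or any `feature_matrix`).
#' @param k number of true ingredients.
#' @param dropout,spurious flip probabilities in `[0, 1)`.
#' @param seed integer seed.
#' @return A list: `sample` (named binary vector over the library's
#'   features) and `truth` (list with `true_ingredients`, `params`).
#' @export
make_complex <- function(library, k, dropout = 0, spurious = 0, seed = 1L) {
  validate_feature_matrix(library)
  stopifnot(k >= 1, k <= ncol(library$values),
            dropout >= 0, dropout < 1, spurious >= 0, spurious < 1)
  with_local_seed(seed, {
    picks <- sort(sample(library$sample_ids, k))
    u <- as.integer(rowSums(library$values[, picks, drop = FALSE]) > 0)
    ones <- u == 1L
    u[ones] <- ifelse(stats::runif(sum(ones)) < dropout, 0L, 1L)
    zeros <- !ones
    u[zeros] <- ifelse(stats::runif(sum(zeros)) < spurious, 1L, 0L)
    list(sample = stats::setNames(u, library$feature_ids),
         truth = list(true_ingredients = picks,
                      params = list(k = k, dropout = dropout,
                                    spurious = spurious, seed = seed)))
  })
}

#' Generate a phenotyped cohort, optionally with a protocol confounder
#'
#' Emulates the structure of aggregated repository cohorts: samples carry
#' class-specific signal features on top of a uniform Bernoulli
#' background, and — when `confound` is set — a block of "internal
#' standard" features that track the acquisition protocol (`dataset_id`)
#' rather than any biology. In training-style generation each class is its
#' own source dataset and the confounded dataset coincides with exactly
#' one class, so the confounder features are perfectly correlated with
#' that class label. Generating a second cohort with `confound` pointing
#' at a *different* class produces the protocol-shifted test set on which
#' a classifier that learned the standard, not the biology, collapses.
#'
#' Feature roles are assigned deterministically by position — signal
#' features for the j-th class (in sorted order) are the j-th block of
#' `signal_per_class` features, confounder features the block after all
#' signal blocks — so cohorts generated with compatible shape parameters
#' share feature identities and can serve as train/test pairs.
#'
#' @param n_per_class named integer vector: samples per class label.
#' @param n_features feature-universe size.
#' @param signal_per_class signal features per class.
#' @param signal_penetrance probability a signal feature is present in its
#'   own class (elsewhere it appears at `background_rate`).
#' @param background_rate Bernoulli rate of every non-role feature. The
#'   defaults mirror repository cohorts in which over 90% of samples are
#'   the majority (healthy) class.
#' @param confound optional `list(class=, dataset_id=, n_features=)`
#'   planting confounder features present in every sample of that dataset
#'   and absent elsewhere.
#' @param seed integer seed.
#' @return A list: `X` ([feature_matrix()]), `pheno`
#'   ([phenotype_table()]), `truth` (signal/confounder feature IDs and
#'   generator parameters).
#' @export
make_cohort <- function(n_per_class = c(healthy = 90, disease = 10),
                        n_features = 200, signal_per_class = 5,
                        signal_penetrance = 0.9, background_rate = 0.05,
                        confound = NULL, seed = 1L) {
  stopifnot(all(n_per_class >= 1), !is.null(names(n_per_class)),
            signal_penetrance >= 0, signal_penetrance <= 1,
            background_rate >= 0, background_rate <= 1)
  classes <- sort(names(n_per_class))
  n_conf <- if (is.null(confound)) 0L else as.integer(confound$n_features)
  if (n_features < length(classes) * signal_per_class + n_conf)
    stop("n_features too small for the requested signal/confounder blocks")
  fids <- sprintf("F%06d", seq_len(n_features))
  signal_sets <- stats::setNames(lapply(seq_along(classes), function(j) {
    fids[(j - 1) * signal_per_class + seq_len(signal_per_class)]
  }), classes)
  conf_ids <- if (n_conf > 0)
    fids[length(classes) * signal_per_class + seq_len(n_conf)]
  else character(0)
  if (!is.null(confound) && !confound$class %in% classes)
    stop("confound$class not among the cohort classes")
  labels <- rep(classes, times = n_per_class[classes])
  n <- length(labels)
  sids <- sprintf("S%04d", seq_len(n))
  dataset <- paste0("DS_", labels)
  if (!is.null(confound)) dataset[labels == confound$class] <- confound$dataset_id
  X <- with_local_seed(seed, {
    v <- matrix(as.integer(stats::runif(n_features * n) < background_rate),
                n_features, n, dimnames = list(fids, sids))
    for (cl in classes) {
      cols <- labels == cl
      sig <- signal_sets[[cl]]
      v[sig, cols] <- matrix(
        as.integer(stats::runif(length(sig) * sum(cols)) < signal_penetrance),
        length(sig), sum(cols))
    }
    if (n_conf > 0) {
      v[conf_ids, ] <- 0L
      v[conf_ids, dataset == confound$dataset_id] <- 1L
    }
    v
  })
  pheno <- phenotype_table(data.frame(sample_id = sids, label = labels,
                                      dataset_id = dataset,
                                      stringsAsFactors = FALSE))
  truth <- list(class_signal_features = signal_sets,
                confounder_features = conf_ids,
                generator_params = list(n_per_class = as.list(n_per_class),
                                        n_features = n_features,
                                        signal_per_class = signal_per_class,
                                        signal_penetrance = signal_penetrance,
                                        background_rate = background_rate,
                                        confound = confound, seed = seed))
  list(X = feature_matrix(X), pheno = pheno, truth = truth)
}
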