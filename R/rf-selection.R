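#' Configuration for the permutation-null random-forest selection
#'
#' Pins every tunable of the selection procedure so a fixed seed yields an
#' identical result, including fold assignments and label permutations.
#' Defaults follow the screening design: 6-fold cross-validation, 1000
#' trees per forest, 5 repeats for the observed importances, and
#' 100/250/500-model permutation nulls evaluated side by side. Forest
#' hyperparameters beyond tree count (square-root feature subsampling,
#' unlimited depth) follow common classification defaults and are fixed
#' here for reproducibility. Feature importance is the impurity (Gini)
#' decrease, normalised within each fitted forest to sum to one.
#'
#' @param n_folds Cross-validation folds (default 6).
#' @param n_trees Trees per forest (default 1000).
#' @param n_repeats Repeats of the observed cross-validated run (default 5).
#' @param n_permutations Permutation-null sizes; all are reported
#'   (default `c(100, 250, 500)`). Smaller sizes are prefix subsets of the
#'   largest, so nulls are computed once.
#' @param alpha Selection threshold on the empirical p-value (default 0.01;
#'   0.05 is the lenient alternative).
#' @param stratified Stratify folds by class (default `TRUE`); with ~19
#'   samples and an 8/11 split, unstratified folds can produce single-class
#'   training sets.
#' @param seed Integer seed.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(n_folds = 6, n_trees = 1000, n_repeats = 5,
                             n_permutations = c(100, 250, 500),
                             alpha = 0.01, stratified = TRUE, seed = 1L) {
  counts <- c(n_folds = n_folds, n_trees = n_trees, n_repeats = n_repeats,
              n_permutations = n_permutations)
  if (any(counts < 1)) abort("All counts must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(list(n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees),
                 n_repeats = as.integer(n_repeats),
                 n_permutations = sort(as.integer(n_permutations)),
                 alpha = alpha, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Align an accession-mean feature table (wide tibble, matrix or
# feature_table) with a label table; returns list(x = matrix, y = factor).
align_features_labels <- function(features, labels) {
  if (inherits(features, "feature_table")) features <- features$wide
  if (is.matrix(features)) {
    features <- as_tibble(features, rownames = "accession")
  }
  if (!"accession" %in% names(features)) {
    abort("`features` must carry an `accession` column (or row names).")
  }
  if (!all(c("accession", "class") %in% names(labels))) {
    abort("`labels` needs columns `accession` and `class`.")
  }
  labels <- as_tibble(labels) %>% distinct(.data$accession, .data$class)
  merged <- dplyr::inner_join(as_tibble(features), labels, by = "accession")
  if (nrow(merged) < nrow(features)) {
    warn("Dropping accessions without a phenotype label.")
  }
  y <- factor(merged$class)
  if (nlevels(y) != 2) abort("Need exactly two phenotype classes.")
  if (min(table(y)) < 2) abort("Need at least two accessions per class.")
  x <- as.matrix(merged[, setdiff(names(merged), c("accession", "class")),
                        drop = FALSE])
  if (ncol(x) < 1) abort("No feature columns found.")
  storage.mode(x) <- "double"
  rownames(x) <- merged$accession
  list(x = x, y = y)
}

# Stratified (or plain) fold assignment; returns an integer vector of fold
# ids. Redraws (with a message) in the pathological case where a training
# set would lose a class entirely.
draw_folds <- function(y, n_folds, stratified) {
  for (attempt in 1:100) {
    fold <- integer(length(y))
    if (stratified) {
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold[idx] <- rep_len(sample(n_folds), length(idx))
      }
    } else {
      fold <- rep_len(sample(n_folds), length(y))[sample(length(y))]
    }
    ok <- all(vapply(seq_len(n_folds), function(k) {
      train <- y[fold != k]
      length(unique(train)) == nlevels(y) && any(fold == k)
    }, logical(1)))
    if (ok) return(fold)
    inform("Fold draw left a training set single-class; redrawing.")
  }
  abort("Could not draw usable cross-validation folds.")
}

# One full cross-validated pass: per fold, fit a forest on the training
# part, record its normalised impurity importances and test-fold accuracy.
cv_pass <- function(x, y, config, fold_seed, forest_seeds) {
  set.seed(fold_seed)
  fold <- draw_folds(y, config$n_folds, config$stratified)
  p <- ncol(x)
  imp <- matrix(0, config$n_folds, p)
  acc <- numeric(config$n_folds)
  d <- data.frame(.class = y, x, check.names = FALSE)
  for (k in seq_len(config$n_folds)) {
    rf <- ranger::ranger(
      dependent.variable.name = ".class",
      data = d[fold != k, , drop = FALSE],
      num.trees = config$n_trees,
      importance = "impurity",
      seed = forest_seeds[k],
      num.threads = 1
    )
    raw <- rf$variable.importance
    tot <- sum(raw)
    imp[k, ] <- if (tot > 0) raw / tot else 0
    pred <- predict(rf, data = d[fold == k, , drop = FALSE],
                    num.threads = 1)$predictions
    acc[k] <- mean(pred == y[fold == k])
  }
  list(importance = colMeans(imp), fold_accuracy = acc)
}

#' Repeated cross-validated random-forest importances
#'
#' Step one of the selection procedure: the classifier is run
#' `n_repeats` times, each with a fresh stratified `n_folds` split; in
#' every fold a `n_trees`-tree forest is fitted on the training part, its
#' impurity importances (normalised to sum to one) and test-fold accuracy
#' recorded. Importances are averaged over folds within a repeat, then
#' over repeats (the SD is taken over repeat means); accuracy is averaged
#' over all folds of all repeats.
#'
#' @param features Accession-mean features: a `feature_table`, a wide
#'   tibble with an `accession` column, or a matrix with accession row
#'   names.
#' @param labels A data frame with `accession` and a two-level `class`
#'   column (e.g. from [classify_whitefly()] / [classify_thrips()]).
#' @param config A [selection_config()].
#' @return A list with `importance` (tibble: `feature`, `mean_importance`,
#'   `sd_importance`), `accuracy` (mean over folds x repeats),
#'   `fold_accuracy` (matrix repeats x folds).
#' @export
run_rf_repeated <- function(features, labels, config = selection_config()) {
  al <- align_features_labels(features, labels)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             config$n_repeats * (config$n_folds + 1L)),
                  nrow = config$n_repeats, byrow = TRUE)
  rep_imp <- matrix(0, config$n_repeats, ncol(al$x))
  fold_acc <- matrix(0, config$n_repeats, config$n_folds)
  for (r in seq_len(config$n_repeats)) {
    pass <- cv_pass(al$x, al$y, config,
                    fold_seed = seeds[r, 1],
                    forest_seeds = seeds[r, -1])
    rep_imp[r, ] <- pass$importance
    fold_acc[r, ] <- pass$fold_accuracy
  }
  list(
    importance = tibble(
      feature = colnames(al$x),
      mean_importance = colMeans(rep_imp),
      sd_importance = apply(rep_imp, 2, sd)
    ),
    accuracy = mean(fold_acc),
    fold_accuracy = fold_acc
  )
}

#' Label-permutation null importance distributions
#'
#' Step two of the selection procedure: the class labels are permuted
#' uniformly at random and the full cross-validated importance computation
#' is re-run once per permuted model (a single repeat per null model).
#' The null is computed once at the largest requested size; smaller sizes
#' are its prefixes, so the 100-model null is a deterministic subsample of
#' the 500-model null under the same seed.
#'
#' @inheritParams run_rf_repeated
#' @return A matrix (`max(n_permutations)` rows x features) of null
#'   cross-validation-averaged importances.
#' @export
permutation_null <- function(features, labels, config = selection_config()) {
  al <- align_features_labels(features, labels)
  n_null <- max(config$n_permutations)
  set.seed(config$seed + 1L)
  # row-wise fill: replicate b always consumes the same seed block, so the
  # first 100 null models of a 500-model run equal a 100-model run
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_null * (config$n_folds + 2L)),
                  nrow = n_null, byrow = TRUE)
  out <- matrix(0, n_null, ncol(al$x),
                dimnames = list(NULL, colnames(al$x)))
  for (b in seq_len(n_null)) {
    set.seed(seeds[b, 1])
    y_perm <- sample(al$y)
    pass <- cv_pass(al$x, y_perm, config,
                    fold_seed = seeds[b, 2],
                    forest_seeds = seeds[b, -(1:2)])
    out[b, ] <- pass$importance
  }
  out
}

#' Empirical per-feature p-values against permutation nulls
#'
#' Step three: each feature's observed mean importance is compared with its
#' permutation-null distribution. The add-one empirical estimator is used,
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`, which cannot return
#' zero; an observed importance exceeding all 100 null draws gives
#' p = 1/101 < 0.01. A feature is selected when its p-value at the largest
#' permutation count is below `alpha`.
#'
#' @param observed Tibble from `run_rf_repeated()$importance` (columns
#'   `feature`, `mean_importance`, `sd_importance`).
#' @param nulls Null importance matrix from [permutation_null()].
#' @param config A [selection_config()].
#' @return A tibble with one row per feature: `feature`,
#'   `mean_importance`, `sd_importance`, one `p_<n>` column per permutation
#'   count, and `selected`.
#' @export
feature_pvalues <- function(observed, nulls, config = selection_config()) {
  if (!all(c("feature", "mean_importance") %in% names(observed))) {
    abort("`observed` needs columns `feature` and `mean_importance`.")
  }
  if (any(is.na(observed$mean_importance))) {
    abort("Observed importance missing for some features.")
  }
  missing_feat <- setdiff(observed$feature, colnames(nulls))
  if (length(missing_feat)) {
    abort(paste0("Null distributions missing for: ",
                 paste(utils::head(missing_feat, 3), collapse = ", ")))
  }
  n_avail <- nrow(nulls)
  sizes <- config$n_permutations[config$n_permutations <= n_avail]
  if (!length(sizes)) abort("Fewer null replicates than any requested size.")
  nulls <- nulls[, observed$feature, drop = FALSE]
  out <- observed
  for (n in sizes) {
    ge <- colSums(nulls[seq_len(n), , drop = FALSE] >=
                    matrix(observed$mean_importance, n,
                           nrow(observed), byrow = TRUE))
    out[[paste0("p_", n)]] <- unname(1 + ge) / (1 + n)
  }
  out$selected <- out[[paste0("p_", max(sizes))]] < config$alpha
  out
}

#' Permutation-null random-forest metabolite selection
#'
#' The full selection procedure: (1) repeated cross-validated forests give
#' each metabolite a mean importance and each model an accuracy
#' ([run_rf_repeated()]); (2) label permutations give per-metabolite null
#' importance distributions ([permutation_null()]); (3) empirical p-values
#' flag metabolites whose importance exceeds its own null
#' ([feature_pvalues()]).
#'
#' @inheritParams run_rf_repeated
#' @return An object of class `rf_selection`; `tidy()` returns the
#'   per-feature table (importance, p-values per null size, `selected`),
#'   `glance()` a one-row model summary, and `autoplot()` an importance
#'   plot against the null.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_feature_table(sim_config(seed = 1))
#' labels <- sim$truth$accessions
#' cfg <- selection_config(n_trees = 50, n_permutations = 20, seed = 1)
#' sel <- rf_select(sim$table, labels, cfg)
#' dplyr::filter(tidy(sel), selected)
#' }
rf_select <- function(features, labels, config = selection_config()) {
  observed <- run_rf_repeated(features, labels, config)
  nulls <- permutation_null(features, labels, config)
  result <- feature_pvalues(observed$importance, nulls, config)
  structure(list(result = result,
                 accuracy = observed$accuracy,
                 fold_accuracy = observed$fold_accuracy,
                 nulls = nulls,
                 config = config),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat("<rf_selection> ", nrow(x$result), " features; CV accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy), "\n", sep = "")
  sel <- x$result$feature[x$result$selected]
  cat("  selected at alpha ", x$config$alpha, ": ",
      if (length(sel)) paste(sel, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' @rdname rf_select
#' @param x An `rf_selection`.
#' @param ... Unused.
#' @export
tidy.rf_selection <- function(x, ...) x$result

#' @rdname rf_select
#' @export
glance.rf_selection <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         n_features = nrow(x$result),
         n_selected = sum(x$result$selected),
         n_folds = x$config$n_folds,
         n_trees = x$config$n_trees,
         n_repeats = x$config$n_repeats,
         n_permutations = max(x$config$n_permutations),
         alpha = x$config$alpha,
         seed = x$config$seed)
}
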