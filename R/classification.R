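#' Feature subsets used for classification and ordination
#'
#' `svm_features()` returns the five features used by the SVM classifier;
#' `pca_features()` the ten features used for ordination.
#'
#' @return Character vector of column names of [features_table()].
#' @export
svm_features <- function() {
  c("n_edges", "frac_alpha_B", "frac_B", "kappa_2", "kappa_5")
}

#' @rdname svm_features
#' @export
pca_features <- function() {
  c("n_nodes", "frac_B", "n_edges", "frac_alpha_B", "kappa_2", "kappa_5",
    "homogeneity", "clustering_C", "avg_degree", "mean_pairwise_dist_um")
}

#' Assemble a numeric feature matrix and aligned label vector
#'
#' @param features data.frame as produced by [features_table()].
#' @param labels class labels aligned with the rows of `features` (one of
#'   [infiltrate_classes()]), or `NULL` for unlabeled data.
#' @param feature_subset columns to keep (default [svm_features()]).
#' @return List with `x` (dense numeric matrix, rownames = infiltrate ids)
#'   and `y` (factor over [infiltrate_classes()], or `NULL`).
#' @export
assemble_feature_matrix <- function(features, labels = NULL,
                                    feature_subset = svm_features()) {
  missing_f <- setdiff(feature_subset, names(features))
  if (length(missing_f) > 0) {
    lg_stop(sprintf("unknown feature(s): %s", paste(missing_f, collapse = ", ")),
            "lg_bad_input")
  }
  x <- as.matrix(features[, feature_subset, drop = FALSE])
  if (!is.null(features$infiltrate_id)) rownames(x) <- features$infiltrate_id
  bad <- which(!stats::complete.cases(x))
  if (length(bad) > 0) {
    lg_stop(sprintf("incomplete record: missing feature value in row(s) %s",
                    paste(utils::head(bad, 5), collapse = ", ")), "lg_bad_input")
  }
  y <- NULL
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) {
      lg_stop("incomplete record: labels not aligned with feature rows", "lg_bad_input")
    }
    if (anyNA(labels)) lg_stop("incomplete record: missing label", "lg_bad_input")
    y <- factor(as.character(labels), levels = infiltrate_classes())
    if (anyNA(y)) {
      lg_stop(sprintf("unknown class label: %s",
                      paste(unique(setdiff(labels, infiltrate_classes())),
                            collapse = ", ")), "lg_bad_input")
    }
  }
  list(x = x, y = y)
}

#' Confusion-matrix derived metrics
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative predictive
#' value, accuracy and F1 from raw counts. Any ratio with a zero denominator
#' is undefined and reported as `NA` (never silently 0).
#'
#' @param TP,TN,FP,FN non-negative integer counts, not all zero.
#' @return Object of class `confusion_metrics`: list of the four counts and
#'   the six derived metrics.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    lg_stop("confusion counts must be non-negative integers", "lg_bad_input")
  }
  if (sum(counts) == 0) lg_stop("empty confusion: all counts zero", "lg_bad_input")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(TP = TP, TN = TN, FP = FP, FN = FN,
         TPR = ratio(TP, TP + FN),
         TNR = ratio(TN, TN + FP),
         PPV = ratio(TP, TP + FP),
         NPV = ratio(TN, TN + FN),
         ACC = (TP + TN) / sum(counts),
         F1 = ratio(2 * TP, 2 * TP + FP + FN)),
    class = "confusion_metrics"
  )
}

metric_names <- function() c("TPR", "TNR", "PPV", "NPV", "ACC", "F1")

#' Macro-average of per-class metric rows
#'
#' Unweighted column mean over classes; this aggregation reproduces the
#' conventional "overall" row of a per-class performance table.
#'
#' @param per_class data.frame of per-class metric values (columns TPR, TNR,
#'   PPV, NPV, ACC, F1; extra columns ignored).
#' @param na.rm drop undefined per-class values before averaging.
#' @return Named numeric vector of the six macro-averaged metrics.
#' @export
macro_average <- function(per_class, na.rm = TRUE) {
  cols <- intersect(metric_names(), names(per_class))
  vapply(cols, function(cl) mean(per_class[[cl]], na.rm = na.rm), 0)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Radial-kernel SVM under stratified k-fold cross-validation
#'
#' Folds are stratified by class. Within each fold, features are z-scored
#' using training-fold statistics only, a radial-kernel SVM (cost 1, kernel
#' width `1/p` on the standardized features, one-vs-one voting for the
#' multiclass decision) is trained, and a one-vs-rest confusion matrix is
#' computed per class on the held-out fold. Metrics are evaluated per fold
#' and then averaged over folds; the overall row is the unweighted
#' macro-average over classes.
#'
#' @param x numeric feature matrix.
#' @param y factor of class labels (each class needs at least `k_folds`
#'   members).
#' @param k_folds number of folds (default 5).
#' @param seed seed controlling the fold assignment.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses `1/ncol(x)`.
#' @param tune if `TRUE`, an inner grid search over cost `{0.1, 1, 10}` and
#'   gamma `{0.5, 1, 2}/p` is run on each training fold (off by default).
#' @return Object of class `cv_result`: list with `per_class` (data.frame of
#'   fold-averaged metrics per class), `overall` (macro-average across
#'   classes), `multiclass_accuracy` (plain fraction of correct predictions,
#'   fold-averaged; chance level `1/nlevels(y)`), `fold` (the assignment),
#'   `predictions`, `k_folds` and `seed`.
#' @export
cross_validate_svm <- function(x, y, k_folds = 5, seed = 1,
                               cost = 1, gamma = NULL, tune = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(factor(y))
  support <- table(y)
  if (any(support < k_folds)) {
    lg_stop(sprintf("insufficient class support: %s has %d member(s), need >= %d",
                    names(support)[which.min(support)], min(support), k_folds),
            "lg_insufficient_support")
  }
  gamma <- gamma %||% (1 / ncol(x))
  fold <- stratified_folds(y, k_folds, seed)
  classes <- levels(y)
  fold_metrics <- array(NA_real_, dim = c(k_folds, length(classes),
                                          length(metric_names())),
                        dimnames = list(NULL, classes, metric_names()))
  predictions <- factor(rep(NA_character_, length(y)), levels = classes)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sd <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    xs_tr <- scale(x[tr, , drop = FALSE], center = mu, scale = sd)
    xs_te <- scale(x[!tr, , drop = FALSE], center = mu, scale = sd)
    pars <- list(cost = cost, gamma = gamma)
    if (tune) {
      tuned <- e1071::tune.svm(xs_tr, y[tr], kernel = "radial",
                               cost = c(0.1, 1, 10),
                               gamma = c(0.5, 1, 2) / ncol(x))
      pars <- tuned$best.parameters
    }
    fit <- e1071::svm(xs_tr, y[tr], kernel = "radial",
                      cost = pars$cost, gamma = pars$gamma, scale = FALSE)
    pred <- stats::predict(fit, xs_te)
    predictions[!tr] <- pred
    truth <- y[!tr]
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      m <- confusion_metrics(TP = sum(pred == cl & truth == cl),
                             TN = sum(pred != cl & truth != cl),
                             FP = sum(pred == cl & truth != cl),
                             FN = sum(pred != cl & truth == cl))
      fold_metrics[f, ci, ] <- unlist(m[metric_names()])
    }
  }
  per_class <- as.data.frame(apply(fold_metrics, c(2, 3), mean, na.rm = TRUE))
  per_class <- cbind(class = classes, per_class)
  rownames(per_class) <- NULL
  fold_acc <- vapply(seq_len(k_folds), function(f) {
    mean(predictions[fold == f] == y[fold == f])
  }, 0)
  structure(
    list(per_class = per_class, overall = macro_average(per_class),
         multiclass_accuracy = mean(fold_acc),
         fold = fold, predictions = predictions,
         k_folds = k_folds, seed = seed,
         cost = cost, gamma = gamma),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (seed %d)\n", x$k_folds, x$seed))
  tab <- x$per_class
  tab[metric_names()] <- round(tab[metric_names()], digits)
  print(tab, row.names = FALSE)
  cat("overall:", paste(sprintf("%s=%.3f", names(x$overall), x$overall),
                        collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of the feature matrix
#'
#' Features are z-scored; constant features are dropped with a warning.
#'
#' @param x numeric feature matrix (>= 2 rows and >= 2 non-constant columns).
#' @return List with `proportions` (explained-variance proportions, sorted
#'   descending and summing to 1), `scores` (projected coordinates) and
#'   `rotation` (loadings).
#' @export
pca_projection <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) lg_stop("fewer than 2 non-constant features", "lg_bad_input")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  list(proportions = p$sdev^2 / sum(p$sdev^2),
       scores = p$x, rotation = p$rotation)
}

#' Nonparametric per-feature comparisons across organization classes
#'
#' For each feature: a Kruskal--Wallis test across all classes, and per class
#' a Mann--Whitney U test of that class against all remaining classes pooled.
#' Raw p-values are reported with a significance flag at `alpha`; no
#' multiple-testing correction is applied. A feature with all values tied is
#' degenerate: its p-value is reported as 1 with a flag.
#'
#' @param features data.frame of feature columns (e.g. [features_table()]).
#' @param labels class labels aligned with rows.
#' @param feature_subset which columns to test (default: all numeric).
#' @param alpha significance level (default 0.001).
#' @return data.frame with columns `feature`, `test` (`"kruskal_wallis"` or
#'   `"mann_whitney"`), `class` (`NA` for the Kruskal--Wallis rows),
#'   `p_value`, `significant`, `degenerate`.
#' @export
class_feature_tests <- function(features, labels, feature_subset = NULL,
                                alpha = 0.001) {
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2 || any(table(y) < 2)) {
    lg_stop("insufficient class support: need >= 2 classes with >= 2 members each",
            "lg_insufficient_support")
  }
  feature_subset <- feature_subset %||%
    names(features)[vapply(features, is.numeric, TRUE)]
  rows <- list()
  for (f in feature_subset) {
    v <- features[[f]]
    degen <- length(unique(v)) == 1
    kw_p <- if (degen) 1 else stats::kruskal.test(v, y)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, test = "kruskal_wallis", class = NA_character_,
      p_value = kw_p, significant = !degen && kw_p < alpha, degenerate = degen)
    for (cl in levels(y)) {
      in_cl <- y == cl
      d2 <- length(unique(v)) == 1
      p <- if (d2) 1 else
        suppressWarnings(stats::wilcox.test(v[in_cl], v[!in_cl])$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, test = "mann_whitney", class = cl,
        p_value = p, significant = !d2 && p < alpha, degenerate = d2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
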