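#' Fisher scores for attribute prefiltering
#'
#' Univariate filter statistic ranking attributes by between-class scatter
#' over within-class scatter:
#' `F_k = sum_c n_c (mu_ck - mu_k)^2 / (sum_c n_c sigma2_ck + eps_var)`
#' with per-class population variances `sigma2_ck` and a small variance
#' guard `eps_var` so attributes with zero within-class variance score large
#' but finite. Used to prefilter high-dimensional (gene-expression-style)
#' tables to a candidate set before the reduct search.
#'
#' @param data A decision table or data frame with at least two classes.
#' @param decision Decision column name.
#' @param eps_var Variance guard added to the denominator (default `1e-12`).
#' @return A tibble sorted by descending score (ties broken by original
#'   attribute order): `attribute`, `score`, `rank`.
#' @export
fisher_scores <- function(data, decision = NULL, eps_var = 1e-12) {
  ctx <- dt_context(data, decision)
  if (length(ctx$classes) < 2L) {
    stop("Fisher scores need at least two decision classes", call. = FALSE)
  }
  mu <- colMeans(ctx$X)
  between <- numeric(ctx$m)
  within <- numeric(ctx$m)
  for (dj in ctx$classes) {
    nc <- length(dj)
    Xc <- ctx$X[dj, , drop = FALSE]
    muc <- colMeans(Xc)
    between <- between + nc * (muc - mu)^2
    within <- within + nc * colMeans((Xc - rep(muc, each = nc))^2)
  }
  score <- as.numeric(between / (within + eps_var))
  ord <- order(-score, seq_len(ctx$m))
  tibble::tibble(attribute = ctx$attrs[ord], score = score[ord],
                 rank = seq_len(ctx$m))
}

#' Top-l attributes of a Fisher ranking
#'
#' @param ranking A tibble from [fisher_scores()].
#' @param l Number of attributes to keep, `1 <= l <= m`.
#' @return Character vector of the `l` top-ranked attribute names.
#' @export
select_top <- function(ranking, l) {
  stopifnot(is.data.frame(ranking), "attribute" %in% names(ranking))
  m <- nrow(ranking)
  if (l < 1L || l > m) {
    stop("l must lie in 1..", m, " (got ", l, ")", call. = FALSE)
  }
  ranking$attribute[seq_len(l)]
}

#' Attribute reduction rate
#'
#' Fraction of attributes eliminated: `(|C| - |R|) / |C|`.
#'
#' @param total_attributes Number of conditional attributes `|C|` (>= 1).
#' @param reduct_size Number of retained attributes `|R|`.
#' @return A number in `[0, 1]`.
#' @export
reduction_rate <- function(total_attributes, reduct_size) {
  stopifnot(total_attributes >= 1, reduct_size >= 0,
            reduct_size <= total_attributes)
  (total_attributes - reduct_size) / total_attributes
}

#' Recall
#'
#' Per-class recall `TP / (TP + FN)`; `macro_recall()` averages per-class
#' recalls without class-size weighting (every class counts equally, the
#' convention used for multi-class reporting here).
#'
#' @param tp True positive count.
#' @param fn False negative count (`tp + fn >= 1`).
#' @return A number in `[0, 1]`.
#' @export
recall_rate <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn < 1) stop("class has no members (tp + fn == 0)", call. = FALSE)
  tp / (tp + fn)
}

#' @rdname recall_rate
#' @param truth Vector of true class labels.
#' @param predicted Vector of predicted labels, same length.
#' @return `macro_recall()`: a list with `macro` (the unweighted mean) and
#'   `per_class` (a tibble of per-class recalls).
#' @export
macro_recall <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  labs <- unique(truth)
  rec <- vapply(labs, function(l) {
    tp <- sum(truth == l & predicted == l)
    recall_rate(tp, sum(truth == l) - tp)
  }, numeric(1))
  list(macro = mean(rec),
       per_class = tibble::tibble(class = labs, recall = unname(rec)))
}

#' Stratified cross-validation of a selected attribute subset
#'
#' Evaluates how well a reduced attribute subset supports classification.
#' Folds are stratified by class and deterministic given `seed`; each fold
#' is the test set exactly once. Classifiers: `"knn3"` (3-nearest-neighbor,
#' [class::knn()]) or `"linear_svm"` ([e1071::svm()] with a linear kernel).
#' Classes with fewer members than folds are spread as evenly as possible
#' (with a warning), so stratification degrades gracefully.
#'
#' @param data A decision table or data frame.
#' @param attributes Attribute subset used for classification (default all).
#' @param classifier `"knn3"` or `"linear_svm"`.
#' @param folds Number of folds (>= 2, default 10).
#' @param seed Integer seed for the fold assignment (default 0).
#' @param decision Decision column name.
#' @return An object of class `cv_report`: per-fold accuracies, their mean,
#'   macro recall with per-class values, and the configuration. Supports
#'   `tidy()` (per-fold rows) and `glance()` (one summary row).
#' @export
cross_validate <- function(data, attributes = NULL,
                           classifier = c("knn3", "linear_svm"),
                           folds = 10L, seed = 0L, decision = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(folds >= 2L)
  ctx <- dt_context(data, decision)
  B <- resolve_attrs(ctx, attributes)
  if (length(B) == 0L) stop("need at least one attribute to classify on", call. = FALSE)
  if (any(lengths(ctx$classes) < folds)) {
    warning("some classes have fewer members than folds; stratification is partial")
  }
  X <- ctx$X[, B, drop = FALSE]
  y <- factor(ctx$y, levels = names(ctx$classes))

  fold_of <- integer(ctx$n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (dj in ctx$classes) {
    fold_of[sample(dj)] <- rep_len(seq_len(folds), length(dj))
  }

  truth_all <- character(0)
  pred_all <- character(0)
  acc <- numeric(folds)
  n_test <- integer(folds)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    if (length(test) == 0L) {
      acc[f] <- NA_real_
      next
    }
    pred <- if (classifier == "knn3") {
      as.character(class::knn(X[train, , drop = FALSE], X[test, , drop = FALSE],
                              y[train], k = min(3L, length(train))))
    } else {
      fit <- e1071::svm(X[train, , drop = FALSE], y[train],
                        kernel = "linear", scale = FALSE)
      as.character(stats::predict(fit, X[test, , drop = FALSE]))
    }
    truth <- as.character(y[test])
    acc[f] <- mean(pred == truth)
    n_test[f] <- length(test)
    truth_all <- c(truth_all, truth)
    pred_all <- c(pred_all, pred)
  }
  rec <- macro_recall(truth_all, pred_all)
  structure(
    list(folds = tibble::tibble(fold = seq_len(folds), n_test = n_test,
                                accuracy = acc),
         mean_accuracy = mean(acc, na.rm = TRUE),
         recall = rec$macro,
         per_class_recall = rec$per_class,
         classifier = classifier,
         n_folds = folds,
         seed = as.integer(seed),
         attributes = ctx$attrs[B],
         n_attributes_total = ctx$m),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("# Cross-validation: ", x$classifier, ", ", x$n_folds,
      " folds (seed ", x$seed, ") on ", length(x$attributes),
      " attribute(s)\n", sep = "")
  cat("  mean accuracy : ", format(x$mean_accuracy, digits = 4), "\n", sep = "")
  cat("  macro recall  : ", format(x$recall, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier,
    folds = x$n_folds,
    seed = x$seed,
    n_attributes = length(x$attributes),
    mean_accuracy = x$mean_accuracy,
    recall = x$recall,
    reduction_rate = reduction_rate(x$n_attributes_total, length(x$attributes))
  )
}
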