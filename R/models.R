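# Stratified splitting, random-forest classification/regression on
# indicator-OTU features, evaluation, permutation importance and
# repeated-split robustness.

#' Stratified train/test split of sites
#'
#' Samples, within each stratum (e.g. land use), a train fraction of sites
#' without replacement; the per-stratum train count is the fraction times
#' the stratum size rounded to the nearest integer, ties rounding up.
#'
#' @param site_info data frame with a \code{site_id} column and the
#'   stratum column, one row per site; or a named vector of strata.
#' @param stratum_key column name holding the stratum (default
#'   \code{"land_use"}).
#' @param fraction train proportion in (0, 1) (default 0.8).
#' @param seed optional seed.
#' @return object of class \code{"split_spec"}: list with \code{train_ids},
#'   \code{test_ids}, \code{stratum} (named vector), \code{fraction},
#'   \code{seed}.
#' @export
stratified_split <- function(site_info, stratum_key = "land_use",
                             fraction = 0.8, seed = NULL) {
  if (is.data.frame(site_info)) {
    stopifnot("site_id" %in% names(site_info),
              stratum_key %in% names(site_info))
    stratum <- stats::setNames(as.character(site_info[[stratum_key]]),
                               site_info$site_id)
  } else {
    stratum <- site_info
    if (is.null(names(stratum))) stop("site strata must be named by site_id")
  }
  if (anyDuplicated(names(stratum))) stop("duplicated site ids")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  sizes <- table(stratum)
  if (any(sizes < 2))
    stop("stratum with fewer than 2 sites: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  train <- unlist(lapply(names(sizes), function(s) {
    ids <- names(stratum)[stratum == s]
    n_train <- floor(fraction * length(ids) + 0.5)  # nearest, ties up
    n_train <- min(max(n_train, 1L), length(ids) - 1L)
    sample(ids, n_train)
  }), use.names = FALSE)
  structure(list(
    train_ids = sort(train),
    test_ids = sort(setdiff(names(stratum), train)),
    stratum = stratum, fraction = fraction, seed = seed
  ), class = "split_spec")
}

check_disjoint <- function(train_ids, test_ids) {
  leak <- intersect(train_ids, test_ids)
  if (length(leak))
    stop("train/test leakage: ", paste(utils::head(leak, 10), collapse = ", "))
  invisible(TRUE)
}

#' Random-forest classifier on OTU features
#'
#' 500 trees with \code{floor(sqrt(p))} candidate features per split (the
#' conventional classification defaults), via the \pkg{randomForest}
#' package.
#'
#' @param features training site x feature numeric matrix.
#' @param labels per-site class labels (>= 2 classes).
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split (default
#'   \code{floor(sqrt(p))}).
#' @param seed optional seed.
#' @param ... passed to \code{randomForest::randomForest}.
#' @return a fitted \code{randomForest} model.
#' @export
fit_classifier <- function(features, labels, ntree = 500, mtry = NULL,
                           seed = NULL, ...) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  if (!is.null(seed)) set.seed(seed)
  randomForest::randomForest(x = features, y = labels, ntree = ntree,
                             mtry = mtry, ...)
}

#' Random-forest regressor on OTU features
#'
#' 500 trees with \code{max(1, floor(p/3))} candidate features per split
#' (the conventional regression defaults).
#'
#' @param features training site x feature numeric matrix.
#' @param target numeric response with positive variance.
#' @inheritParams fit_classifier
#' @return a fitted \code{randomForest} model.
#' @export
fit_regressor <- function(features, target, ntree = 500, mtry = NULL,
                          seed = NULL, ...) {
  features <- as.matrix(features)
  target <- as.numeric(target)
  if (stats::sd(target) == 0) stop("constant target: nothing to regress")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(features) / 3))
  if (!is.null(seed)) set.seed(seed)
  randomForest::randomForest(x = features, y = target, ntree = ntree,
                             mtry = mtry, ...)
}

#' Evaluate a classifier on held-out sites
#'
#' @param model fitted classifier.
#' @param test_features held-out site x feature matrix.
#' @param test_labels held-out true labels.
#' @return object of class \code{"classification_result"}: list with
#'   \code{confusion} (true x predicted counts over the union of label
#'   sets), \code{accuracy}, \code{per_class_recall} and
#'   \code{predictions}.
#' @export
evaluate_classification <- function(model, test_features, test_labels) {
  pred <- stats::predict(model, as.matrix(test_features))
  levs <- union(levels(factor(test_labels)), levels(factor(pred)))
  unseen <- setdiff(unique(as.character(test_labels)), levels(model$y))
  if (length(unseen))
    warning("test labels unseen in training: ",
            paste(unseen, collapse = ", "))
  truth <- factor(test_labels, levels = levs)
  pred <- factor(as.character(pred), levels = levs)
  confusion <- table(true = truth, predicted = pred)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    per_class_recall = recall,
    predictions = stats::setNames(as.character(pred), rownames(test_features))
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Held-out classification: accuracy %.3f (%d/%d)\n",
              x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a regressor on held-out sites
#'
#' Ordinary least squares of the predicted values (response) on the actual
#' values (explanatory); slope and adjusted \eqn{R^2} near 1 indicate a
#' model that tracks the truth without shrinkage.
#'
#' @param model fitted regressor.
#' @param test_features held-out site x feature matrix.
#' @param test_target held-out true values (>= 3 sites, positive
#'   variance).
#' @return object of class \code{"regression_eval"}: list with
#'   \code{predictions}, \code{slope}, \code{intercept}, \code{r2},
#'   \code{adj_r2} (\eqn{1 - (1 - R^2)(n-1)/(n-2)}) and \code{n}.
#' @export
evaluate_regression <- function(model, test_features, test_target) {
  pred <- as.numeric(stats::predict(model, as.matrix(test_features)))
  out <- ols_eval(pred, as.numeric(test_target))
  out$predictions <- stats::setNames(pred, rownames(test_features))
  structure(out, class = "regression_eval")
}

# OLS of predicted (response) on actual (explanatory)
ols_eval <- function(pred, actual) {
  n <- length(actual)
  if (n < 3) stop("need at least 3 test sites")
  if (stats::sd(actual) == 0) stop("zero variance in actual values")
  fit <- stats::lm(pred ~ actual)
  r2 <- summary(fit)$r.squared
  list(predictions = pred, actual = actual,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n)
}

#' @export
print.regression_eval <- function(x, ...) {
  cat(sprintf("Held-out regression (n = %d): slope %.3f, adj R2 %.3f\n",
              x$n, x$slope, x$adj_r2))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean, over \code{n_repeats} permutations
#' of that feature's values in the evaluation data, of the relative
#' increase in error: \code{(permuted error - baseline error) / baseline
#' error x 100}. Error is mean squared error for regression (so this is
#' the \% increase in MSE) and 1 - accuracy for classification. Computed
#' on explicitly supplied evaluation data (typically the held-out sites),
#' independent of any library-internal importance definition.
#'
#' @param model fitted \code{randomForest} model.
#' @param data evaluation site x feature matrix.
#' @param target evaluation response (numeric or class labels).
#' @param n_repeats permutations per feature (default 5).
#' @param seed optional seed.
#' @param top_k how many top features to flag (default 15).
#' @return object of class \code{"importance_table"}: data frame
#'   (\code{feature}, \code{importance}, \code{rank}, \code{top})
#'   ordered by descending importance, ties broken by feature id.
#' @export
permutation_importance <- function(model, data, target, n_repeats = 5,
                                   seed = NULL, top_k = 15) {
  data <- as.matrix(data)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  regression <- model$type == "regression"
  err <- function(d) {
    p <- stats::predict(model, d)
    if (regression) mean((as.numeric(p) - as.numeric(target))^2)
    else mean(as.character(p) != as.character(target))
  }
  baseline <- err(data)
  if (baseline == 0) baseline <- .Machine$double.eps  # perfect baseline fit
  if (!is.null(seed)) set.seed(seed)
  imp <- vapply(seq_len(ncol(data)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      d <- data
      d[, j] <- d[sample.int(nrow(d)), j]
      (err(d) - baseline) / baseline * 100
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = colnames(data), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Aggregate top-ranked features by phylum
#'
#' @param importance an [permutation_importance()] table (or any data
#'   frame with \code{feature} and \code{top} columns).
#' @param taxonomy data frame with \code{otu_id} and \code{phylum}
#'   columns; features without a taxonomy row count as
#'   \code{"unclassified"}.
#' @return named integer vector of top-feature counts per phylum.
#' @export
aggregate_importance_by_phylum <- function(importance, taxonomy) {
  top <- importance$feature[importance$top]
  phylum <- taxonomy$phylum[match(top, taxonomy$otu_id)]
  phylum[is.na(phylum) | phylum == ""] <- "unclassified"
  sort(table(phylum), decreasing = TRUE)
}

#' Cross-model overlap of top features
#'
#' Counts, over a list of importance tables (one per model), in how many
#' models each top feature appears, and histograms those counts.
#'
#' @param importance_list list of [permutation_importance()] tables.
#' @return list with \code{per_feature} (models sharing each feature) and
#'   \code{histogram} (table over 1..n_models).
#' @export
importance_overlap <- function(importance_list) {
  tops <- lapply(importance_list, function(t) t$feature[t$top])
  counts <- table(unlist(tops))
  list(per_feature = counts, histogram = table(as.integer(counts)))
}

#' Repeated random splits for robustness assessment
#'
#' Reruns a split-fit-evaluate stage under a family of seeds and
#' summarizes the resulting metric distribution; an error in one repeat is
#' recorded, not fatal.
#'
#' @param runner function(seed) returning a named numeric vector of
#'   metrics for that repeat.
#' @param n_repeats number of repeats (>= 2; the reference analysis used
#'   100).
#' @param base_seed repeats use seeds \code{base_seed + 0:(n_repeats-1)}.
#' @return list with \code{metrics} (repeat x metric data frame, NA rows
#'   for failures), \code{summary} (mean, sd, quartiles per metric) and
#'   \code{failures} (error messages by seed).
#' @export
repeated_splits <- function(runner, n_repeats, base_seed = 1) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  seeds <- base_seed + seq_len(n_repeats) - 1
  failures <- list()
  rows <- lapply(seeds, function(s) {
    tryCatch(runner(s), error = function(e) {
      failures[[as.character(s)]] <<- conditionMessage(e)
      NULL
    })
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("every repeat failed; first error: ", failures[[1]])
  metrics <- do.call(rbind, rows[ok])
  metrics <- as.data.frame(metrics)
  metrics$seed <- seeds[ok]
  summ <- do.call(rbind, lapply(setdiff(names(metrics), "seed"), function(mn) {
    v <- metrics[[mn]]
    data.frame(metric = mn, mean = mean(v), sd = stats::sd(v),
               q25 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  list(metrics = metrics, summary = summ, failures = failures)
}
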