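# Probabilistic PCA of soil chemistry (missing values marginalized in the
# E-step) and the guideline-based soil-quality category machinery.

#' Probabilistic PCA by EM, with missing values
#'
#' Fits the latent-variable PCA model \eqn{x = W z + \mu + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2 I)}, by expectation-maximization.
#' Variables are standardized using their observed entries; missing cells
#' are marginalized in the E-step (each site's posterior over z uses only
#' its observed variables), so no imputation step is needed. On complete
#' data the fitted subspace coincides with classical PCA. Components are
#' rotated to the principal-axis basis and ordered by explained variance.
#'
#' @param chem site x variable numeric table; NAs allowed. Every variable
#'   must be observed in at least 2 sites.
#' @param n_components number of latent components (default 2), less than
#'   the number of variables.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the relative change in observed-data
#'   log-likelihood (default 1e-6).
#' @param seed seed for the random initialization (only used when
#'   \code{init = "random"}).
#' @param init \code{"svd"} (default: classical PCA of the mean-imputed
#'   table) or \code{"random"}.
#' @return object of class \code{"ppca_result"}: list with \code{loadings}
#'   (variable x component, principal-axis scaling), \code{scores} (site x
#'   component posterior means), \code{noise_variance}, \code{mu} (on the
#'   standardized scale), \code{center}, \code{scale}, \code{loglik}
#'   (per-iteration trace), \code{iterations_run}, \code{converged} and
#'   \code{fitted} (reconstruction on the original scale, usable for
#'   imputation).
#' @export
ppca_em <- function(chem, n_components = 2, max_iter = 500, tol = 1e-6,
                    seed = NULL, init = c("svd", "random")) {
  init <- match.arg(init)
  x <- as.matrix(chem)
  if (!is.numeric(x)) stop("chem must be numeric")
  n <- nrow(x); p <- ncol(x); q <- as.integer(n_components)
  if (q < 1 || q >= p) stop("n_components must be in [1, n_variables - 1]")
  n_obs_var <- colSums(!is.na(x))
  if (any(n_obs_var == 0))
    stop("variable(s) entirely missing: ",
         paste(colnames(x)[n_obs_var == 0], collapse = ", "))
  if (any(n_obs_var < 2))
    stop("variable(s) observed in fewer than 2 sites: ",
         paste(colnames(x)[n_obs_var < 2], collapse = ", "))
  center <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  obs <- !is.na(xs)
  x0 <- xs; x0[!obs] <- 0

  if (init == "random") {
    if (!is.null(seed)) set.seed(seed)
    w <- matrix(stats::rnorm(p * q, sd = 0.1), p, q)
  } else {
    xi <- xs; xi[!obs] <- 0  # standardized scale: observed mean is 0
    sv <- svd(xi, nu = 0, nv = q)
    w <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(max(n - 1, 1)), q, q)
  }
  mu <- rep(0, p)
  sigma2 <- 1
  ll_trace <- numeric(0)
  converged <- FALSE
  ez <- matrix(0, n, q)
  ezz <- array(0, c(q, q, n))

  loglik <- function(w, mu, sigma2) {
    ll <- 0
    for (i in seq_len(n)) {
      o <- obs[i, ]
      if (!any(o)) next
      wo <- w[o, , drop = FALSE]
      co <- tcrossprod(wo) + diag(sigma2, sum(o))
      r <- xs[i, o] - mu[o]
      ch <- chol(co)
      ll <- ll - 0.5 * (sum(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, r, transpose = TRUE)^2))
    }
    ll
  }

  for (iter in seq_len(max_iter)) {
    # E-step
    for (i in seq_len(n)) {
      o <- obs[i, ]
      wo <- w[o, , drop = FALSE]
      m <- crossprod(wo) + diag(sigma2, q)
      mi <- solve(m)
      ez[i, ] <- mi %*% crossprod(wo, xs[i, o] - mu[o])
      ezz[, , i] <- sigma2 * mi + tcrossprod(ez[i, ])
    }
    # M-step (conditional updates: mu, then W rows, then sigma^2)
    fit0 <- ez %*% t(w)
    mu <- colSums((x0 - fit0) * obs) / colSums(obs)
    for (v in seq_len(p)) {
      s <- obs[, v]
      szz <- apply(ezz[, , s, drop = FALSE], c(1, 2), sum)
      sxz <- crossprod(ez[s, , drop = FALSE], xs[s, v] - mu[v])
      w[v, ] <- solve(szz, sxz)
    }
    res <- 0
    for (v in seq_len(p)) {
      s <- obs[, v]
      szz <- apply(ezz[, , s, drop = FALSE], c(1, 2), sum)
      r <- xs[s, v] - mu[v]
      res <- res + sum(r^2) - 2 * sum(r * (ez[s, , drop = FALSE] %*% w[v, ])) +
        crossprod(w[v, ], szz %*% w[v, ])
    }
    sigma2 <- max(as.numeric(res) / sum(obs), 1e-12)
    ll <- loglik(w, mu, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      rel <- abs(ll - ll_trace[iter - 1]) / max(abs(ll), 1)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("ppca_em did not converge in ", max_iter, " iterations")

  # rotate to principal axes, order by explained variance
  sv <- svd(w)
  loadings <- sv$u %*% diag(sv$d, q, q)
  scores <- ez %*% sv$v
  ord <- order(sv$d, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  for (j in seq_len(q)) {  # deterministic sign: largest loading positive
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(q)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(q)))
  fitted_std <- sweep(scores %*% t(loadings), 2, mu, "+")
  fitted <- sweep(sweep(fitted_std, 2, scl, "*"), 2, center, "+")
  structure(list(
    n_components = q, loadings = loadings, scores = scores,
    noise_variance = sigma2, mu = mu, center = center, scale = scl,
    loglik = ll_trace, iterations_run = length(ll_trace),
    converged = converged, fitted = fitted
  ), class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat(sprintf(
    "Probabilistic PCA: %d components, sigma^2 = %.4g, %d iterations (%s)\n",
    x$n_components, x$noise_variance, x$iterations_run,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

QUALITY_CATEGORIES <- c("very_low", "low", "normal", "high", "very_high")

#' Load a soil-quality thresholds configuration
#'
#' Reads a YAML file defining, per soil variable and context (land use
#' and/or soil type, with a \code{default} fallback), the four breakpoints
#' that bound the five categories very low / low / normal / high / very
#' high, and the optimal category. The file shipped with the package
#' (\code{system.file("extdata", "quality_thresholds.yaml", package =
#' "microsoilq")}) carries illustrative placeholder values only; supply
#' your jurisdiction's guideline values for real assessments.
#'
#' @param path path to the YAML config; default: the shipped example.
#' @return object of class \code{"quality_thresholds"}.
#' @export
load_quality_thresholds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "quality_thresholds.yaml",
                        package = "microsoilq")
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$categories, as.list(QUALITY_CATEGORIES)) &&
      !identical(unlist(cfg$categories), QUALITY_CATEGORIES))
    stop("thresholds config must declare the 5 categories: ",
         paste(QUALITY_CATEGORIES, collapse = ", "))
  for (v in names(cfg$variables)) {
    var <- cfg$variables[[v]]
    if (is.null(var$optimal)) cfg$variables[[v]]$optimal <- "normal"
    else if (!var$optimal %in% QUALITY_CATEGORIES)
      stop("variable ", v, ": unknown optimal category '", var$optimal, "'")
    if (is.null(var$contexts$default))
      stop("variable ", v, ": a 'default' context is required")
    for (ctx in names(var$contexts)) {
      b <- as.numeric(unlist(var$contexts[[ctx]]))
      if (length(b) != 4 || any(diff(b) <= 0))
        stop("variable ", v, ", context ", ctx,
             ": need 4 strictly increasing breakpoints")
      cfg$variables[[v]]$contexts[[ctx]] <- b
    }
  }
  structure(cfg, class = "quality_thresholds")
}

threshold_breaks <- function(thresholds, variable, context = "default") {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  var <- thresholds$variables[[variable]]
  if (is.null(var)) stop("unknown variable '", variable, "' in thresholds")
  b <- var$contexts[[context]]
  if (is.null(b)) b <- var$contexts$default
  b
}

#' Assign a value to a soil-quality category
#'
#' Intervals are lower-closed / upper-open: a value exactly on a
#' breakpoint belongs to the higher category.
#'
#' @param value numeric value(s) of the variable.
#' @param variable variable name as declared in the thresholds config.
#' @param context context key (e.g. a land use); falls back to
#'   \code{"default"} when absent from the config.
#' @param thresholds a [load_quality_thresholds()] result.
#' @return ordered factor over very_low < low < normal < high < very_high.
#' @export
assign_category <- function(value, variable, context = "default",
                            thresholds = load_quality_thresholds()) {
  b <- threshold_breaks(thresholds, variable, context)
  idx <- findInterval(value, b) + 1L
  factor(QUALITY_CATEGORIES[idx], levels = QUALITY_CATEGORIES, ordered = TRUE)
}

category_deviation <- function(category, variable, thresholds) {
  opt <- thresholds$variables[[variable]]$optimal
  match(as.character(category), QUALITY_CATEGORIES) -
    match(opt, QUALITY_CATEGORIES)
}

#' Compare a predicted quality category with the true one
#'
#' Outcomes are defined by the signed deviation of each category from the
#' variable's optimal category: identical categories are \code{correct};
#' equal-magnitude deviations on opposite sides of the optimum are
#' \code{opposite}; a prediction strictly closer to the optimum than the
#' truth is \code{better}; anything else is \code{worse}.
#'
#' @param true_cat,pred_cat categories (strings or factors over the five
#'   levels).
#' @param variable variable name (determines the optimal category).
#' @param thresholds a [load_quality_thresholds()] result.
#' @return character vector over \code{correct}, \code{better},
#'   \code{worse}, \code{opposite}.
#' @export
compare_categories <- function(true_cat, pred_cat, variable,
                               thresholds = load_quality_thresholds()) {
  dt <- category_deviation(true_cat, variable, thresholds)
  dp <- category_deviation(pred_cat, variable, thresholds)
  out <- rep("worse", length(dt))
  out[dt != 0 & dp == -dt] <- "opposite"
  out[abs(dp) < abs(dt)] <- "better"
  out[dp == dt] <- "correct"
  out
}

#' Score predicted against true soil-variable values
#'
#' Converts both value sets to quality categories and tabulates the
#' correct / better / worse / opposite outcome of every (site, variable)
#' pair, with per-variable outcome proportions.
#'
#' @param true_values,predicted_values site x variable numeric tables with
#'   matching dimensions.
#' @param variables variable names (default: column names).
#' @param contexts per-site context keys, recycled (default
#'   \code{"default"}).
#' @param thresholds a [load_quality_thresholds()] result.
#' @return object of class \code{"quality_assessment"}: list with
#'   \code{table} (long per-site data frame) and \code{summary}
#'   (per-variable outcome proportions, rows summing to 1).
#' @export
score_table <- function(true_values, predicted_values,
                        variables = colnames(true_values),
                        contexts = "default",
                        thresholds = load_quality_thresholds()) {
  tv <- as.matrix(true_values); pv <- as.matrix(predicted_values)
  if (!identical(dim(tv), dim(pv)))
    stop("true and predicted tables must have the same dimensions")
  colnames(tv) <- colnames(pv) <- variables
  n <- nrow(tv)
  contexts <- rep_len(contexts, n)
  site_ids <- rownames(tv)
  if (is.null(site_ids)) site_ids <- as.character(seq_len(n))
  rows <- lapply(variables, function(v) {
    tc <- mapply(function(val, ctx)
      as.character(assign_category(val, v, ctx, thresholds)), tv[, v], contexts)
    pc <- mapply(function(val, ctx)
      as.character(assign_category(val, v, ctx, thresholds)), pv[, v], contexts)
    data.frame(site_id = site_ids, variable = v,
               true_value = tv[, v], predicted_value = pv[, v],
               true_category = tc, predicted_category = pc,
               outcome = compare_categories(tc, pc, v, thresholds),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  outcome_levels <- c("correct", "better", "worse", "opposite")
  summ <- do.call(rbind, lapply(variables, function(v) {
    oc <- factor(tab$outcome[tab$variable == v], levels = outcome_levels)
    props <- as.numeric(table(oc)) / length(oc)
    data.frame(variable = v, t(stats::setNames(props, outcome_levels)))
  }))
  structure(list(table = tab, summary = summ), class = "quality_assessment")
}

#' @export
print.quality_assessment <- function(x, ...) {
  cat("Soil-quality category assessment\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
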