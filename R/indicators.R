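# Specificity-fidelity indicator statistics and threshold selection of
# model-input OTUs.

#' Specificity and fidelity scores per (OTU, cluster)
#'
#' For OTU k and cluster g, specificity
#' \eqn{A_{kg} = \bar x_{kg} / \sum_h \bar x_{kh}} is the group-size
#' corrected share of the OTU's mean abundance concentrated in g (so A
#' sums to 1 over clusters), and fidelity \eqn{B_{kg}} is the fraction of
#' g's sites in which the OTU occurs. With
#' \code{specificity = "presence"}, A is computed from occurrence
#' frequencies instead of mean abundances. OTUs absent from every site get
#' A = 0 everywhere and are flagged.
#'
#' @param table site x OTU abundance matrix.
#' @param solution a \code{cluster_solution} with \code{k >= 2} covering
#'   the table's sites.
#' @param specificity \code{"abundance"} (default) or \code{"presence"}.
#' @return object of class \code{"indicator_scores"}: list with
#'   \code{scores} (long data frame: otu_id, cluster, A, B),
#'   \code{otu_summary} (otu_id, best_cluster, A_best, B_best,
#'   indval_max), \code{flagged} (all-zero OTU ids) and matrices \code{A},
#'   \code{B}.
#' @export
indicator_scores <- function(table, solution,
                             specificity = c("abundance", "presence")) {
  specificity <- match.arg(specificity)
  m <- as_otu_matrix(table)
  if (!inherits(solution, "cluster_solution"))
    stop("solution must be a cluster_solution")
  if (solution$k < 2) stop("indicator scores require k >= 2 clusters")
  labels <- solution$labels
  if (!is.null(names(labels))) {
    if (!all(rownames(m) %in% names(labels)))
      stop("cluster solution does not cover all sites in the table")
    labels <- labels[rownames(m)]
  }
  if (length(labels) != nrow(m))
    stop("cluster solution does not align with the table")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("fewer than 2 non-empty clusters")
  basis <- if (specificity == "abundance") m else (m > 0) * 1
  group_mean <- do.call(rbind, lapply(clusters, function(g)
    colMeans(basis[labels == g, , drop = FALSE])))
  pres <- do.call(rbind, lapply(clusters, function(g)
    colMeans(m[labels == g, , drop = FALSE] > 0)))
  tot <- colSums(group_mean)
  flagged <- colnames(m)[colSums(m) == 0]
  A <- sweep(group_mean, 2, ifelse(tot > 0, tot, 1), "/")
  A[, tot == 0] <- 0
  dimnames(A) <- dimnames(pres) <- list(clusters, colnames(m))
  indval <- A * pres
  best <- apply(indval, 2, which.max)
  otu_summary <- data.frame(
    otu_id = colnames(m),
    best_cluster = clusters[best],
    A_best = A[cbind(best, seq_len(ncol(m)))],
    B_best = pres[cbind(best, seq_len(ncol(m)))],
    indval_max = indval[cbind(best, seq_len(ncol(m)))],
    flagged = colnames(m) %in% flagged,
    stringsAsFactors = FALSE
  )
  scores <- data.frame(
    otu_id = rep(colnames(m), each = length(clusters)),
    cluster = rep(clusters, ncol(m)),
    A = as.vector(A), B = as.vector(pres),
    stringsAsFactors = FALSE
  )
  structure(list(scores = scores, otu_summary = otu_summary,
                 flagged = flagged, A = A, B = pres,
                 specificity = specificity),
            class = "indicator_scores")
}

#' @export
print.indicator_scores <- function(x, ...) {
  cat(sprintf("Indicator scores (%s specificity): %d OTUs x %d clusters",
              x$specificity, ncol(x$A), nrow(x$A)))
  if (length(x$flagged)) cat(sprintf(", %d all-zero OTUs flagged",
                                     length(x$flagged)))
  cat("\n")
  invisible(x)
}

#' Select indicator OTUs by specificity and fidelity thresholds
#'
#' An OTU is selected if some cluster gives it specificity strictly above
#' \code{a_min} and fidelity strictly above \code{b_min} (strict, matching
#' the "> threshold" screening convention). All-zero OTUs are never
#' selected.
#'
#' @param scores an [indicator_scores()] result.
#' @param a_min specificity threshold in \code{[0, 1]} (default 0.4).
#' @param b_min fidelity threshold in \code{[0, 1]} (default 0.4).
#' @return character vector of OTU ids, ordered by descending maximum
#'   A x B, ties broken by OTU id.
#' @export
select_indicator_otus <- function(scores, a_min = 0.4, b_min = 0.4) {
  stopifnot(inherits(scores, "indicator_scores"))
  if (a_min < 0 || a_min > 1 || b_min < 0 || b_min > 1)
    stop("thresholds must lie in [0, 1]")
  pass <- colSums(scores$A > a_min & scores$B > b_min) > 0
  pass[colnames(scores$A) %in% scores$flagged] <- FALSE
  ids <- colnames(scores$A)[pass]
  indval_max <- apply(scores$A * scores$B, 2, max)[ids]
  ids[order(-indval_max, ids)]
}
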