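# Ward clustering of sites, multi-criteria dendrogram cut selection,
# and Dunn's rank-based post-hoc test for characterizing clusters.

#' Ward's minimum-variance clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under the Ward criterion via the
#' Lance-Williams update on squared dissimilarities (the \code{"ward.D2"}
#' convention of \code{stats::hclust}).
#'
#' @param dist a \code{dist} object or symmetric non-negative matrix.
#' @return an \code{hclust} tree.
#' @export
ward_cluster <- function(dist) {
  d <- as_dist_matrix(dist)
  if (nrow(d) < 2) stop("need at least 2 sites")
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the \code{k - 1} highest merges; cluster labels are assigned in
#' order of first site appearance.
#'
#' @param tree an \code{hclust} tree (e.g. from [ward_cluster()]).
#' @param k number of clusters, in \code{[1, n]}.
#' @param source optional tag recording what was clustered
#'   (\code{"community"} or \code{"chemistry"}).
#' @return object of class \code{"cluster_solution"}: list with \code{k},
#'   \code{labels} (named integer vector over sites) and \code{source}.
#' @export
cut_tree <- function(tree, k, source = "community") {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  # relabel in order of first appearance
  labels <- match(raw, unique(raw))
  names(labels) <- names(raw)
  structure(list(k = as.integer(k), labels = labels, source = source),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution (%s): k = %d, sizes: %s\n", x$source, x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Silhouette widths of a clustering
#'
#' \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)} with \eqn{a_i} the mean
#' within-cluster distance and \eqn{b_i} the smallest mean distance to
#' another cluster; members of singleton clusters get 0.
#'
#' @param dist dissimilarities between the clustered sites.
#' @param solution a \code{cluster_solution} with \code{k >= 2}.
#' @return list with per-site \code{widths} and their \code{mean}.
#' @export
silhouette_widths <- function(dist, solution) {
  d <- as_dist_matrix(dist)
  if (solution$k < 2) stop("silhouette requires k >= 2")
  labels <- align_solution(solution, d)
  sil <- cluster::silhouette(labels, dmatrix = d)
  widths <- stats::setNames(sil[, "sil_width"], rownames(d))
  list(widths = widths, mean = mean(widths))
}

align_solution <- function(solution, d) {
  labels <- solution$labels
  if (!is.null(rownames(d)) && !is.null(names(labels))) {
    if (!all(rownames(d) %in% names(labels)))
      stop("cluster solution does not cover all sites in the matrix")
    labels <- labels[rownames(d)]
  }
  if (length(labels) != nrow(d))
    stop("cluster solution does not align with the distance matrix")
  labels
}

#' Dissimilarity / binary matrix correlation of a clustering
#'
#' Pearson correlation, over the strict lower triangle, between the
#' observed dissimilarities and the binary "different cluster" indicator.
#' High values mean the partition separates distant sites.
#'
#' @inheritParams silhouette_widths
#' @return a correlation in \code{[-1, 1]}.
#' @export
matrix_correlation <- function(dist, solution) {
  d <- as_dist_matrix(dist)
  if (solution$k < 2) stop("matrix correlation requires k >= 2")
  labels <- align_solution(solution, d)
  split <- outer(labels, labels, "!=")
  lt <- lower.tri(d)
  b <- as.numeric(split[lt])
  if (stats::sd(b) == 0) stop("binary split matrix is constant")
  stats::cor(d[lt], b)
}

#' Species-fidelity profile of a clustering
#'
#' For each OTU, its indicator value is the maximum over clusters of
#' specificity x fidelity (A x B, see [indicator_scores()]). Returns how
#' many OTUs reach \code{indval_threshold} and the sum of their indicator
#' values; partitions that match real community structure support more,
#' stronger indicators.
#'
#' @param table site x OTU abundance matrix aligned with the solution.
#' @param solution a \code{cluster_solution}.
#' @param indval_threshold screening level in \code{[0, 1]} (default 0.25).
#' @return list with \code{count}, \code{sum} and the per-OTU \code{indval}.
#' @export
fidelity_profile <- function(table, solution, indval_threshold = 0.25) {
  if (indval_threshold < 0 || indval_threshold > 1)
    stop("indval_threshold must be in [0, 1]")
  scores <- indicator_scores(table, solution)
  indval <- scores$otu_summary$indval_max
  names(indval) <- scores$otu_summary$otu_id
  pass <- indval >= indval_threshold
  list(count = sum(pass), sum = sum(indval[pass]), indval = indval)
}

#' Select a dendrogram cutting level by multi-criteria vote
#'
#' Computes, for each candidate k, the mean silhouette width, the
#' dissimilarity/binary matrix correlation and (when an OTU table is
#' supplied) the species-fidelity profile (count and summed indicator
#' value of OTUs passing \code{indval_threshold}). Candidates whose
#' smallest cluster is below \code{min_cluster_size} are excluded so every
#' cluster keeps enough sites for downstream modelling. The chosen k is
#' best on the largest number of criteria; ties go to the candidate with
#' the higher mean silhouette width, then to the smaller k (the binary
#' matrix correlation systematically favours coarse partitions, so a
#' plain smallest-k tie-break would under-split; see the vignette).
#'
#' @param tree \code{hclust} tree of the sites.
#' @param dist the dissimilarities the tree was built from.
#' @param table optional site x OTU table for the fidelity criterion.
#' @param k_range candidate cluster counts (default \code{2:8}).
#' @param min_cluster_size smallest admissible cluster (default 2).
#' @param indval_threshold fidelity screening level (default 0.25).
#' @param source passed to [cut_tree()].
#' @return list with \code{k} (chosen), \code{solution} (the cut at k) and
#'   \code{diagnostics} (per-candidate data frame, with excluded
#'   candidates flagged).
#' @export
select_cut_level <- function(tree, dist, table = NULL, k_range = 2:8,
                             min_cluster_size = 2, indval_threshold = 0.25,
                             source = "community") {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  rows <- lapply(k_range, function(k) {
    sol <- cut_tree(tree, k, source = source)
    sizes <- table(sol$labels)
    row <- data.frame(
      k = k,
      min_size = min(sizes),
      silhouette = silhouette_widths(d, sol)$mean,
      matrix_cor = matrix_correlation(d, sol),
      fidelity_count = NA_real_,
      fidelity_sum = NA_real_
    )
    if (!is.null(table)) {
      fp <- fidelity_profile(table, sol, indval_threshold)
      row$fidelity_count <- fp$count
      row$fidelity_sum <- fp$sum
    }
    row
  })
  diag <- do.call(rbind, rows)
  diag$admissible <- diag$min_size >= min_cluster_size
  if (!any(diag$admissible))
    stop("no candidate k satisfies min_cluster_size = ", min_cluster_size,
         "; try a smaller value")
  criteria <- c("silhouette", "matrix_cor",
                if (!is.null(table)) c("fidelity_count", "fidelity_sum"))
  adm <- diag[diag$admissible, , drop = FALSE]
  votes <- rep(0L, nrow(adm))
  for (cr in criteria)
    votes <- votes + (adm[[cr]] >= max(adm[[cr]]) - 1e-12)
  diag$votes <- NA_integer_
  diag$votes[diag$admissible] <- votes
  # vote ties go to the candidate with the higher mean silhouette (then
  # smaller k): the binary matrix correlation is biased toward coarse
  # partitions, so a plain smallest-k tie-break under-splits
  cand <- which(votes == max(votes))
  cand <- cand[order(-adm$silhouette[cand], adm$k[cand])]
  chosen <- adm$k[cand[1]]
  list(k = chosen, solution = cut_tree(tree, chosen, source = source),
       diagnostics = diag)
}

#' Dunn's test for multiple comparisons among groups
#'
#' Rank-based post-hoc comparison in the Kruskal-Wallis framework with
#' mid-rank tie correction: for groups i, j the statistic is
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with two-sided normal p-values and Bonferroni adjustment over all
#' pairs.
#'
#' @param values numeric observations (e.g. one soil variable per site).
#' @param groups per-observation group labels (e.g. chemistry clusters).
#' @param adjustment \code{"bonferroni"} (default) or \code{"none"}.
#' @return data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{z}, \code{p_value}, \code{p_adjusted}.
#' @export
dunn_test <- function(values, groups, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("every group needs >= 2 observations; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (stats::sd(values) == 0) stop("all values identical: ranks carry no information")
  n_total <- length(values)
  r <- rank(values)  # mid-ranks for ties
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  var_core <- n_total * (n_total + 1) / 12 - tie_term
  pairs <- utils::combn(levels(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(var_core * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  out$p_adjusted <- if (adjustment == "bonferroni")
    pmin(1, out$p_value * nrow(out)) else out$p_value
  out
}
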