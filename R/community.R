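# Community-matrix preprocessing and dissimilarity-based statistics.

as_otu_matrix <- function(table) {
  m <- as.matrix(table)
  if (is.null(rownames(m)))
    stop("OTU table must have row (sample/site) identifiers")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("OTU table has duplicated row or OTU identifiers")
  if (anyNA(m)) stop("OTU table must have no missing entries")
  if (any(m < 0)) stop("OTU table values must be non-negative")
  m
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each row's reads without replacement (hypergeometric) to
#' exactly \code{depth}. Rows whose total is below \code{depth} cannot be
#' rarefied and are dropped with a warning, mirroring the usual practice of
#' retaining only samples that reach the target depth.
#'
#' @param table sample x OTU matrix of non-negative integer counts.
#' @param depth target reads per sample (default 2000).
#' @param seed optional integer seed for the subsampling draw.
#' @return integer OTU table whose rows all sum to \code{depth}.
#' @export
rarefy <- function(table, depth = 2000, seed = NULL) {
  m <- as_otu_matrix(table)
  if (any(m != round(m))) stop("rarefaction needs integer counts")
  if (length(depth) != 1L || depth <= 0) stop("depth must be a positive integer")
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep))
    stop("no rows reach the rarefaction depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " of ", nrow(m), " rows below depth ", depth,
            " dropped: ", paste(utils::head(rownames(m)[!keep], 10),
                                collapse = ", "),
            if (sum(!keep) > 10) ", ..." else "")
  m <- m[keep, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # vegan's advisory warnings (pre-transformed counts, short rows) are
  # covered by the validation above
  out <- suppressWarnings(vegan::rrarefy(m, depth))
  storage.mode(out) <- "integer"
  out
}

#' Average replicate samples into one community per site
#'
#' @param table sample x OTU matrix (typically rarefied counts).
#' @param sample_to_site named character vector mapping sample IDs to site
#'   IDs, or a data frame with columns \code{sample_id} and \code{site_id}.
#' @return site x OTU matrix of arithmetic replicate means, sites in order
#'   of first appearance.
#' @export
average_replicates <- function(table, sample_to_site) {
  m <- as_otu_matrix(table)
  if (is.data.frame(sample_to_site)) {
    stopifnot(all(c("sample_id", "site_id") %in% names(sample_to_site)))
    sample_to_site <- stats::setNames(as.character(sample_to_site$site_id),
                                      sample_to_site$sample_id)
  }
  unmapped <- setdiff(rownames(m), names(sample_to_site))
  if (length(unmapped))
    stop("samples missing from the site mapping: ",
         paste(utils::head(unmapped, 10), collapse = ", "))
  site <- sample_to_site[rownames(m)]
  sites <- unique(site)
  out <- t(vapply(sites, function(s) colMeans(m[site == s, , drop = FALSE]),
                  numeric(ncol(m))))
  dimnames(out) <- list(sites, colnames(m))
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes \eqn{d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} +
#' x_{jk})} between all row pairs.
#'
#' @param table site x OTU abundance matrix; every row must have at least
#'   one positive value.
#' @return a \code{dist} object with values in \code{[0, 1]}.
#' @export
bray_curtis <- function(table) {
  m <- as_otu_matrix(table)
  if (nrow(m) < 2) stop("need at least 2 rows")
  empty <- rowSums(m) == 0
  if (any(empty))
    stop("rows with all-zero abundance: ",
         paste(utils::head(rownames(m)[empty], 10), collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

as_dist_matrix <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be square and symmetric")
  if (any(d < -1e-12)) stop("distance matrix must be non-negative")
  d
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (Anderson's
#' distance-based formulation): partitions the sum of squared
#' dissimilarities between and within groups; significance by free
#' permutation of group labels with the \eqn{(1 + \#\{F^* \ge F\}) / (1 +
#' n_{perm})} convention, so p is never 0. Delegates to
#' \code{vegan::adonis2}.
#'
#' @param dist a \code{dist} object or symmetric matrix of dissimilarities.
#' @param groups per-site group labels, aligned with \code{dist} (named
#'   vectors are matched by name).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @return object of class \code{"permanova_result"}: list with
#'   \code{pseudo_F}, \code{R2}, \code{p_value}, \code{n_permutations},
#'   \code{group_labels} and the underlying ANOVA \code{table}.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d))) {
    if (!all(rownames(d) %in% names(groups)))
      stop("groups missing for some sites in the distance matrix")
    groups <- groups[rownames(d)]
  }
  if (length(groups) != n) stop("groups must align with the distance matrix")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("every group needs >= 2 sites; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  off <- d[lower.tri(d)]
  if (stats::sd(off) == 0)
    stop("constant distance matrix: pseudo-F is undefined")
  if (!is.null(seed)) set.seed(seed)
  g <- groups
  fit <- vegan::adonis2(stats::as.dist(d) ~ g,
                        permutations = n_permutations)
  structure(list(
    pseudo_F = fit$F[1],
    R2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = n_permutations,
    group_labels = levels(groups),
    table = as.data.frame(fit)
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%d permutations): pseudo-F = %.4g, R2 = %.4f, p = %.4g\n",
    x$n_permutations, x$pseudo_F, x$R2, x$p_value))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and adjusts
#' the pair p-values for multiple testing.
#'
#' @inheritParams permanova
#' @param adjustment \code{"bonferroni"} (default) or \code{"bh"}
#'   (Benjamini-Hochberg).
#' @return data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{pseudo_F}, \code{R2}, \code{p_value}, \code{p_adjusted}.
#' @export
pairwise_permanova <- function(dist, groups, n_permutations = 999,
                               adjustment = c("bonferroni", "bh"),
                               seed = NULL) {
  adjustment <- match.arg(adjustment)
  d <- as_dist_matrix(dist)
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  groups <- factor(groups)
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(levs, 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- groups %in% pairs[, j]
    res <- permanova(d[sel, sel, drop = FALSE], droplevels(groups[sel]),
                     n_permutations = n_permutations)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               pseudo_F = res$pseudo_F, R2 = res$R2, p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(
    out$p_value, method = if (adjustment == "bh") "BH" else "bonferroni")
  out
}
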