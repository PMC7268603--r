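# Shared fixtures and independent oracles, built in code.

# wrap a plain label vector as a cluster solution
make_solution <- function(labels, source = "community") {
  labels <- stats::setNames(as.integer(labels), names(labels))
  structure(list(k = length(unique(labels)), labels = labels,
                 source = source), class = "cluster_solution")
}

# small OTU matrix with named rows/columns
otu_mat <- function(..., otu_ids = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- if (is.null(otu_ids)) paste0("OTU_", seq_len(ncol(m)))
    else otu_ids
  m
}

# a tight two-pair distance matrix: within 0.01, between 0.99
tight_pairs_dist <- function() {
  d <- matrix(0.99, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0.01
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d
}

# brute-force Ward agglomeration for Euclidean points: at each step merge
# the pair of clusters with the smallest cost
# sqrt(2 nA nB / (nA + nB)) * ||centroid_A - centroid_B||, the ward.D2
# merge height. Recomputes every cost from the raw coordinates.
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- list()
  for (s in seq_len(n - 1)) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (i < j) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                     sum((ca - cb)^2))
      if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
    }
    heights[s] <- best_cost
    clusters <- c(clusters[-best],
                  list(c(clusters[[best[1]]], clusters[[best[2]]])))
    partitions[[s]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# label-invariant partition comparison
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# one-way PERMANOVA pseudo-F straight from the sums-of-squares formulas,
# independent of vegan
permanova_F_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  a <- length(unique(groups))
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# small strong-signal scenario used by several module tests
quick_scenario <- function(seed = 1, n_sites = 40, effect_lu = 2,
                           effect_chem = 1.5, n_otus = 120, depth = 500) {
  generate_scenario(scenario_config(
    n_sites = n_sites, land_use_proportions = rep(0.25, 4),
    n_replicates = 3, n_otus = n_otus, depth_mean = depth,
    n_responsive_otus = max(10, n_otus %/% 5),
    effect_size_chem = effect_chem, effect_size_landuse = effect_lu,
    missing_chem_rate = 0, seed = seed))
}
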