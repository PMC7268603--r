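# Synthetic soil-microbiome scenario generator: land-use-structured soil
# chemistry plus OTU count tables whose composition responds to latent
# chemistry and land use, with known ground truth for recovery tests.

SOIL_VARIABLES <- c("pH", "C_pct", "TN_pct", "AMN", "OlsenP", "MP", "BD")
LAND_USES <- c("indigenous", "exotic", "horticulture", "pastoral")

default_chem_means <- function() {
  m <- rbind(
    indigenous   = c(5.4, 8.0, 0.50, 150, 10, 25, 0.85),
    exotic       = c(5.6, 6.0, 0.35, 100, 15, 22, 0.95),
    horticulture = c(6.3, 3.5, 0.30,  80, 60, 14, 1.25),
    pastoral     = c(5.9, 6.0, 0.55, 140, 35, 12, 1.10)
  )
  colnames(m) <- SOIL_VARIABLES
  m
}

default_chem_sds <- function() {
  stats::setNames(c(0.35, 1.5, 0.10, 30, 15, 5, 0.12), SOIL_VARIABLES)
}

#' Scenario configuration for the synthetic soil-microbiome generator
#'
#' Builds and validates the parameter set that defines a simulated survey:
#' how many sites and replicate cores, the mix of the four land uses
#' (indigenous forest, exotic forest, horticulture, pastoral grassland),
#' per-land-use means and correlations of the seven soil variables
#' (pH, C \%, total N \%, anaerobically mineralizable N, Olsen P,
#' macroporosity, bulk density), and how strongly OTU composition responds
#' to standardized latent chemistry and to land use.
#'
#' @param n_sites number of sites.
#' @param land_use_proportions four non-negative weights (indigenous,
#'   exotic, horticulture, pastoral) summing to 1.
#' @param n_replicates replicate soil cores per site.
#' @param n_otus number of OTUs.
#' @param depth_mean expected sequencing reads per replicate sample
#'   (per-replicate totals are Poisson with this mean).
#' @param chem_means 4 x 7 matrix of per-land-use means for the soil
#'   variables, rows in the order of \code{land_use_proportions}.
#' @param chem_sds per-variable standard deviations (length 7).
#' @param chem_corr list with element \code{mp_bd}: the
#'   macroporosity--bulk-density correlation, in \code{[-1, 0]} (compacted
#'   soils are dense and poorly aerated).
#' @param n_responsive_otus how many OTUs respond to chemistry/land use.
#' @param effect_size_chem magnitude of a responsive OTU's log-abundance
#'   coefficient on its standardized chemistry variable.
#' @param effect_size_landuse magnitude of a responsive OTU's land-use
#'   specific log-abundance offset.
#' @param overdispersion Dirichlet concentration scalar (> 0); smaller
#'   values give more replicate-to-replicate compositional overdispersion.
#' @param missing_chem_rate probability in \code{[0, 1)} that an observed
#'   chemistry cell is masked (missing completely at random).
#' @param responsive_variable_probs length-7 sampling weights for which
#'   soil variable each responsive OTU tracks; the default emphasises pH,
#'   the dominant driver of soil bacterial composition.
#' @param chem_effect_weights length-7 per-variable multiplier applied to
#'   chemistry response coefficients (all 1 by default).
#' @param chem_cluster_means optional k x 7 matrix of chemistry-group
#'   means. When supplied, each site is assigned a latent chemistry group
#'   (independently of land use, with weights
#'   \code{chem_cluster_proportions}) and its chemistry is drawn around
#'   that group's means; the assignment is recorded in the truth. Used to
#'   plant well-separated chemistry clusters.
#' @param chem_cluster_proportions weights over the rows of
#'   \code{chem_cluster_means}.
#' @param seed integer seed; the whole scenario is reproducible from it.
#' @return a validated list of class \code{"scenario_config"}.
#' @seealso [generate_scenario()]
#' @export
scenario_config <- function(n_sites,
                            land_use_proportions = c(0.1, 0.12, 0.23, 0.55),
                            n_replicates = 5,
                            n_otus = 500,
                            depth_mean = 2000,
                            chem_means = default_chem_means(),
                            chem_sds = default_chem_sds(),
                            chem_corr = list(mp_bd = -0.7),
                            n_responsive_otus = 60,
                            effect_size_chem = 1,
                            effect_size_landuse = 1,
                            overdispersion = 200,
                            missing_chem_rate = 0.05,
                            responsive_variable_probs = NULL,
                            chem_effect_weights = NULL,
                            chem_cluster_means = NULL,
                            chem_cluster_proportions = NULL,
                            seed = 1L) {
  stopifnot(length(n_sites) == 1L, n_sites >= 1, n_replicates >= 1,
            n_otus >= 1, depth_mean > 0, overdispersion > 0)
  if (length(land_use_proportions) != 4L || any(land_use_proportions < 0))
    stop("land_use_proportions must be 4 non-negative weights")
  if (abs(sum(land_use_proportions) - 1) > 1e-9)
    stop("land_use_proportions must sum to 1 (tolerance 1e-9)")
  chem_means <- as.matrix(chem_means)
  if (!identical(dim(chem_means), c(4L, 7L)))
    stop("chem_means must be a 4 x 7 matrix (land use x soil variable)")
  colnames(chem_means) <- SOIL_VARIABLES
  rownames(chem_means) <- LAND_USES
  chem_sds <- stats::setNames(as.numeric(chem_sds), SOIL_VARIABLES)
  if (any(chem_sds <= 0)) stop("chem_sds must be strictly positive")
  if (is.null(chem_corr$mp_bd) || chem_corr$mp_bd < -1 || chem_corr$mp_bd > 0)
    stop("chem_corr$mp_bd must lie in [-1, 0]")
  if (n_responsive_otus > n_otus)
    stop("n_responsive_otus must not exceed n_otus")
  if (effect_size_chem < 0 || effect_size_landuse < 0)
    stop("effect sizes must be non-negative")
  if (missing_chem_rate < 0 || missing_chem_rate >= 1)
    stop("missing_chem_rate must be in [0, 1)")
  if (is.null(responsive_variable_probs))
    responsive_variable_probs <- c(0.3, rep(0.7 / 6, 6))
  responsive_variable_probs <- stats::setNames(
    as.numeric(responsive_variable_probs), SOIL_VARIABLES)
  if (any(responsive_variable_probs < 0) || sum(responsive_variable_probs) <= 0)
    stop("responsive_variable_probs must be non-negative, not all zero")
  if (is.null(chem_effect_weights)) chem_effect_weights <- rep(1, 7)
  chem_effect_weights <- stats::setNames(as.numeric(chem_effect_weights),
                                         SOIL_VARIABLES)
  if (!is.null(chem_cluster_means)) {
    chem_cluster_means <- as.matrix(chem_cluster_means)
    if (ncol(chem_cluster_means) != 7L)
      stop("chem_cluster_means must have 7 columns")
    colnames(chem_cluster_means) <- SOIL_VARIABLES
    if (is.null(chem_cluster_proportions))
      chem_cluster_proportions <- rep(1 / nrow(chem_cluster_means),
                                      nrow(chem_cluster_means))
    if (length(chem_cluster_proportions) != nrow(chem_cluster_means))
      stop("chem_cluster_proportions must match rows of chem_cluster_means")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    land_use_proportions = stats::setNames(land_use_proportions, LAND_USES),
    n_replicates = as.integer(n_replicates),
    n_otus = as.integer(n_otus),
    depth_mean = depth_mean,
    chem_means = chem_means,
    chem_sds = chem_sds,
    chem_corr = chem_corr,
    n_responsive_otus = as.integer(n_responsive_otus),
    effect_size_chem = effect_size_chem,
    effect_size_landuse = effect_size_landuse,
    overdispersion = overdispersion,
    missing_chem_rate = missing_chem_rate,
    responsive_variable_probs = responsive_variable_probs,
    chem_effect_weights = chem_effect_weights,
    chem_cluster_means = chem_cluster_means,
    chem_cluster_proportions = chem_cluster_proportions,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

chem_covariance <- function(config) {
  r <- diag(7)
  dimnames(r) <- list(SOIL_VARIABLES, SOIL_VARIABLES)
  r["MP", "BD"] <- r["BD", "MP"] <- config$chem_corr$mp_bd
  sigma <- diag(config$chem_sds) %*% r %*% diag(config$chem_sds)
  dimnames(sigma) <- dimnames(r)
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("implied chemistry covariance is not positive definite; ",
         "check chem_sds and chem_corr$mp_bd (= ", config$chem_corr$mp_bd, ")")
  sigma
}

clip_chemistry <- function(x) {
  x[, "pH"] <- pmin(pmax(x[, "pH"], 3), 10)
  for (v in c("C_pct", "TN_pct", "MP"))
    x[, v] <- pmin(pmax(x[, v], 0), 100)
  for (v in c("AMN", "OlsenP", "BD"))
    x[, v] <- pmax(x[, v], 1e-3)
  x
}

#' Generate per-site soil chemistry
#'
#' Draws each site's seven soil variables from the multivariate normal
#' implied by its group's means, the per-variable SDs and the
#' macroporosity--bulk-density correlation, clips to natural ranges
#' (pH to \[3, 10\], percentages to \[0, 100\], concentrations and bulk
#' density positive), and masks cells at \code{missing_chem_rate} to give
#' the observed table.
#'
#' @param config a [scenario_config()].
#' @param land_use_labels per-site land use (character, one of the four
#'   classes).
#' @param chem_cluster_labels optional per-site row index into
#'   \code{config$chem_cluster_means}; when absent, means follow land use.
#' @return list with \code{observed} (site x variable data frame, NAs for
#'   masked cells) and \code{latent} (the complete, noise-free-of-masking
#'   values actually used downstream).
#' @export
generate_chemistry <- function(config, land_use_labels,
                               chem_cluster_labels = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- length(land_use_labels)
  if (!all(land_use_labels %in% LAND_USES))
    stop("land_use_labels must be drawn from: ",
         paste(LAND_USES, collapse = ", "))
  sigma <- chem_covariance(config)
  set.seed(config$seed + 1L)
  noise <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = sigma)
  if (is.null(dim(noise))) noise <- matrix(noise, nrow = 1)
  if (!is.null(config$chem_cluster_means)) {
    if (is.null(chem_cluster_labels))
      stop("chem_cluster_labels required when chem_cluster_means is set")
    mu <- config$chem_cluster_means[chem_cluster_labels, , drop = FALSE]
  } else {
    mu <- config$chem_means[land_use_labels, , drop = FALSE]
  }
  latent <- clip_chemistry(mu + noise)
  site_ids <- names(land_use_labels)
  if (is.null(site_ids)) site_ids <- sprintf("site_%04d", seq_len(n))
  rownames(latent) <- site_ids
  observed <- latent
  if (config$missing_chem_rate > 0) {
    mask <- matrix(stats::runif(n * 7) < config$missing_chem_rate, n, 7)
    observed[mask] <- NA_real_
  }
  list(observed = as.data.frame(observed), latent = as.data.frame(latent))
}

#' Generate replicate-level OTU counts responding to chemistry and land use
#'
#' Site-level expected relative abundances follow a softmax (multinomial
#' logit) model: a per-OTU baseline, plus for each responsive OTU a
#' coefficient of magnitude \code{effect_size_chem} on one standardized
#' latent chemistry variable, plus a land-use offset of magnitude
#' \code{effect_size_landuse}. Replicate counts are Dirichlet-multinomial
#' (concentration \code{overdispersion} times the expected composition)
#' with Poisson total reads, so replicate cores are overdispersed relative
#' to a plain multinomial.
#'
#' @param config a [scenario_config()].
#' @param latent_chemistry complete site x 7 chemistry table (no missing
#'   values), e.g. the \code{latent} element of [generate_chemistry()].
#' @param land_use_labels per-site land use.
#' @return list with \code{counts} (replicate sample x OTU integer matrix),
#'   \code{metadata} (sample_id, site_id, land_use) and \code{truth}
#'   (baseline, beta, gamma, responsive OTU ids, expected site
#'   compositions).
#' @export
generate_counts <- function(config, latent_chemistry, land_use_labels) {
  stopifnot(inherits(config, "scenario_config"))
  chem <- as.matrix(latent_chemistry)[, SOIL_VARIABLES, drop = FALSE]
  if (anyNA(chem)) stop("latent chemistry must have no missing values")
  n_sites <- nrow(chem)
  stopifnot(length(land_use_labels) == n_sites)
  z <- scale(chem)
  z[is.nan(z)] <- 0  # constant column across sites carries no signal
  otu_ids <- sprintf("OTU_%04d", seq_len(config$n_otus))
  site_ids <- rownames(chem)
  if (is.null(site_ids)) site_ids <- sprintf("site_%04d", seq_len(n_sites))

  set.seed(config$seed + 2L)
  baseline <- stats::rnorm(config$n_otus, 0, 1.5)
  beta <- matrix(0, config$n_otus, 7, dimnames = list(otu_ids, SOIL_VARIABLES))
  gamma <- matrix(0, config$n_otus, 4, dimnames = list(otu_ids, LAND_USES))
  responsive <- sort(sample.int(config$n_otus, config$n_responsive_otus))
  for (k in responsive) {
    v <- sample.int(7, 1, prob = config$responsive_variable_probs)
    beta[k, v] <- sample(c(-1, 1), 1) * config$effect_size_chem *
      config$chem_effect_weights[v]
    l <- sample.int(4, 1)
    gamma[k, l] <- sample(c(-1, 1), 1) * config$effect_size_landuse
  }
  lu_idx <- match(land_use_labels, LAND_USES)
  eta <- matrix(baseline, n_sites, config$n_otus, byrow = TRUE) +
    z %*% t(beta) + t(gamma)[lu_idx, , drop = FALSE]
  eta <- eta - apply(eta, 1, max)  # softmax, numerically stable
  p <- exp(eta) / rowSums(exp(eta))

  n_rep <- config$n_replicates
  counts <- matrix(0L, n_sites * n_rep, config$n_otus)
  sample_ids <- character(n_sites * n_rep)
  row <- 0L
  for (i in seq_len(n_sites)) {
    alpha <- config$overdispersion * p[i, ]
    for (r in seq_len(n_rep)) {
      row <- row + 1L
      g <- stats::rgamma(config$n_otus, shape = alpha)
      q <- if (sum(g) > 0) g / sum(g) else p[i, ]
      total <- stats::rpois(1, config$depth_mean)
      counts[row, ] <- as.integer(stats::rmultinom(1, total, q))
      sample_ids[row] <- paste0(site_ids[i], "_r", r)
    }
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  metadata <- data.frame(
    sample_id = sample_ids,
    site_id = rep(site_ids, each = n_rep),
    land_use = rep(as.character(land_use_labels), each = n_rep),
    stringsAsFactors = FALSE
  )
  rownames(p) <- site_ids
  list(counts = counts, metadata = metadata,
       truth = list(baseline = baseline, beta = beta, gamma = gamma,
                    responsive_otus = otu_ids[responsive],
                    expected_composition = p))
}

soil_phyla <- c("Proteobacteria", "Acidobacteria", "Actinobacteria",
                "Verrucomicrobia", "Bacteroidetes", "Chloroflexi",
                "Planctomycetes", "Firmicutes", "Gemmatimonadetes")

#' Generate a complete synthetic survey scenario
#'
#' Draws per-site land-use labels (and, if configured, latent chemistry
#' groups), composes [generate_chemistry()] and [generate_counts()], and
#' attaches a simple synthetic 7-rank taxonomy (random phylum assignment;
#' purely a stand-in for a real classifier's output) plus the full ground
#' truth used by parameter-recovery tests.
#'
#' @param config a [scenario_config()].
#' @return object of class \code{"synthetic_dataset"}: list with
#'   \code{otu_counts} (replicate x OTU integer matrix), \code{chemistry}
#'   (observed site x variable data frame with NAs), \code{metadata}
#'   (sample_id, site_id, land_use, region), \code{taxonomy} (7-rank data
#'   frame per OTU, synthetic), \code{truth} and \code{config}.
#' @examples
#' cfg <- scenario_config(n_sites = 10, n_otus = 40, n_responsive_otus = 8,
#'                        depth_mean = 500, seed = 7)
#' ds <- generate_scenario(cfg)
#' dim(ds$otu_counts)  # 50 replicate samples x 40 OTUs
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  site_ids <- sprintf("site_%04d", seq_len(config$n_sites))
  land_use <- stats::setNames(
    sample(LAND_USES, config$n_sites, replace = TRUE,
           prob = config$land_use_proportions),
    site_ids)
  chem_cluster <- NULL
  if (!is.null(config$chem_cluster_means)) {
    chem_cluster <- stats::setNames(
      sample.int(nrow(config$chem_cluster_means), config$n_sites,
                 replace = TRUE, prob = config$chem_cluster_proportions),
      site_ids)
  }
  region <- stats::setNames(
    sample(paste0("region_", 1:4), config$n_sites, replace = TRUE), site_ids)
  chem <- generate_chemistry(config, land_use, chem_cluster)
  cnt <- generate_counts(config, chem$latent, land_use)
  cnt$metadata$region <- region[cnt$metadata$site_id]
  set.seed(config$seed + 3L)
  otu_ids <- colnames(cnt$counts)
  taxonomy <- data.frame(
    otu_id = otu_ids,
    domain = "Bacteria",
    phylum = sample(soil_phyla, config$n_otus, replace = TRUE),
    class = "unclassified", order = "unclassified", family = "unclassified",
    genus = "unclassified", species = "unclassified",
    stringsAsFactors = FALSE
  )
  structure(list(
    otu_counts = cnt$counts,
    chemistry = cbind(data.frame(site_id = site_ids), chem$observed),
    metadata = cnt$metadata,
    taxonomy = taxonomy,
    truth = c(cnt$truth,
              list(latent_chemistry = chem$latent, land_use = land_use,
                   chem_cluster = chem_cluster)),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic soil-microbiome scenario\n")
  cat(sprintf("  %d sites x %d replicates, %d OTUs, mean depth %g\n",
              x$config$n_sites, x$config$n_replicates, x$config$n_otus,
              x$config$depth_mean))
  cat("  land uses:",
      paste(names(table(x$truth$land_use)), table(x$truth$land_use),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the OTU table as TSV (first column \code{sample_id}), metadata
#' and chemistry as CSV (empty cell = missing), taxonomy as TSV, and the
#' ground truth as JSON.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu = file.path(dir, "otu_counts.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    chemistry = file.path(dir, "chemistry.csv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json")
  )
  otu_df <- data.frame(sample_id = rownames(dataset$otu_counts),
                       dataset$otu_counts, check.names = FALSE)
  utils::write.table(otu_df, paths["otu"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(dataset$chemistry, paths["chemistry"], row.names = FALSE,
                   na = "")
  utils::write.table(dataset$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$land_use <- as.list(truth$land_use)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
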