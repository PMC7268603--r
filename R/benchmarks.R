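# Reference simulation studies: fixed strong-signal scenarios that
# exercise the full pipeline and report its headline metrics. These are
# the package's standing benchmarks; the vignette discusses the scenario
# choices.

#' Land-use classification benchmark
#'
#' A 300-site survey with the four land uses in unbalanced proportions
#' (10/12/23/55 \%), five replicate cores per site, 500 OTUs of which 60
#' respond to chemistry and land use with a strong land-use effect
#' (magnitude 2 on the log scale), and 2000 expected reads per replicate.
#' The full chain is run: rarefaction to 2000 reads, replicate averaging,
#' Bray-Curtis + Ward clustering cut at k = 5, indicator selection at
#' A, B > 0.4, stratified 80/20 split and a 500-tree random-forest
#' land-use classifier evaluated on the held-out sites.
#'
#' @param seed integer seed controlling the whole run.
#' @return list with \code{accuracy_pct} (held-out accuracy, percent),
#'   \code{n_test}, \code{n_features} and the \code{evaluation}.
#' @export
sim_landuse_benchmark <- function(seed) {
  ds <- generate_scenario(scenario_config(
    n_sites = 300, land_use_proportions = c(0.1, 0.12, 0.23, 0.55),
    n_replicates = 5, n_otus = 500, depth_mean = 2000,
    n_responsive_otus = 60, effect_size_chem = 1, effect_size_landuse = 2,
    seed = seed))
  front <- benchmark_frontend(ds, seed, k = 5, a_min = 0.4, b_min = 0.4)
  sp <- stratified_split(front$land_use, fraction = 0.8, seed = seed)
  fit <- fit_classifier(front$features[sp$train_ids, , drop = FALSE],
                        front$land_use[sp$train_ids], seed = seed)
  ev <- evaluate_classification(fit,
                                front$features[sp$test_ids, , drop = FALSE],
                                front$land_use[sp$test_ids])
  list(accuracy_pct = 100 * ev$accuracy, n_test = length(sp$test_ids),
       n_features = ncol(front$features), evaluation = ev)
}

#' Chemistry-cluster classification benchmark
#'
#' A 200-site survey over the two non-pastoral managed land uses whose
#' chemistry is drawn around four planted cluster centres separated by
#' more than 3 within-cluster standard deviations on pH and carbon, with
#' composition strongly coupled to chemistry (effect size 2,
#' pH/C-weighted). Sites are clustered on their (PPCA-completed,
#' standardized) chemistry by Ward clustering with multi-criteria cut
#' selection; a random forest then predicts the chemistry cluster of
#' held-out sites from indicator OTUs (A, B > 0.5 on the k = 7 community
#' clustering).
#'
#' @param seed integer seed.
#' @return list with \code{accuracy_pct}, \code{k_selected},
#'   \code{n_test} and the \code{evaluation}.
#' @export
sim_chem_cluster_benchmark <- function(seed) {
  # four chemistry regimes spread across several variables at once
  # (compacted high-P, fertile, acidic organic, alkaline low-fertility);
  # within-cluster SDs are half the survey-wide defaults so adjacent
  # centres sit >= 3 within-cluster SDs apart
  centres <- rbind(
    c(6.2, 2.5, 0.20, 60, 70, 8, 1.35),
    c(5.8, 6.0, 0.50, 150, 35, 15, 1.05),
    c(5.0, 10.0, 0.70, 240, 12, 22, 0.80),
    c(6.8, 4.0, 0.35, 100, 20, 18, 1.15))
  ds <- generate_scenario(scenario_config(
    n_sites = 200, land_use_proportions = c(0, 0.5, 0.5, 0),
    n_replicates = 5, n_otus = 500, depth_mean = 2000,
    n_responsive_otus = 60, effect_size_chem = 2,
    effect_size_landuse = 0.5,
    chem_sds = default_chem_sds() / 2,
    responsive_variable_probs = c(0.35, 0.35, 0.06, 0.06, 0.06, 0.06, 0.06),
    chem_cluster_means = centres, seed = seed))
  front <- benchmark_frontend(ds, seed, k = 7, a_min = 0.5, b_min = 0.5)
  # chemistry clustering on PPCA-completed, standardized variables
  chem <- ds$chemistry
  rownames(chem) <- chem$site_id
  chem <- as.matrix(chem[rownames(front$features), SOIL_VARIABLES])
  pca <- ppca_em(chem, n_components = 2, seed = seed)
  chem[is.na(chem)] <- pca$fitted[is.na(chem)]
  d_chem <- stats::dist(scale(chem))
  # cut chosen from the chemistry structure criteria (silhouette, matrix
  # correlation); the planted regimes dominate both
  cut <- select_cut_level(ward_cluster(d_chem), d_chem, k_range = 2:8,
                          min_cluster_size = 5, source = "chemistry")
  clusters <- factor(cut$solution$labels)
  sp <- stratified_split(stats::setNames(as.character(clusters),
                                         names(cut$solution$labels)),
                         fraction = 0.8, seed = seed)
  fit <- fit_classifier(front$features[sp$train_ids, , drop = FALSE],
                        clusters[sp$train_ids], seed = seed)
  ev <- evaluate_classification(fit,
                                front$features[sp$test_ids, , drop = FALSE],
                                clusters[sp$test_ids])
  list(accuracy_pct = 100 * ev$accuracy, k_selected = cut$k,
       n_test = length(sp$test_ids), evaluation = ev)
}

#' Soil-variable regression and quality-scoring benchmark
#'
#' The land-use benchmark survey with a strong chemistry effect (size 2):
#' one random-forest regressor per soil variable on the indicator-OTU
#' features, evaluated by OLS of held-out predicted on actual values, and
#' quality-category scoring of the predictions under the example
#' thresholds. \code{ph_weight = 2} doubles the responsive-OTU
#' coefficients on pH, the strong pH-coupling variant.
#'
#' @param seed integer seed.
#' @param ph_weight multiplier on pH response coefficients (default 1).
#' @param variables which soil variables to model (default: all seven).
#' @return list with \code{adj_r2} (named per variable),
#'   \code{best_adj_r2}, \code{correct_pct} (pooled percent of correct
#'   category assignments), \code{correct_by_variable} (percent per
#'   variable) and \code{n_test}.
#' @export
sim_regression_benchmark <- function(seed, ph_weight = 1,
                                     variables = SOIL_VARIABLES) {
  ds <- generate_scenario(scenario_config(
    n_sites = 300, land_use_proportions = c(0.1, 0.12, 0.23, 0.55),
    n_replicates = 5, n_otus = 500, depth_mean = 2000,
    n_responsive_otus = 60, effect_size_chem = 2, effect_size_landuse = 2,
    chem_effect_weights = c(ph_weight, 1, 1, 1, 1, 1, 1), seed = seed))
  front <- benchmark_frontend(ds, seed, k = 5, a_min = 0.4, b_min = 0.4)
  chem <- ds$chemistry
  rownames(chem) <- chem$site_id
  chem <- as.matrix(chem[rownames(front$features), SOIL_VARIABLES])
  sp <- stratified_split(front$land_use, fraction = 0.8, seed = seed)
  thresholds <- load_quality_thresholds()
  adj_r2 <- c(); outcomes <- character(0); correct_by <- c()
  for (v in variables) {
    tr <- sp$train_ids[!is.na(chem[sp$train_ids, v])]
    te <- sp$test_ids[!is.na(chem[sp$test_ids, v])]
    fit <- fit_regressor(front$features[tr, , drop = FALSE], chem[tr, v],
                         seed = seed)
    ev <- evaluate_regression(fit, front$features[te, , drop = FALSE],
                              chem[te, v])
    adj_r2[v] <- ev$adj_r2
    sc <- score_table(matrix(ev$actual, ncol = 1,
                             dimnames = list(te, v)),
                      matrix(ev$predictions, ncol = 1),
                      variables = v, thresholds = thresholds)
    outcomes <- c(outcomes, sc$table$outcome)
    correct_by[v] <- 100 * mean(sc$table$outcome == "correct")
  }
  list(adj_r2 = adj_r2, best_adj_r2 = max(adj_r2),
       correct_pct = 100 * mean(outcomes == "correct"),
       correct_by_variable = correct_by,
       n_test = length(sp$test_ids))
}

# shared front end: rarefy, average, community cluster at fixed k,
# indicator-select features
benchmark_frontend <- function(ds, seed, k, a_min, b_min) {
  rarefied <- withCallingHandlers(
    rarefy(ds$otu_counts, depth = 2000, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  site_table <- average_replicates(rarefied,
                                   ds$metadata[, c("sample_id", "site_id")])
  land_use <- ds$truth$land_use[rownames(site_table)]
  d <- bray_curtis(site_table)
  sol <- cut_tree(ward_cluster(d), k)
  sel <- select_indicator_otus(indicator_scores(site_table, sol),
                               a_min, b_min)
  list(features = site_table[, sel, drop = FALSE], land_use = land_use,
       site_table = site_table, solution = sol)
}
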