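# Orchestration: table I/O with cross-validation of identifiers, and the
# end-to-end pipeline (rarefy -> average -> Bray-Curtis -> Ward/cut ->
# indicators -> chemistry clustering + PPCA -> stratified RF -> evaluation
# -> quality scores).

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Read and cross-validate the pipeline input tables
#'
#' Loads the OTU table (TSV, first column \code{sample_id}), the 7-rank
#' taxonomy (TSV), the sample metadata (CSV: sample_id, site_id, land_use,
#' region) and the site chemistry (CSV: site_id + soil variables, empty
#' cell = missing); checks that every OTU-table sample is in the metadata
#' and flags sites without chemistry; fills absent taxonomy ranks with
#' \code{"unclassified"}.
#'
#' @param otu_path,metadata_path,chemistry_path required file paths.
#' @param taxonomy_path optional taxonomy TSV.
#' @return list with \code{otu_counts} (matrix), \code{metadata},
#'   \code{chemistry}, \code{taxonomy} (or NULL).
#' @export
read_tables <- function(otu_path, metadata_path, chemistry_path,
                        taxonomy_path = NULL) {
  otu_df <- utils::read.delim(otu_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (names(otu_df)[1] != "sample_id")
    stop("OTU table must have 'sample_id' as its first column")
  m <- as.matrix(otu_df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(otu_df[-1], is.numeric, logical(1)))[1]
    stop("malformed numeric cell(s) in OTU column '",
         names(otu_df)[bad + 1], "'")
  }
  rownames(m) <- otu_df$sample_id
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "land_use")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  orphans <- setdiff(rownames(m), metadata$sample_id)
  if (length(orphans))
    stop("OTU-table samples missing from metadata: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  chemistry <- utils::read.csv(chemistry_path, stringsAsFactors = FALSE,
                               na.strings = c("", "NA"))
  if (!"site_id" %in% names(chemistry))
    stop("chemistry must have a site_id column")
  n_missing <- sum(is.na(chemistry[, -1]))
  if (n_missing)
    message(n_missing, " missing chemistry cells loaded as NA")
  no_chem <- setdiff(unique(metadata$site_id), chemistry$site_id)
  if (length(no_chem))
    warning("sites without chemistry: ",
            paste(utils::head(no_chem, 10), collapse = ", "))
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    if (!"otu_id" %in% names(taxonomy))
      stop("taxonomy must have an otu_id column")
    for (r in TAXONOMY_RANKS) {
      if (!r %in% names(taxonomy)) taxonomy[[r]] <- "unclassified"
      taxonomy[[r]][is.na(taxonomy[[r]]) | taxonomy[[r]] == ""] <-
        "unclassified"
    }
    taxonomy <- taxonomy[, c("otu_id", TAXONOMY_RANKS)]
  }
  list(otu_counts = m, metadata = metadata, chemistry = chemistry,
       taxonomy = taxonomy)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Inputs can be given
#' in memory (a \code{synthetic_dataset} or the list returned by
#' [read_tables()]).
#'
#' @param data input tables: a \code{synthetic_dataset} or
#'   [read_tables()] result.
#' @param scope \code{"all"} (all four land uses), \code{"AM"} (all
#'   managed: exotic, horticulture, pastoral) or \code{"NPG"} (non-pastoral
#'   managed: exotic, horticulture).
#' @param depth rarefaction depth (default 2000).
#' @param k_range candidate cluster counts for both dendrograms.
#' @param min_cluster_size smallest admissible cluster at cut selection.
#' @param a_min,b_min indicator specificity/fidelity thresholds.
#' @param split_fraction train proportion for the stratified split.
#' @param n_components PPCA components retained (default 2).
#' @param ntree random-forest trees (default 500).
#' @param thresholds quality thresholds ([load_quality_thresholds()]
#'   result or path); default: the shipped example config.
#' @param seed master seed for rarefaction, splitting and model fits.
#' @param out_dir optional directory; when set, every stage artifact and a
#'   JSON manifest are written there.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(data, scope = c("all", "AM", "NPG"),
                            depth = 2000, k_range = 2:8,
                            min_cluster_size = 5, a_min = 0.4, b_min = 0.4,
                            split_fraction = 0.8, n_components = 2,
                            ntree = 500, thresholds = NULL, seed = 1,
                            out_dir = NULL) {
  scope <- match.arg(scope)
  if (inherits(data, "synthetic_dataset"))
    data <- list(otu_counts = data$otu_counts, metadata = data$metadata,
                 chemistry = data$chemistry, taxonomy = data$taxonomy)
  stopifnot(all(c("otu_counts", "metadata", "chemistry") %in% names(data)))
  if (is.null(thresholds)) thresholds <- load_quality_thresholds()
  else if (is.character(thresholds))
    thresholds <- load_quality_thresholds(thresholds)
  structure(list(data = data, scope = scope, depth = depth,
                 k_range = k_range, min_cluster_size = min_cluster_size,
                 a_min = a_min, b_min = b_min,
                 split_fraction = split_fraction,
                 n_components = n_components, ntree = ntree,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

scope_land_uses <- function(scope) {
  switch(scope,
         all = LAND_USES,
         AM = c("exotic", "horticulture", "pastoral"),
         NPG = c("exotic", "horticulture"))
}

#' Run the full prediction pipeline
#'
#' Executes, in order: land-use scope filtering, rarefaction, replicate
#' averaging, Bray-Curtis + PERMANOVA (overall and pairwise), Ward
#' clustering of communities with multi-criteria cut selection, indicator
#' OTU selection, PPCA of chemistry and Ward clustering of the
#' (PPCA-completed) chemistry with Dunn's test, a stratified train/test
#' split, random-forest models (land-use classifier, chemistry-cluster
#' classifier, one regressor per soil variable and per PPCA axis),
#' held-out evaluation, permutation importance with phylum aggregation,
#' and quality-category scoring of the regression predictions. When
#' \code{out_dir} is set, every stage writes a CSV artifact plus a JSON
#' manifest (full configuration, seed, package and R versions) sufficient
#' to reproduce the run.
#'
#' @param config a [pipeline_config()].
#' @return list of class \code{"pipeline_result"} with the per-stage
#'   outputs (see the vignette for a walk-through).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- config$data
  seed <- config$seed

  # -- scope filter ---------------------------------------------------------
  keep_lu <- scope_land_uses(config$scope)
  md <- data$metadata[data$metadata$land_use %in% keep_lu, , drop = FALSE]
  if (nrow(md) == 0) stop("stage scope_filter: no samples left in scope")
  counts <- data$otu_counts[md$sample_id, , drop = FALSE]

  # -- rarefy + average -----------------------------------------------------
  rarefied <- withCallingHandlers(
    rarefy(counts, depth = config$depth, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  site_table <- average_replicates(
    rarefied, md[, c("sample_id", "site_id")])
  site_info <- unique(md[, c("site_id", "land_use")])
  site_info <- site_info[site_info$site_id %in% rownames(site_table), ]
  land_use <- stats::setNames(site_info$land_use, site_info$site_id)
  land_use <- land_use[rownames(site_table)]

  # -- community dissimilarity + PERMANOVA ----------------------------------
  d_comm <- bray_curtis(site_table)
  perm <- NULL; perm_pairs <- NULL
  if (length(unique(land_use)) >= 2 && all(table(land_use) >= 2)) {
    perm <- permanova(d_comm, land_use, n_permutations = 999, seed = seed)
    perm_pairs <- if (length(unique(land_use)) > 2)
      pairwise_permanova(d_comm, land_use, n_permutations = 999,
                         seed = seed) else NULL
  }

  # -- community clustering + indicator OTUs --------------------------------
  tree_comm <- ward_cluster(d_comm)
  cut_comm <- select_cut_level(tree_comm, d_comm, site_table,
                               k_range = config$k_range,
                               min_cluster_size = config$min_cluster_size,
                               source = "community")
  ind <- indicator_scores(site_table, cut_comm$solution)
  selected <- select_indicator_otus(ind, config$a_min, config$b_min)
  if (length(selected) < 2)
    stop("stage indicators: fewer than 2 OTUs pass the thresholds")
  features <- site_table[, selected, drop = FALSE]

  # -- chemistry: PPCA + clustering + Dunn ----------------------------------
  chem <- data$chemistry
  rownames(chem) <- chem$site_id
  chem <- as.matrix(chem[rownames(site_table),
                         setdiff(colnames(chem), "site_id"), drop = FALSE])
  pca <- ppca_em(chem, n_components = config$n_components, seed = seed)
  chem_complete <- chem
  chem_complete[is.na(chem_complete)] <- pca$fitted[is.na(chem_complete)]
  d_chem <- stats::dist(scale(chem_complete))
  tree_chem <- ward_cluster(d_chem)
  cut_chem <- select_cut_level(tree_chem, d_chem, site_table,
                               k_range = config$k_range,
                               min_cluster_size = config$min_cluster_size,
                               source = "chemistry")
  chem_clusters <- cut_chem$solution$labels
  dunn <- do.call(rbind, lapply(colnames(chem), function(v) {
    ok <- !is.na(chem[, v])
    res <- tryCatch(dunn_test(chem[ok, v], chem_clusters[ok]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(variable = v, res)
  }))

  # -- stratified split + models --------------------------------------------
  split <- stratified_split(land_use, fraction = config$split_fraction,
                            seed = seed + 10L)
  check_disjoint(split$train_ids, split$test_ids)
  tr <- split$train_ids; te <- split$test_ids

  landuse_model <- NULL; landuse_eval <- NULL
  if (length(unique(land_use[tr])) >= 2) {
    landuse_model <- fit_classifier(features[tr, , drop = FALSE],
                                    land_use[tr], ntree = config$ntree,
                                    seed = seed + 20L)
    landuse_eval <- evaluate_classification(
      landuse_model, features[te, , drop = FALSE], land_use[te])
  }
  cluster_model <- fit_classifier(features[tr, , drop = FALSE],
                                  factor(chem_clusters[tr]),
                                  ntree = config$ntree, seed = seed + 21L)
  cluster_eval <- evaluate_classification(
    cluster_model, features[te, , drop = FALSE], factor(chem_clusters[te]))

  targets <- cbind(chem, pca$scores)
  regressions <- list()
  for (v in colnames(targets)) {
    tr_v <- tr[!is.na(targets[tr, v])]
    te_v <- te[!is.na(targets[te, v])]
    if (length(tr_v) < 5 || length(te_v) < 3 ||
        stats::sd(targets[tr_v, v]) == 0) next
    mod <- fit_regressor(features[tr_v, , drop = FALSE], targets[tr_v, v],
                         ntree = config$ntree, seed = seed + 30L)
    eval <- evaluate_regression(mod, features[te_v, , drop = FALSE],
                                targets[te_v, v])
    imp <- permutation_importance(mod, features[te_v, , drop = FALSE],
                                  targets[te_v, v], seed = seed + 40L)
    regressions[[v]] <- list(model = mod, eval = eval, importance = imp)
  }

  importance_list <- lapply(regressions, `[[`, "importance")
  phylum_counts <- if (!is.null(data$taxonomy))
    lapply(importance_list, aggregate_importance_by_phylum,
           taxonomy = data$taxonomy) else NULL
  overlap <- if (length(importance_list) > 1)
    importance_overlap(importance_list) else NULL

  # -- quality scoring of held-out regression predictions -------------------
  quality <- NULL
  chem_vars <- intersect(colnames(chem), names(config$thresholds$variables))
  scored_vars <- intersect(chem_vars, names(regressions))
  if (length(scored_vars)) {
    # score each variable separately: per-variable missingness means the
    # held-out coverage can differ between variables
    quality_tabs <- lapply(scored_vars, function(v) {
      ev <- regressions[[v]]$eval
      score_table(matrix(ev$actual, ncol = 1,
                         dimnames = list(names(ev$predictions), v)),
                  matrix(ev$predictions, ncol = 1),
                  variables = v, thresholds = config$thresholds)
    })
    tab <- do.call(rbind, lapply(quality_tabs, `[[`, "table"))
    summ <- do.call(rbind, lapply(quality_tabs, `[[`, "summary"))
    quality <- structure(list(table = tab, summary = summ),
                         class = "quality_assessment")
  }

  result <- structure(list(
    scope = config$scope, seed = seed,
    n_sites = nrow(site_table), site_table = site_table,
    land_use = land_use, permanova = perm,
    pairwise_permanova = perm_pairs,
    community_cut = cut_comm, indicator_scores = ind,
    selected_otus = selected,
    ppca = pca, chemistry_cut = cut_chem, dunn = dunn,
    split = split,
    landuse_model = landuse_model, landuse_eval = landuse_eval,
    cluster_model = cluster_model, cluster_eval = cluster_eval,
    regressions = regressions, phylum_counts = phylum_counts,
    importance_overlap = overlap, quality = quality,
    config = config
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (scope %s, seed %d): %d sites, %d indicator OTUs\n",
              x$scope, x$seed, x$n_sites, length(x$selected_otus)))
  if (!is.null(x$landuse_eval))
    cat(sprintf("  land-use accuracy: %.3f\n", x$landuse_eval$accuracy))
  cat(sprintf("  chemistry clusters: k = %d, accuracy %.3f\n",
              x$chemistry_cut$k, x$cluster_eval$accuracy))
  if (length(x$regressions)) {
    r2 <- vapply(x$regressions, function(r) r$eval$adj_r2, numeric(1))
    cat(sprintf("  regression adj R2: %s\n",
                paste(sprintf("%s=%.2f", names(r2), r2), collapse = ", ")))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(data.frame(site_id = names(result$community_cut$solution$labels),
                  cluster = result$community_cut$solution$labels),
       "community_clusters.csv")
  wcsv(result$community_cut$diagnostics, "community_cut_diagnostics.csv")
  wcsv(data.frame(site_id = names(result$chemistry_cut$solution$labels),
                  cluster = result$chemistry_cut$solution$labels),
       "chemistry_clusters.csv")
  wcsv(result$chemistry_cut$diagnostics, "chemistry_cut_diagnostics.csv")
  wcsv(result$indicator_scores$scores, "indicator_scores.csv")
  writeLines(result$selected_otus, file.path(dir, "selected_otus.txt"))
  if (!is.null(result$permanova)) {
    tab <- result$permanova$table
    tab$term <- rownames(tab)
    wcsv(tab, "permanova.csv")
  }
  if (!is.null(result$pairwise_permanova))
    wcsv(result$pairwise_permanova, "pairwise_permanova.csv")
  if (!is.null(result$dunn)) wcsv(result$dunn, "dunn_test.csv")
  utils::write.csv(result$ppca$scores, file.path(dir, "ppca_scores.csv"))
  if (!is.null(result$landuse_eval))
    utils::write.csv(as.data.frame(result$landuse_eval$confusion),
                     file.path(dir, "landuse_confusion.csv"),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(result$cluster_eval$confusion),
                   file.path(dir, "cluster_confusion.csv"), row.names = FALSE)
  if (length(result$regressions)) {
    wcsv(do.call(rbind, lapply(names(result$regressions), function(v) {
      e <- result$regressions[[v]]$eval
      data.frame(variable = v, n = e$n, slope = e$slope,
                 intercept = e$intercept, r2 = e$r2, adj_r2 = e$adj_r2)
    })), "regression_evaluations.csv")
    wcsv(do.call(rbind, lapply(names(result$regressions), function(v)
      cbind(variable = v,
            as.data.frame(result$regressions[[v]]$importance)))),
      "permutation_importance.csv")
  }
  if (!is.null(result$quality)) {
    wcsv(result$quality$table, "quality_assessment.csv")
    wcsv(result$quality$summary, "quality_summary.csv")
  }
  cfg <- result$config
  manifest <- list(
    package = "microsoilq",
    package_version = as.character(utils::packageVersion("microsoilq")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = list(scope = cfg$scope, depth = cfg$depth,
                  k_range = cfg$k_range,
                  min_cluster_size = cfg$min_cluster_size,
                  a_min = cfg$a_min, b_min = cfg$b_min,
                  split_fraction = cfg$split_fraction,
                  n_components = cfg$n_components, ntree = cfg$ntree)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
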