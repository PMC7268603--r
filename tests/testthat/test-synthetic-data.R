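# Synthetic scenario generator: configuration validation, statistical
# structure of the generated chemistry and counts, determinism.

test_that("scenario_config validates its parameters", {
  expect_error(scenario_config(10, land_use_proportions = c(0.5, 0.5, 0, 0.1)),
               "sum to 1")
  expect_error(scenario_config(10, land_use_proportions = c(-0.1, 0.5, 0.3, 0.3)),
               "non-negative")
  expect_error(scenario_config(10, n_otus = 20, n_responsive_otus = 30),
               "n_responsive_otus")
  expect_error(scenario_config(10, missing_chem_rate = 1), "missing_chem_rate")
  expect_error(scenario_config(10, chem_corr = list(mp_bd = 0.5)), "mp_bd")
  expect_error(scenario_config(10, overdispersion = 0), NULL)
  expect_s3_class(scenario_config(10), "scenario_config")
})

test_that("chemistry generation honours masking, clipping and correlation", {
  lu <- rep(c("indigenous", "pastoral"), each = 5)
  cfg0 <- scenario_config(10, missing_chem_rate = 0, seed = 3)
  chem <- generate_chemistry(cfg0, lu)
  # no masking: observed identical to latent
  expect_identical(chem$observed, chem$latent)
  expect_false(anyNA(chem$observed))

  cfg_na <- scenario_config(200, missing_chem_rate = 0.2, seed = 3)
  chem_na <- generate_chemistry(cfg_na, rep("exotic", 200))
  frac <- mean(is.na(chem_na$observed))
  expect_gt(frac, 0.15); expect_lt(frac, 0.25)
  # masked cells agree with latent wherever observed
  obs <- !is.na(chem_na$observed)
  expect_equal(as.matrix(chem_na$observed)[obs],
               as.matrix(chem_na$latent)[obs])

  # planted macroporosity-bulk density correlation is recovered
  cfg_corr <- scenario_config(2000, chem_corr = list(mp_bd = -0.8),
                              missing_chem_rate = 0, seed = 11)
  big <- generate_chemistry(cfg_corr, rep("pastoral", 2000))
  r <- cor(big$latent$MP, big$latent$BD)
  expect_gt(r, -0.9); expect_lt(r, -0.7)
  # natural-scale clipping
  expect_true(all(big$latent$pH >= 3 & big$latent$pH <= 10))
  expect_true(all(big$latent$BD > 0))
})

test_that("chemistry generation is deterministic given config and seed", {
  lu <- rep(c("exotic", "horticulture"), 10)
  cfg <- scenario_config(20, seed = 9)
  expect_identical(generate_chemistry(cfg, lu), generate_chemistry(cfg, lu))
})

test_that("null scenario gives identical expected composition at all sites", {
  cfg <- scenario_config(12, n_otus = 30, n_responsive_otus = 5,
                         effect_size_chem = 0, effect_size_landuse = 0,
                         missing_chem_rate = 0, seed = 2)
  lu <- rep(c("indigenous", "exotic", "horticulture", "pastoral"), 3)
  chem <- generate_chemistry(cfg, lu)
  cnt <- generate_counts(cfg, chem$latent, lu)
  p <- cnt$truth$expected_composition
  expect_lt(max(apply(p, 2, function(col) diff(range(col)))), 1e-12)
  expect_true(all(cnt$truth$beta == 0))
  expect_true(all(cnt$truth$gamma == 0))
})

test_that("a strongly pH-responsive OTU tracks latent pH", {
  cfg <- scenario_config(
    500, n_otus = 2, n_responsive_otus = 1, effect_size_chem = 3,
    effect_size_landuse = 0, depth_mean = 2000, overdispersion = 500,
    responsive_variable_probs = c(1, 0, 0, 0, 0, 0, 0),
    missing_chem_rate = 0, seed = 5)
  lu <- sample(c("indigenous", "pastoral"), 500, replace = TRUE)
  chem <- generate_chemistry(cfg, lu)
  cnt <- generate_counts(cfg, chem$latent, lu)
  resp <- cnt$truth$responsive_otus
  expect_length(resp, 1)
  b <- cnt$truth$beta[resp, "pH"]
  expect_equal(abs(b), 3)
  rel <- cnt$counts[, resp] / rowSums(cnt$counts)
  site_rel <- tapply(rel, cnt$metadata$site_id, mean)
  rho <- cor(site_rel[rownames(chem$latent)], chem$latent$pH,
             method = "spearman")
  # correlation matches the planted coefficient sign, strongly
  expect_gt(sign(b) * rho, 0.8)
})

test_that("sequencing depth is Poisson around depth_mean", {
  cfg <- scenario_config(50, n_replicates = 5, n_otus = 50,
                         n_responsive_otus = 10, depth_mean = 2000,
                         missing_chem_rate = 0, seed = 8)
  ds <- generate_scenario(cfg)
  totals <- rowSums(ds$otu_counts)
  se <- sqrt(2000 / length(totals))
  expect_lt(abs(mean(totals) - 2000), 3 * se)
})

test_that("generate_scenario satisfies the dataset invariants", {
  cfg <- scenario_config(10, n_replicates = 5, n_otus = 25,
                         n_responsive_otus = 5, depth_mean = 300, seed = 4)
  ds <- generate_scenario(cfg)
  expect_equal(nrow(ds$otu_counts), 50)
  expect_true(all(ds$otu_counts >= 0))
  expect_true(all(ds$otu_counts == round(ds$otu_counts)))
  # every replicate maps to exactly one site, every site has 5 replicates
  expect_true(all(table(ds$metadata$site_id) == 5))
  expect_setequal(ds$metadata$sample_id, rownames(ds$otu_counts))
  # degenerate weights: all pastoral
  cfg_p <- scenario_config(8, land_use_proportions = c(0, 0, 0, 1),
                           n_otus = 20, n_responsive_otus = 2,
                           depth_mean = 200, seed = 4)
  expect_true(all(generate_scenario(cfg_p)$metadata$land_use == "pastoral"))
  # determinism: identical config and seed give identical datasets
  expect_identical(generate_scenario(cfg), generate_scenario(cfg))
})

test_that("planted chemistry groups override land-use means", {
  centers <- matrix(rep(c(5, 3, 0.3, 80, 20, 15, 1.2), each = 2), nrow = 2)
  centers[2, 1] <- 8  # second group: strongly alkaline
  cfg <- scenario_config(300, land_use_proportions = c(0, 0.5, 0.5, 0),
                         n_otus = 20, n_responsive_otus = 4,
                         chem_cluster_means = centers,
                         missing_chem_rate = 0, depth_mean = 200, seed = 6)
  ds <- generate_scenario(cfg)
  expect_false(is.null(ds$truth$chem_cluster))
  ph_by_group <- tapply(ds$truth$latent_chemistry$pH, ds$truth$chem_cluster,
                        mean)
  expect_lt(ph_by_group[["1"]], 5.5)
  expect_gt(ph_by_group[["2"]], 7.5)
})

test_that("with zero effect sizes PERMANOVA rejects at the nominal rate", {
  rejections <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config(20, land_use_proportions = rep(0.25, 4),
                           n_replicates = 1, n_otus = 40,
                           n_responsive_otus = 5, depth_mean = 300,
                           effect_size_chem = 0, effect_size_landuse = 0,
                           missing_chem_rate = 0, seed = 1000 + r)
    ds <- generate_scenario(cfg)
    lu <- ds$truth$land_use
    if (min(table(lu)) < 2) next
    site <- average_replicates(ds$otu_counts,
                               ds$metadata[, c("sample_id", "site_id")])
    p <- permanova(bray_curtis(site), lu, n_permutations = 99,
                   seed = r)$p_value
    rejections <- rejections + (p <= 0.05)
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.05 - 2 * sqrt(0.05 * 0.95 / n_rep))
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("held-out land-use accuracy is non-decreasing in the land-use effect", {
  grid <- c(0, 0.5, 1, 2)
  seeds <- 1:3
  acc <- sapply(grid, function(es) {
    mean(sapply(seeds, function(s) {
      ds <- generate_scenario(scenario_config(
        60, land_use_proportions = rep(0.25, 4), n_replicates = 2,
        n_otus = 80, n_responsive_otus = 20, depth_mean = 400,
        effect_size_chem = 0.5, effect_size_landuse = es,
        missing_chem_rate = 0, seed = 100 + s))
      site <- average_replicates(ds$otu_counts,
                                 ds$metadata[, c("sample_id", "site_id")])
      lu <- ds$truth$land_use[rownames(site)]
      sp <- stratified_split(lu, fraction = 0.8, seed = s)
      fit <- fit_classifier(site[sp$train_ids, ], lu[sp$train_ids],
                            seed = s)
      evaluate_classification(fit, site[sp$test_ids, ],
                              lu[sp$test_ids])$accuracy
    }))
  })
  expect_true(all(diff(acc) > -0.05))
  # land use leaks through chemistry even at zero direct effect, so the
  # baseline sits above chance; the direct effect still adds a clear gain
  expect_gt(acc[4], acc[1] + 0.1)
  expect_gt(acc[4], 0.85)  # strong effect is easily recovered
})

test_that("write_scenario round-trips through read_tables", {
  cfg <- scenario_config(6, n_otus = 15, n_responsive_otus = 3,
                         depth_mean = 200, missing_chem_rate = 0.1, seed = 2)
  ds <- generate_scenario(cfg)
  dir <- withr::local_tempdir()
  paths <- write_scenario(ds, dir)
  expect_true(all(file.exists(paths)))
  suppressMessages(back <- read_tables(paths["otu"], paths["metadata"],
                                       paths["chemistry"], paths["taxonomy"]))
  expect_equal(back$otu_counts[rownames(ds$otu_counts), colnames(ds$otu_counts)],
               ds$otu_counts)
  expect_equal(back$chemistry$pH, ds$chemistry$pH)
  expect_equal(back$taxonomy$phylum, ds$taxonomy$phylum)
})
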