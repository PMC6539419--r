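test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_metabolites = 60, n_genes = 120,
                           planted_dams = data.frame(
                             comparison = "PEC_vs_NEC", direction = "up",
                             log2fc = 3, n = 10),
                           planted_pathways = data.frame(
                             pathway_id = "ko00230", n_members = 10,
                             n_dams = 5),
                           seed = 11)
  a <- generate_metabolome(cfg)
  b <- generate_metabolome(cfg)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth$stage_means, b$truth$stage_means)
  ta <- generate_transcriptome(cfg, a)
  tb <- generate_transcriptome(cfg, b)
  expect_identical(ta$data$values, tb$data$values)
})

test_that("class counts follow largest-remainder apportionment", {
  # oracle: floors plus extra units to the biggest remainders
  counts <- apportion_counts(100, c(flavone = 0.15, lipid = 0.11))
  expect_equal(counts[["flavone"]], 15L)
  expect_equal(counts[["lipid"]], 11L)
  expect_equal(counts[["other"]], 74L)
  expect_equal(sum(counts), 100L)

  # remainder tie/rounding behaviour on an awkward split
  c2 <- apportion_counts(7, c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
  expect_equal(sum(c2), 7L)
  expect_equal(as.integer(sort(c2)), c(2L, 2L, 3L))

  cfg <- simulation_config(n_metabolites = 100,
                           planted_dams = data.frame(
                             comparison = "PEC_vs_NEC", direction = "up",
                             log2fc = 3, n = 5),
                           planted_pathways = data.frame(
                             pathway_id = "ko00230", n_members = 8,
                             n_dams = 3),
                           n_genes = 50, seed = 2)
  sim <- generate_metabolome(cfg)
  tab <- table(sim$data$annotation$feature_class)
  expect_equal(as.integer(tab[["Flavone"]]), 15L)
  expect_equal(as.integer(tab[["Amino acid"]]), 15L)
  expect_equal(as.integer(tab[["Nucleotide"]]), 10L)
})

test_that("noiseless planting gives closed-form fold changes and pair PCC", {
  cfg <- simulation_config(
    n_metabolites = 30, n_genes = 30, replicate_cv = 0,
    planted_dams = data.frame(comparison = "PEC_vs_NEC",
                              direction = c("up", "down"),
                              log2fc = c(15, 3), n = c(3, 3)),
    planted_pairs = data.frame(gene = c("gene0001", "gene0002"),
                               metabolite = c("met0001", "met0004"),
                               sign = c(1, -1)),
    planted_pathways = data.frame(pathway_id = "ko00230",
                                  n_members = 5, n_dams = 2),
    zero_fraction = 0.3, seed = 5)
  sim <- generate_metabolome(cfg)
  xi <- impute_zeros(sim$data)
  fc <- fold_change(xi, comparison_spec("PEC", "NEC"))
  expect_equal(fc$fc[1:3], rep(2^15, 3), tolerance = 1e-9)
  expect_equal(fc$fc[4:6], rep(2^-3, 3), tolerance = 1e-9)
  # zeroed reference features follow the closed form baseline / half-min
  # and are at least 2-fold up (half-min <= baseline / 2), so truth lists
  # them as differential
  zf <- sim$truth$zero_features
  expect_true(length(zf) > 0)
  sm <- sim$truth$stage_means
  half_min <- min(sm[sm > 0]) / 2
  expect_equal(fc$fc[match(zf, fc$feature_id)],
               unname(sm[zf, "PEC"] / half_min), tolerance = 1e-9)
  expect_true(all(fc$fc[match(zf, fc$feature_id)] >= 2))
  tr <- sim$truth$status$PEC_vs_NEC
  expect_true(all(tr$true_status[match(zf, tr$feature_id)] == "up"))

  tx <- generate_transcriptome(cfg, sim)
  cols <- sim$data$design$sample_id[sim$data$design$stage %in%
                                      c("NEC", "PEC")]
  p1 <- pair_pcc(log2(tx$data$values["gene0001", cols] + 1),
                 log2(sim$data$values["met0001", cols] + 1))
  p2 <- pair_pcc(log2(tx$data$values["gene0002", cols] + 1),
                 log2(sim$data$values["met0004", cols] + 1))
  expect_equal(p1, 1, tolerance = 1e-9)
  expect_equal(p2, -1, tolerance = 1e-9)
})

test_that("empirical replicate CV tracks the configured CV", {
  cfg <- simulation_config(n_metabolites = 500, n_genes = 200,
                           replicate_cv = 0.2, zero_fraction = 0,
                           planted_dams = data.frame(
                             comparison = "PEC_vs_NEC", direction = "up",
                             log2fc = 3, n = 10),
                           planted_pathways = data.frame(
                             pathway_id = "ko00230", n_members = 10,
                             n_dams = 5),
                           seed = 9)
  sim <- generate_metabolome(cfg)
  nec <- sim$data$values[, grep("^NEC", colnames(sim$data$values))]
  # pooled log-scale variance across features recovers the noise CV
  pooled_var <- mean(apply(log(nec), 1, var))
  cv_hat <- sqrt(exp(pooled_var) - 1)
  expect_lt(abs(cv_hat - 0.2) / 0.2, 0.2)
})

test_that("infeasible planting fails before sampling", {
  expect_error(simulation_config(n_metabolites = 10,
                                 planted_dams = data.frame(
                                   comparison = "PEC_vs_NEC",
                                   direction = "up", log2fc = 3, n = 50)),
               "exceeds")
  expect_error(simulation_config(planted_dams = data.frame(
    comparison = "PEC_vs_NEC", direction = "up", log2fc = 0.5, n = 5)),
    "log2fc")
  cfg <- simulation_config(n_metabolites = 50, n_genes = 120,
                           planted_dams = data.frame(
                             comparison = "PEC_vs_NEC", direction = "up",
                             log2fc = 3, n = 10),
                           planted_pathways = data.frame(
                             pathway_id = "ko00230", n_members = 8,
                             n_dams = 4),
                           planted_pairs = data.frame(
                             gene = "gene0001", metabolite = "met9999",
                             sign = 1),
                           seed = 1)
  sim <- generate_metabolome(cfg)
  expect_error(generate_transcriptome(cfg, sim), "unknown metabolite")
})

test_that("fixture bundles reload to the generated matrices", {
  cfg <- simulation_config(n_metabolites = 40, n_genes = 110,
                           planted_dams = data.frame(
                             comparison = "PEC_vs_NEC",
                             direction = c("up", "down"),
                             log2fc = 3, n = c(6, 4)),
                           planted_pathways = data.frame(
                             pathway_id = c("ko00230", "ko00941"),
                             n_members = c(8, 8), n_dams = c(4, 0)),
                           seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(cfg, dir)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  sim <- generate_metabolome(cfg)
  design <- read_design(paths[["design"]])
  met <- read_abundance(paths[["metabolome"]], design)
  expect_equal(met$values, sim$data$values, tolerance = 1e-6)
  pm <- read_pathway_map(paths[["pathway_map"]])
  expect_equal(sort(unique(unlist(pm))),
               sort(cfg$planted_pathways$pathway_id))
  truth <- read_result_table(paths[["truth"]])
  expect_equal(sum(truth$feature_id %in% rownames(met$values)),
               sum(cfg$planted_dams$n))
})
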