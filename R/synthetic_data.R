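#' Simulation configuration for synthetic staged omics data
#'
#' Describes a synthetic widely-targeted metabolome (and companion
#' transcriptome) with the statistical structure the downstream analysis
#' assumes: log-normal baselines per feature, multiplicative stage effects,
#' multiplicative replicate noise, true zeros in the reference stage, planted
#' differential features, planted enriched pathways, and planted correlated
#' gene-metabolite pairs. Defaults emulate a 581-metabolite, 3-stage x
#' 3-replicate design with the compound-class composition reported for the
#' cotton somatic-embryogenesis metabolome (amino acids 15%, flavones 15%,
#' organic acids 12%, lipids 11%, nucleotides 10%, remainder "other").
#'
#' @param n_metabolites number of metabolite features (default 581).
#' @param n_genes number of gene features (default 2000).
#' @param stages ordered stage labels (default \code{c("NEC","PEC","GE")}).
#' @param replicates_per_stage replicates per stage (default 3).
#' @param class_proportions named fractions per compound class summing to
#'   at most 1; the remainder is labelled \code{"other"}. Counts are obtained
#'   by largest-remainder apportionment (see \code{\link{apportion_counts}}).
#' @param baseline_log_mean,baseline_log_sd mean and sd of the natural-log
#'   baseline peak area (defaults \code{log(1e6)} and 1.5, spanning the
#'   orders of magnitude typical of MRM peak areas).
#' @param replicate_cv within-stage coefficient of variation of the
#'   multiplicative replicate noise (default 0.1).
#' @param planted_dams data.frame with columns \code{comparison}
#'   (\code{"TEST_vs_REF"}), \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{log2fc} (absolute log2 effect, >= 1) and \code{n} (feature count).
#'   Default plants, for each successive-stage comparison and the overall
#'   comparison, 20 up and 10 down features with |log2 effect| 3.
#' @param planted_pathways data.frame with columns \code{pathway_id},
#'   \code{n_members} and \code{n_dams}: each pathway receives
#'   \code{n_members} member metabolites of which \code{n_dams} are drawn
#'   from the planted differential features of the first comparison. A
#'   background pathway with no planted members is always added.
#' @param planted_pairs data.frame with columns \code{gene}, \code{metabolite},
#'   \code{sign} (+1/-1): gene stage profiles are coupled to the metabolite's
#'   log-scale stage profile with the requested correlation sign.
#' @param zero_fraction fraction of non-planted metabolites whose
#'   reference-stage (first stage) values are true zeros (default 0.05),
#'   exercising the imputation step and generating the extreme fold changes
#'   characteristic of on/off metabolites.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   matrices bit for bit.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_metabolites = 581,
                              n_genes = 2000,
                              stages = c("NEC", "PEC", "GE"),
                              replicates_per_stage = 3,
                              class_proportions = c(
                                "Amino acid" = 0.15,
                                "Flavone" = 0.15,
                                "Organic acid" = 0.12,
                                "Lipid" = 0.11,
                                "Nucleotide" = 0.10),
                              baseline_log_mean = log(1e6),
                              baseline_log_sd = 1.5,
                              replicate_cv = 0.1,
                              planted_dams = NULL,
                              planted_pathways = NULL,
                              planted_pairs = NULL,
                              zero_fraction = 0.05,
                              seed = 1L) {
  stages <- as.character(stages)
  if (length(stages) < 2 || anyDuplicated(stages))
    stop("stages must be >= 2 distinct labels")
  if (replicates_per_stage < 2)
    stop("replicates_per_stage must be >= 2 for within-group statistics")
  if (sum(class_proportions) > 1 + 1e-12)
    stop("class_proportions must sum to <= 1")
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must be in [0, 1)")
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (is.null(planted_dams)) {
    cmps <- c(paste0(stages[-1], "_vs_", stages[-length(stages)]),
              paste0(stages[length(stages)], "_vs_", stages[1]))
    cmps <- unique(cmps)
    planted_dams <- data.frame(
      comparison = rep(cmps, each = 2),
      direction = rep(c("up", "down"), length(cmps)),
      log2fc = 3,
      n = rep(c(20L, 10L), length(cmps)),
      stringsAsFactors = FALSE)
  }
  if (!all(c("comparison", "direction", "log2fc", "n") %in%
           names(planted_dams)))
    stop("planted_dams needs columns comparison, direction, log2fc, n")
  if (any(abs(planted_dams$log2fc) < 1))
    stop("planted |log2fc| must be >= 1 so that fold change >= 2 is achievable")
  if (sum(planted_dams$n) > n_metabolites)
    stop("planted DAM count exceeds n_metabolites")
  if (is.null(planted_pathways)) {
    planted_pathways <- data.frame(
      pathway_id = c("ko00230", "ko00941"),
      n_members = c(20L, 20L),
      n_dams = c(12L, 0L),
      stringsAsFactors = FALSE)
  }
  if (!all(c("pathway_id", "n_members", "n_dams") %in% names(planted_pathways)))
    stop("planted_pathways needs columns pathway_id, n_members, n_dams")
  if (any(planted_pathways$n_dams > planted_pathways$n_members))
    stop("pathway n_dams cannot exceed n_members")
  if (sum(planted_pathways$n_members) > n_metabolites)
    stop("pathway membership exceeds n_metabolites")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(
      gene = sprintf("gene%04d", 1:12),
      metabolite = sprintf("met%04d", rep(1:6, each = 2)),
      sign = rep(c(1, -1), 6),
      stringsAsFactors = FALSE)
  }
  if (!all(c("gene", "metabolite", "sign") %in% names(planted_pairs)))
    stop("planted_pairs needs columns gene, metabolite, sign")
  if (!all(planted_pairs$sign %in% c(-1, 1)))
    stop("planted pair sign must be +1 or -1")
  if (sum(planted_dams$n) + length(unique(planted_pairs$gene)) > n_genes)
    stop("planted DEGs plus paired genes exceed n_genes")
  structure(list(
    n_metabolites = as.integer(n_metabolites),
    n_genes = as.integer(n_genes),
    stages = stages,
    replicates_per_stage = as.integer(replicates_per_stage),
    class_proportions = class_proportions,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    replicate_cv = replicate_cv,
    planted_dams = planted_dams,
    planted_pathways = planted_pathways,
    planted_pairs = planted_pairs,
    zero_fraction = zero_fraction,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Largest-remainder apportionment of counts
#'
#' Distributes \code{n} units over categories proportionally to
#' \code{fractions}, assigning floors first and then one extra unit to the
#' categories with the largest fractional remainders (ties broken by input
#' order). Deterministic, and the counts always sum to \code{n}.
#'
#' @param n total count.
#' @param fractions named non-negative fractions summing to at most 1; the
#'   shortfall from 1 is assigned to a category named \code{"other"}.
#' @return named integer vector summing to \code{n}.
#' @export
apportion_counts <- function(n, fractions) {
  if (sum(fractions) < 1 - 1e-12)
    fractions <- c(fractions, other = 1 - sum(fractions))
  quota <- n * fractions / sum(fractions)
  base <- floor(quota)
  rem <- quota - base
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# stage design for a config
config_design <- function(config) {
  reps <- config$replicates_per_stage
  sample_design(
    sample_id = paste0(rep(config$stages, each = reps), "_", seq_len(reps)),
    stage = rep(config$stages, each = reps),
    replicate = rep(seq_len(reps), length(config$stages)),
    stage_levels = config$stages)
}

parse_comparison <- function(label, stages) {
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% stages))
    stop("comparison label '", label, "' does not match stages ",
         paste(stages, collapse = "/"))
  comparison_spec(parts[1], parts[2])
}

# derive the per-comparison true DAM status from noiseless stage means,
# zeros replaced by half the minimum positive mean (mirrors impute_zeros)
derive_true_status <- function(stage_means, comparisons) {
  pos <- stage_means[stage_means > 0]
  if (!length(pos)) stop("all-zero true stage means")
  imp <- pmax(stage_means, min(pos) / 2)
  out <- list()
  for (lab in names(comparisons)) {
    cmp <- comparisons[[lab]]
    fc <- imp[, cmp$test_stage] / imp[, cmp$ref_stage]
    status <- ifelse(fc >= 2, "up", ifelse(fc <= 0.5, "down", "unchanged"))
    out[[lab]] <- data.frame(feature_id = rownames(stage_means),
                             true_fc = fc, true_status = status,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Generate a synthetic metabolome with known ground truth
#'
#' Draws per-metabolite baselines from a log-normal distribution, applies the
#' planted stage effects multiplicatively as \code{2^log2fc} at the test stage
#' of each planted comparison, zeroes the reference-stage baseline of a
#' \code{zero_fraction} subset of non-planted features (true on/off
#' metabolites), and adds multiplicative log-normal replicate noise with
#' standard deviation \code{log(1 + replicate_cv)} on the natural-log scale.
#' Compound classes are assigned by largest-remainder apportionment of
#' \code{class_proportions}, and a pathway map consistent with
#' \code{planted_pathways} is built over the metabolites.
#'
#' The returned ground truth records, per comparison, the differential status
#' implied by the noiseless stage means after zero imputation, so truth and
#' emitted matrix are consistent by construction (zero-driven extreme fold
#' changes are true positives).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{data} (an \code{\link{abundance_matrix}}),
#'   \code{pathway_map} (feature to pathway-id list), and \code{truth} (list
#'   with \code{status} per comparison, \code{stage_means}, planted tables and
#'   \code{enriched_pathways}).
#' @export
generate_metabolome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_metabolites
  ids <- sprintf("met%04d", seq_len(n))
  stages <- config$stages
  reps <- config$replicates_per_stage

  counts <- apportion_counts(n, config$class_proportions)
  classes <- rep(names(counts), counts)

  baseline <- exp(rnorm(n, config$baseline_log_mean, config$baseline_log_sd))

  # noiseless stage means: baseline x 2^effect at each planted test stage
  stage_means <- matrix(baseline, n, length(stages),
                        dimnames = list(ids, stages))
  pd <- config$planted_dams
  pool <- seq_len(n)
  planted <- data.frame(feature_id = character(), comparison = character(),
                        direction = character(), log2fc = numeric(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pd))) {
    k <- pd$n[i]
    if (k > length(pool)) stop("planted DAM counts exceed the feature pool")
    take <- pool[seq_len(k)]
    pool <- pool[-seq_len(k)]
    cmp <- parse_comparison(pd$comparison[i], stages)
    eff <- abs(pd$log2fc[i]) * if (pd$direction[i] == "up") 1 else -1
    stage_means[take, cmp$test_stage] <-
      stage_means[take, cmp$test_stage] * 2^eff
    planted <- rbind(planted, data.frame(
      feature_id = ids[take], comparison = pd$comparison[i],
      direction = pd$direction[i], log2fc = eff, stringsAsFactors = FALSE))
  }

  # true zeros in the reference (first) stage among non-planted features
  n_zero <- floor(config$zero_fraction * length(pool))
  zero_idx <- integer()
  if (n_zero > 0) {
    zero_idx <- sample(pool, n_zero)
    stage_means[zero_idx, stages[1]] <- 0
  }

  design <- config_design(config)
  noise_sd <- log(1 + config$replicate_cv)
  vals <- matrix(0, n, nrow(design), dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- stage_means[, as.character(design$stage[j])]
    eps <- if (noise_sd > 0) exp(rnorm(n, 0, noise_sd)) else 1
    vals[, j] <- mu * eps
  }

  # pathway map: planted pathways draw n_dams members from comparison-1
  # planted features, the rest from unplanted features
  pp <- config$planted_pathways
  first_cmp <- if (nrow(pd)) pd$comparison[1] else NA_character_
  dam_pool <- planted$feature_id[planted$comparison == first_cmp]
  other_pool <- setdiff(ids, dam_pool)
  pmap_rows <- list()
  for (i in seq_len(nrow(pp))) {
    nd <- pp$n_dams[i]
    if (nd > length(dam_pool))
      stop("pathway '", pp$pathway_id[i],
           "' requests more planted DAM members than available")
    memb_d <- if (nd > 0) dam_pool[seq_len(nd)] else character()
    dam_pool <- setdiff(dam_pool, memb_d)
    nb <- pp$n_members[i] - nd
    if (nb > length(other_pool))
      stop("pathway '", pp$pathway_id[i], "' membership exceeds feature pool")
    memb_b <- if (nb > 0) sample(other_pool, nb) else character()
    other_pool <- setdiff(other_pool, memb_b)
    pmap_rows[[i]] <- data.frame(feature_id = c(memb_d, memb_b),
                                 pathway_id = pp$pathway_id[i],
                                 stringsAsFactors = FALSE)
  }
  pmap_df <- do.call(rbind, pmap_rows)
  pathway_map <- if (is.null(pmap_df)) structure(list(), names = character())
                 else split(pmap_df$pathway_id,
                            factor(pmap_df$feature_id,
                                   levels = unique(pmap_df$feature_id)))

  ann <- feature_annotation(ids, name = paste0("metabolite ", seq_len(n)),
                            feature_class = classes)
  data <- abundance_matrix(vals, ann, design)

  comparisons <- lapply(unique(pd$comparison), parse_comparison, stages)
  names(comparisons) <- unique(pd$comparison)
  truth <- list(
    status = derive_true_status(stage_means, comparisons),
    stage_means = stage_means,
    planted_dams = planted,
    planted_pathways = pp,
    zero_features = ids[zero_idx],
    enriched_pathways = pp$pathway_id[pp$n_dams > 0])
  list(data = data, pathway_map = pathway_map, truth = truth)
}

#' Generate a companion synthetic transcriptome
#'
#' Gene baselines are log-normal as for metabolites. For each planted
#' gene-metabolite pair, the gene's log-scale stage profile is set to
#' \code{sign} times the metabolite's centered log-scale stage-mean profile
#' (plus the gene's own baseline), so that in the noiseless limit the
#' replicate-level Pearson correlation between the pair equals exactly the
#' planted sign. Unpaired genes receive independent stage effects from
#' \code{planted_dams} scaled to the gene side (same comparisons, same
#' effect sizes), making DEG calling testable too.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param metabolome result of \code{\link{generate_metabolome}} under the
#'   same config.
#' @return list with elements \code{data} (gene
#'   \code{\link{abundance_matrix}}) and \code{truth} (list with per-
#'   comparison \code{status}, \code{stage_means} and \code{planted_pairs}).
#' @export
generate_transcriptome <- function(config, metabolome) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  ids <- sprintf("gene%04d", seq_len(n))
  stages <- config$stages
  design <- config_design(config)

  baseline <- exp(rnorm(n, config$baseline_log_mean, config$baseline_log_sd))
  stage_means <- matrix(baseline, n, length(stages),
                        dimnames = list(ids, stages))

  # independent planted DEGs on genes not used by pairs
  pairs <- config$planted_pairs
  bad <- setdiff(pairs$metabolite, rownames(metabolome$truth$stage_means))
  if (length(bad))
    stop("planted pair references unknown metabolite: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(pairs$gene, ids)
  if (length(bad))
    stop("planted pair references unknown gene: ", paste(bad, collapse = ", "))
  pd <- config$planted_dams
  pool <- setdiff(seq_len(n), match(pairs$gene, ids))
  planted_degs <- data.frame(feature_id = character(),
                             comparison = character(),
                             direction = character(), log2fc = numeric(),
                             stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pd))) {
    k <- pd$n[i]
    if (k > length(pool)) stop("planted DEG counts exceed the gene pool")
    take <- pool[seq_len(k)]
    pool <- pool[-seq_len(k)]
    cmp <- parse_comparison(pd$comparison[i], stages)
    eff <- abs(pd$log2fc[i]) * if (pd$direction[i] == "up") 1 else -1
    stage_means[take, cmp$test_stage] <-
      stage_means[take, cmp$test_stage] * 2^eff
    planted_degs <- rbind(planted_degs, data.frame(
      feature_id = ids[take], comparison = pd$comparison[i],
      direction = pd$direction[i], log2fc = eff, stringsAsFactors = FALSE))
  }

  # couple paired genes to metabolite log-profiles
  met_means <- metabolome$truth$stage_means
  pos <- met_means[met_means > 0]
  met_log <- log2(pmax(met_means, min(pos) / 2))
  for (i in seq_len(nrow(pairs))) {
    g <- match(pairs$gene[i], ids)
    prof <- met_log[pairs$metabolite[i], stages]
    prof <- prof - mean(prof)
    stage_means[g, ] <- baseline[g] * 2^(pairs$sign[i] * prof)
  }

  noise_sd <- log(1 + config$replicate_cv)
  vals <- matrix(0, n, nrow(design), dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- stage_means[, as.character(design$stage[j])]
    eps <- if (noise_sd > 0) exp(rnorm(n, 0, noise_sd)) else 1
    vals[, j] <- mu * eps
  }

  ann <- feature_annotation(ids, name = ids, feature_class = "gene")
  data <- abundance_matrix(vals, ann, design)

  comparisons <- lapply(unique(pd$comparison), parse_comparison, stages)
  names(comparisons) <- unique(pd$comparison)
  truth <- list(status = derive_true_status(stage_means, comparisons),
                stage_means = stage_means,
                planted_degs = planted_degs,
                planted_pairs = pairs)
  list(data = data, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits every table the pipeline consumes: metabolome and transcriptome
#' abundance TSVs, the sample design, the metabolite pathway map, and a
#' ground-truth table of planted differential features.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the five written file paths.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  met <- generate_metabolome(config)
  tx <- generate_transcriptome(config, met)
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create directory: ", out_dir)
  paths <- c(
    metabolome = file.path(out_dir, "metabolome.tsv"),
    transcriptome = file.path(out_dir, "transcriptome.tsv"),
    design = file.path(out_dir, "design.tsv"),
    pathway_map = file.path(out_dir, "pathway_map.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_abundance(met$data, paths["metabolome"])
  write_abundance(tx$data, paths["transcriptome"])
  d <- met$data$design
  write_table(data.frame(sample_id = d$sample_id,
                         stage = as.character(d$stage),
                         replicate = d$replicate), paths["design"])
  pm <- met$pathway_map
  pm_df <- data.frame(
    feature_id = rep(names(pm), lengths(pm)),
    pathway_id = unlist(pm, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_table(pm_df, paths["pathway_map"])
  write_table(rbind(met$truth$planted_dams, tx$truth$planted_degs),
              paths["truth"])
  paths
}
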