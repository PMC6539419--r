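#' Pipeline configuration
#'
#' Bundles every input path (or a simulation request), the comparison list
#' and all thresholds for a full end-to-end run. Thresholds default to the
#' standard rule set: fold change >= 2 / <= 0.5, VIP >= 1, p < 0.05
#' (switchable), pathway FDR < 0.05, |PCC| > 0.8.
#'
#' @param metabolome,transcriptome,design,pathway_map input file paths, or
#'   NULL when \code{simulation} is given.
#' @param simulation optional \code{\link{simulation_config}}; when set the
#'   pipeline generates its own inputs.
#' @param comparisons character vector of \code{"TEST_vs_REF"} labels;
#'   default the three stage contrasts
#'   \code{c("PEC_vs_NEC","GE_vs_PEC","GE_vs_NEC")}.
#' @param fc_up,fc_down,vip_min,p_max,use_p,fdr_max,pcc_threshold thresholds.
#' @param pcc_mode \code{"replicates"} or \code{"stage_means"}.
#' @param impute_rule zero-handling rule.
#' @param n_components PLS-DA components.
#' @param out_dir output directory for the result bundle.
#' @param seed integer seed used for any simulation.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(metabolome = NULL, transcriptome = NULL,
                            design = NULL, pathway_map = NULL,
                            simulation = NULL,
                            comparisons = c("PEC_vs_NEC", "GE_vs_PEC",
                                            "GE_vs_NEC"),
                            fc_up = 2, fc_down = 0.5, vip_min = 1,
                            p_max = 0.05, use_p = TRUE, fdr_max = 0.05,
                            pcc_threshold = 0.8,
                            pcc_mode = "replicates",
                            impute_rule = "half_min_positive",
                            n_components = 2,
                            out_dir = tempfile("metranet_run_"),
                            seed = 1L) {
  comparisons <- as.character(unlist(comparisons))
  if (is.null(simulation) && is.null(metabolome))
    stop("either input paths or a simulation config must be given")
  if (any(c(fc_up, vip_min, p_max, fdr_max, pcc_threshold) <= 0) ||
      fc_down <= 0)
    stop("thresholds must be positive")
  structure(list(metabolome = metabolome, transcriptome = transcriptome,
                 design = design, pathway_map = pathway_map,
                 simulation = simulation, comparisons = comparisons,
                 fc_up = fc_up, fc_down = fc_down, vip_min = vip_min,
                 p_max = p_max, use_p = use_p, fdr_max = fdr_max,
                 pcc_threshold = pcc_threshold, pcc_mode = pcc_mode,
                 impute_rule = impute_rule, n_components = n_components,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; a
#' \code{simulation:} block (keys mirroring
#' \code{\link{simulation_config}}) requests synthetic inputs. Relative
#' input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file values.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    pd <- if (!is.null(y$simulation$planted_dams))
      do.call(rbind.data.frame, y$simulation$planted_dams) else NULL
    y$simulation$planted_dams <- pd
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  base <- dirname(normalizePath(path))
  for (k in c("metabolome", "transcriptome", "design", "pathway_map"))
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y[names(y) %in% names(formals(pipeline_config))])
}

pipe_log <- function(...) message("[metranet] ", sprintf(...))

#' Run the full metabolome-transcriptome association pipeline
#'
#' Executes, per comparison: QC (sample correlation, PCA variance),
#' differential metabolite calling (fold change + PLS-DA VIP + optional
#' p-filter), differential gene calling, pathway enrichment on both sides
#' with co-mapped pathway intersection, nine-quadrant association, and
#' signed bipartite network construction and export. Writes one TSV per
#' result plus a GraphML network per comparison and a run manifest, all
#' under \code{config$out_dir}. Identical config and seed reproduce the
#' bundle exactly.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with all in-memory results (\code{qc},
#'   per-comparison \code{differential}, \code{deg}, \code{enrichment},
#'   \code{pairs}, \code{network}, plus \code{venn} and \code{manifest}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulation)) {
    pipe_log("simulating inputs (seed %d)", config$simulation$seed)
    sim <- generate_metabolome(config$simulation)
    tx <- generate_transcriptome(config$simulation, sim)
    met <- sim$data
    genes <- tx$data
    pmap <- sim$pathway_map
  } else {
    design <- read_design(config$design)
    met <- read_abundance(config$metabolome, design)
    genes <- if (!is.null(config$transcriptome))
      read_abundance(config$transcriptome, design) else NULL
    pmap <- if (!is.null(config$pathway_map))
      read_pathway_map(config$pathway_map)
      else structure(list(), names = character())
  }
  cmps <- lapply(config$comparisons, parse_comparison,
                 stages = levels(met$design$stage))
  names(cmps) <- config$comparisons

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  counts <- list()

  pipe_log("qc: %d features x %d samples", nrow(met$values),
           ncol(met$values))
  out$qc <- list(sample_correlation = sample_correlation_matrix(met),
                 pca = pca_variance(met))
  write_table(as.data.frame(out$qc$sample_correlation),
              file.path(config$out_dir, "qc_sample_correlation.tsv"))
  write_table(data.frame(component = seq_along(
                           out$qc$pca$variance_fractions),
                         variance_fraction =
                           out$qc$pca$variance_fractions),
              file.path(config$out_dir, "qc_pc_variance.tsv"))

  dams <- list()
  for (lab in names(cmps)) {
    cmp <- cmps[[lab]]
    res <- differential_analysis(
      met, cmp, n_components = config$n_components, use_p = config$use_p,
      fc_up = config$fc_up, fc_down = config$fc_down,
      vip_min = config$vip_min, p_max = config$p_max,
      impute_rule = config$impute_rule)
    out$differential[[lab]] <- res
    dams[[lab]] <- res$feature_id[res$status != "unchanged"]
    counts[[paste0("dams_", lab)]] <- length(dams[[lab]])
    pipe_log("differential %s: %d DAMs", lab, length(dams[[lab]]))
    write_table(res, file.path(config$out_dir,
                               paste0("differential_", lab, ".tsv")))
    write_table(volcano_data(res),
                file.path(config$out_dir, paste0("volcano_", lab, ".tsv")))
    comp <- class_composition(dams[[lab]], met$annotation)
    write_table(comp, file.path(config$out_dir,
                                paste0("class_composition_", lab, ".tsv")))
    if (length(dams[[lab]]) >= 2) {
      hc <- hca_order(met, features = dams[[lab]])
      write_table(data.frame(feature_id = hc$feature_order),
                  file.path(config$out_dir,
                            paste0("hca_order_", lab, ".tsv")))
    }
  }
  if (length(dams) == 3) {
    out$venn <- venn_partition(dams)
    venn_df <- data.frame(region = names(out$venn),
                          size = lengths(out$venn),
                          features = vapply(out$venn, paste,
                                            character(1), collapse = ","),
                          stringsAsFactors = FALSE, row.names = NULL)
    write_table(venn_df, file.path(config$out_dir, "venn_regions.tsv"))
  }

  for (lab in names(cmps)) {
    cmp <- cmps[[lab]]
    if (length(pmap) && length(dams[[lab]])) {
      enr <- enrich_pathways(dams[[lab]], rownames(met$values), pmap,
                             fdr_max = config$fdr_max)
      out$enrichment[[lab]] <- enr
      write_table(enr, file.path(config$out_dir,
                                 paste0("enrichment_", lab, ".tsv")))
      counts[[paste0("enriched_", lab)]] <- sum(enr$significant)
      pipe_log("enrichment %s: %d pathways tested, %d significant", lab,
               nrow(enr), sum(enr$significant))
    }
    if (!is.null(genes)) {
      deg <- deg_analysis(genes, cmp, fdr_max = config$fdr_max)
      out$deg[[lab]] <- deg
      write_table(deg, file.path(config$out_dir,
                                 paste0("deg_", lab, ".tsv")))
      pairs <- associate_pairs(genes, met, deg, out$differential[[lab]],
                               cmp, mode = config$pcc_mode,
                               pcc_threshold = config$pcc_threshold)
      out$pairs[[lab]] <- pairs
      qt <- quadrant_table(pairs[pairs$passes_threshold, , drop = FALSE])
      write_table(data.frame(quadrant = names(qt$counts),
                             count = as.integer(qt$counts)),
                  file.path(config$out_dir,
                            paste0("quadrant_counts_", lab, ".tsv")))
      write_table(qt$table, file.path(config$out_dir,
                                      paste0("quadrants_", lab, ".tsv")))
      net <- build_network(pairs, pcc_threshold = config$pcc_threshold)
      out$network[[lab]] <- net
      counts[[paste0("edges_", lab)]] <- nrow(net$edges)
      pipe_log("network %s: %d nodes, %d edges", lab, nrow(net$nodes),
               nrow(net$edges))
      export_network(net, file.path(config$out_dir,
                                    paste0("network_", lab, ".graphml")),
                     format = "graphml")
      export_network(net, file.path(config$out_dir,
                                    paste0("network_", lab, ".sif")),
                     format = "sif")
    }
  }
  if (!is.null(out$enrichment) && length(out$enrichment) &&
      !is.null(genes) && length(pmap)) {
    # gene-side enrichment against the same map (genes unannotated here
    # unless the map covers them) is meaningful only when the map includes
    # gene ids; guard accordingly
    gene_ids <- rownames(genes$values)
    if (any(gene_ids %in% names(pmap))) {
      for (lab in names(cmps)) {
        degs <- out$deg[[lab]]$feature_id[out$deg[[lab]]$status !=
                                            "unchanged"]
        if (length(degs)) {
          genr <- enrich_pathways(degs, gene_ids, pmap,
                                  fdr_max = config$fdr_max)
          com <- co_mapped_pathways(out$enrichment[[lab]], genr)
          out$co_mapped[[lab]] <- com
          write_table(com, file.path(config$out_dir,
                                     paste0("co_mapped_", lab, ".tsv")))
        }
      }
    }
  }

  manifest <- data.frame(
    key = c("seed", "comparisons", "fc_up", "fc_down", "vip_min", "p_max",
            "use_p", "fdr_max", "pcc_threshold", "pcc_mode",
            "n_features", "n_samples", names(counts)),
    value = c(config$seed, paste(config$comparisons, collapse = ","),
              config$fc_up, config$fc_down, config$vip_min, config$p_max,
              config$use_p, config$fdr_max, config$pcc_threshold,
              config$pcc_mode, nrow(met$values), ncol(met$values),
              unlist(counts)),
    stringsAsFactors = FALSE)
  write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  out$manifest <- manifest
  pipe_log("done in %.1fs; results in %s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")),
           config$out_dir)
  invisible(out)
}
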