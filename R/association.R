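#' Pearson correlation of a gene-metabolite pair
#'
#' Correlates the two profiles over the selected samples. In
#' \code{"replicates"} mode the profiles are the replicate-level values of
#' the two compared stages (typically 6 points); in \code{"stage_means"} mode
#' they are the two stage means, where any non-degenerate pair gives exactly
#' +1 or -1 (the two-point correlation is always perfect, which is the only
#' reading consistent with published tables reporting PCC values of exactly
#' +/-1). Zero-variance profiles make the correlation undefined and the pair
#' is excluded upstream.
#'
#' @param gene_profile,metabolite_profile numeric vectors over the same
#'   samples (or the two stage means).
#' @return Pearson r, or \code{NA_real_} when either profile is constant.
#' @export
pair_pcc <- function(gene_profile, metabolite_profile) {
  if (length(gene_profile) != length(metabolite_profile))
    stop("profiles must have equal length")
  if (length(gene_profile) < 2) stop("need >= 2 points")
  if (sd(gene_profile) == 0 || sd(metabolite_profile) == 0)
    return(NA_real_)
  cor(gene_profile, metabolite_profile, method = "pearson")
}

#' Nine-quadrant classification of a gene-metabolite pair
#'
#' Maps the 3x3 combinations of (metabolite status, gene status) onto
#' quadrants 1-9 of the association diagram: rows from upregulated (top) to
#' downregulated (bottom) metabolites, columns from downregulated (left) to
#' upregulated (right) genes. Quadrants 3 and 7 hold co-directional
#' (positively associated) pairs, 1 and 9 opposite (negatively associated)
#' pairs, and 5 the doubly unchanged pairs.
#'
#' @param metabolite_status,gene_status character vectors in
#'   \code{c("up","down","unchanged")} (recycled to common length).
#' @return integer vector of quadrants in 1..9.
#' @export
quadrant_classify <- function(metabolite_status, gene_status) {
  valid <- c("up", "down", "unchanged")
  if (!all(metabolite_status %in% valid) || !all(gene_status %in% valid))
    stop("statuses must be one of up/down/unchanged")
  n <- max(length(metabolite_status), length(gene_status))
  metabolite_status <- rep_len(metabolite_status, n)
  gene_status <- rep_len(gene_status, n)
  row <- match(metabolite_status, c("up", "unchanged", "down"))  # 1..3 top-down
  col <- match(gene_status, c("down", "unchanged", "up"))        # 1..3 left-right
  as.integer((row - 1L) * 3L + col)
}

#' Build classified gene-metabolite association pairs
#'
#' For every (gene, metabolite) combination of the supplied differential
#' results, computes the replicate-level (or stage-mean) Pearson correlation
#' over the two compared stages on log2(x+1) values, classifies the pair into
#' its nine-quadrant cell, and flags pairs passing the |PCC| threshold.
#' Pairs with undefined correlation (constant profile) are excluded, with
#' the count reported via a message.
#'
#' @param genes gene \code{\link{abundance_matrix}}.
#' @param metabolites metabolite \code{\link{abundance_matrix}} on the same
#'   design.
#' @param gene_results,metabolite_results \code{differential_result} tables
#'   for the same comparison (supply the statuses and log2 fold changes).
#' @param cmp the \code{\link{comparison_spec}} correlated over.
#' @param mode \code{"replicates"} (default; all replicates of the two
#'   stages) or \code{"stage_means"} (two points, PCC exactly +/-1).
#' @param pcc_threshold absolute-correlation cutoff, strict (default 0.8).
#' @param gene_ids,metabolite_ids optional id subsets (e.g. curated gene
#'   lists and pathway metabolites) to restrict the pair grid.
#' @return data.frame of class \code{association_pairs}: \code{gene_id},
#'   \code{metabolite_id}, \code{pcc}, \code{gene_status},
#'   \code{metabolite_status}, \code{gene_log2fc}, \code{metabolite_log2fc},
#'   \code{quadrant}, \code{passes_threshold}.
#' @export
associate_pairs <- function(genes, metabolites, gene_results,
                            metabolite_results, cmp,
                            mode = c("replicates", "stage_means"),
                            pcc_threshold = 0.8,
                            gene_ids = NULL, metabolite_ids = NULL) {
  mode <- match.arg(mode)
  check_comparison(genes, cmp)
  check_comparison(metabolites, cmp)
  if (is.null(gene_ids)) gene_ids <- gene_results$feature_id
  if (is.null(metabolite_ids)) metabolite_ids <- metabolite_results$feature_id
  gene_ids <- intersect(gene_ids, rownames(genes$values))
  metabolite_ids <- intersect(metabolite_ids, rownames(metabolites$values))
  cols <- c(stage_columns(genes, cmp$test_stage),
            stage_columns(genes, cmp$ref_stage))
  gv <- log2p1(genes$values[gene_ids, cols, drop = FALSE])
  mv <- log2p1(metabolites$values[metabolite_ids, cols, drop = FALSE])
  if (mode == "stage_means") {
    grp <- factor(colnames(gv) %in% stage_columns(genes, cmp$test_stage),
                  levels = c(FALSE, TRUE))
    gv <- t(apply(gv, 1, function(v) tapply(v, grp, mean)))
    mv <- t(apply(mv, 1, function(v) tapply(v, grp, mean)))
  }
  grid <- expand.grid(gene_id = gene_ids, metabolite_id = metabolite_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pcc <- mapply(function(g, m) pair_pcc(gv[g, ], mv[m, ]),
                grid$gene_id, grid$metabolite_id)
  dropped <- sum(is.na(pcc))
  if (dropped)
    message(dropped, " pair(s) excluded: undefined correlation ",
            "(constant profile)")
  keep <- !is.na(pcc)
  grid <- grid[keep, , drop = FALSE]
  pcc <- pcc[keep]
  gs <- gene_results$status[match(grid$gene_id, gene_results$feature_id)]
  ms <- metabolite_results$status[match(grid$metabolite_id,
                                        metabolite_results$feature_id)]
  out <- data.frame(
    gene_id = grid$gene_id, metabolite_id = grid$metabolite_id, pcc = pcc,
    gene_status = gs, metabolite_status = ms,
    gene_log2fc =
      gene_results$log2fc[match(grid$gene_id, gene_results$feature_id)],
    metabolite_log2fc =
      metabolite_results$log2fc[match(grid$metabolite_id,
                                      metabolite_results$feature_id)],
    quadrant = quadrant_classify(ms, gs),
    passes_threshold = abs(pcc) > pcc_threshold,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("association_pairs", "data.frame")
  out
}

#' Per-quadrant counts and plot table
#'
#' @param pairs an \code{\link{associate_pairs}} result (or any data.frame
#'   with a \code{quadrant} column in 1..9).
#' @return list with \code{counts} (named integer vector over quadrants 1-9,
#'   summing to the number of pairs) and \code{table} (plot-ready data.frame
#'   of gene/metabolite log2fc and quadrant).
#' @export
quadrant_table <- function(pairs) {
  counts <- stats::setNames(integer(9), as.character(1:9))
  if (nrow(pairs)) {
    tab <- table(factor(pairs$quadrant, levels = 1:9))
    counts[] <- as.integer(tab)
  }
  tbl <- if (nrow(pairs))
    data.frame(gene_id = pairs$gene_id, metabolite_id = pairs$metabolite_id,
               gene_log2fc = pairs$gene_log2fc,
               metabolite_log2fc = pairs$metabolite_log2fc,
               quadrant = pairs$quadrant, stringsAsFactors = FALSE)
  else
    data.frame(gene_id = character(), metabolite_id = character(),
               gene_log2fc = numeric(), metabolite_log2fc = numeric(),
               quadrant = integer(), stringsAsFactors = FALSE)
  list(counts = counts, table = tbl)
}

#' Build a signed bipartite gene-metabolite network
#'
#' Keeps the pairs with |PCC| strictly above the threshold; edge sign is the
#' sign of the correlation, nodes are exactly the endpoints of kept edges,
#' and duplicate (gene, metabolite) pairs are collapsed to their first
#' occurrence.
#'
#' @param pairs data.frame with columns \code{gene_id},
#'   \code{metabolite_id}, \code{pcc} (e.g. from
#'   \code{\link{associate_pairs}} or a curated pair table).
#' @param pcc_threshold strict absolute-correlation cutoff (default 0.8).
#' @return list of class \code{bipartite_network}: \code{nodes} (data.frame
#'   \code{id}, \code{kind} in gene/metabolite) and \code{edges} (data.frame
#'   \code{gene_id}, \code{metabolite_id}, \code{pcc}, \code{sign} in
#'   positive/negative).
#' @export
build_network <- function(pairs, pcc_threshold = 0.8) {
  need <- c("gene_id", "metabolite_id", "pcc")
  if (!all(need %in% names(pairs)))
    stop("pairs need columns: ", paste(need, collapse = ", "))
  keep <- !is.na(pairs$pcc) & abs(pairs$pcc) > pcc_threshold
  e <- pairs[keep, need, drop = FALSE]
  e <- e[!duplicated(e[, c("gene_id", "metabolite_id")]), , drop = FALSE]
  e$sign <- ifelse(e$pcc > 0, "positive", "negative")
  rownames(e) <- NULL
  nodes <- data.frame(
    id = c(unique(e$gene_id), unique(e$metabolite_id)),
    kind = c(rep("gene", length(unique(e$gene_id))),
             rep("metabolite", length(unique(e$metabolite_id)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = e), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  s <- network_summary(x)
  cat("bipartite_network: ", s$n_nodes, " nodes (", s$n_genes, " genes, ",
      s$n_metabolites, " metabolites), ", s$n_edges, " edges (",
      s$n_positive, " positive, ", s$n_negative, " negative)\n", sep = "")
  invisible(x)
}

#' Summarize a bipartite network
#'
#' @param net a \code{\link{build_network}} result.
#' @return list with counts \code{n_nodes}, \code{n_genes},
#'   \code{n_metabolites}, \code{n_edges}, \code{n_positive},
#'   \code{n_negative}, and \code{degree} (data.frame \code{id},
#'   \code{kind}, \code{degree}, sorted by degree descending then id).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  e <- net$edges
  deg <- table(factor(c(e$gene_id, e$metabolite_id),
                      levels = net$nodes$id))
  degree <- data.frame(id = net$nodes$id, kind = net$nodes$kind,
                       degree = as.integer(deg[net$nodes$id]),
                       stringsAsFactors = FALSE)
  degree <- degree[order(-degree$degree, degree$id), , drop = FALSE]
  rownames(degree) <- NULL
  list(n_nodes = nrow(net$nodes),
       n_genes = sum(net$nodes$kind == "gene"),
       n_metabolites = sum(net$nodes$kind == "metabolite"),
       n_edges = nrow(e),
       n_positive = sum(e$sign == "positive"),
       n_negative = sum(e$sign == "negative"),
       degree = degree)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$gene_id, to = net$edges$metabolite_id,
                   pcc = net$edges$pcc, sign = net$edges$sign,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, kind = net$nodes$kind,
                          stringsAsFactors = FALSE))
  g
}

#' Export a bipartite network
#'
#' GraphML (with node \code{kind} and edge \code{sign}/\code{pcc}
#' attributes; re-importable via \code{\link{read_network_graphml}}), SIF
#' (\code{gene pos|neg metabolite}, one line per edge), or a plain edge TSV.
#'
#' @param net a \code{\link{build_network}} result.
#' @param path output file.
#' @param format \code{"graphml"}, \code{"sif"} or \code{"edge_tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif",
                                                 "edge_tsv")) {
  stopifnot(inherits(net, "bipartite_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$gene_id,
                     ifelse(net$edges$sign == "positive", "pos", "neg"),
                     net$edges$metabolite_id)
    writeLines(lines, path)
  } else {
    write_table(net$edges, path)
  }
  invisible(path)
}

#' Re-import a GraphML network written by \code{\link{export_network}}
#'
#' @param path GraphML file.
#' @return a \code{bipartite_network}.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, kind = igraph::V(g)$kind,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  kind1 <- nodes$kind[match(el[, 1], nodes$id)]
  edges <- data.frame(
    gene_id = ifelse(kind1 == "gene", el[, 1], el[, 2]),
    metabolite_id = ifelse(kind1 == "gene", el[, 2], el[, 1]),
    pcc = igraph::E(g)$pcc, sign = igraph::E(g)$sign,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "bipartite_network")
}
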