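#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k annotated-in-pathway features when n features are drawn without
#' replacement from a background of N features of which K are in the pathway.
#' This one-sided over-representation probability equals the one-sided
#' Fisher's exact test on the corresponding 2x2 table. Computed in log space
#' for numerical stability.
#'
#' @param k observed overlap (differential features in the pathway).
#' @param n differential features with any annotation.
#' @param K background features in the pathway.
#' @param N annotated background size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotone enforcement; the output preserves the
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order and length.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric (Fisher's exact) enrichment of a differential
#' feature set against the annotated background, with BH FDR across tested
#' pathways and the enrichment factor (k/n)/(K/N). The background is the set
#' of detected features carrying at least one pathway annotation; pathways
#' with no differential member are omitted from the report.
#'
#' @param significant character vector of differential feature ids (e.g. the
#'   DAMs of one comparison).
#' @param background character vector of all detected feature ids.
#' @param pathway_map named list feature_id -> character vector of pathway
#'   ids (see \code{\link{read_pathway_map}}).
#' @param pathway_names optional named character vector pathway_id -> name.
#' @param fdr_max significance flag threshold (default 0.05).
#' @param factor_definition \code{"relative"} (default, (k/n)/(K/N)) or
#'   \code{"coverage"} (k/K).
#' @return data.frame of class \code{enrichment_result}, sorted by p then
#'   pathway_id, with columns \code{pathway_id}, \code{pathway_name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p}, \code{fdr},
#'   \code{enrichment_factor}, \code{significant}.
#' @export
enrich_pathways <- function(significant, background, pathway_map,
                            pathway_names = NULL, fdr_max = 0.05,
                            factor_definition = c("relative", "coverage")) {
  factor_definition <- match.arg(factor_definition)
  significant <- unique(as.character(significant))
  background <- unique(as.character(background))
  miss <- setdiff(significant, background)
  if (length(miss))
    stop("significant features missing from background: ",
         paste(head(miss), collapse = ", "))
  pm <- pathway_map[names(pathway_map) %in% background]
  annotated <- names(pm)[lengths(pm) > 0]
  if (!length(annotated)) stop("no annotated features in the background")
  N <- length(annotated)
  sig_ann <- intersect(significant, annotated)
  n <- length(sig_ann)
  long <- data.frame(feature_id = rep(names(pm), lengths(pm)),
                     pathway_id = unlist(pm, use.names = FALSE),
                     stringsAsFactors = FALSE)
  Ktab <- table(long$pathway_id)
  ktab <- table(long$pathway_id[long$feature_id %in% sig_ann])
  paths <- names(ktab)[ktab > 0]
  if (!length(paths)) {
    out <- data.frame(pathway_id = character(), pathway_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      enrichment_factor = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  k <- as.integer(ktab[paths])
  K <- as.integer(Ktab[paths])
  p <- mapply(hypergeom_upper_tail, k = k, n = n, K = K, N = N)
  ef <- if (factor_definition == "relative") (k / n) / (K / N) else k / K
  out <- data.frame(
    pathway_id = paths,
    pathway_name = if (is.null(pathway_names)) paths
                   else ifelse(is.na(pathway_names[paths]), paths,
                               pathway_names[paths]),
    k = k, n = n, K = K, N = N, p = p, fdr = bh_fdr(p),
    enrichment_factor = ef,
    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$fdr < fdr_max
  out <- out[order(out$p, out$pathway_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pathways hit by both omics layers
#'
#' Intersects the metabolite-side and gene-side enrichment reports on
#' pathway id (each side contributes pathways with at least one differential
#' member), attaching both result sets.
#'
#' @param metabolite_results an \code{\link{enrich_pathways}} result.
#' @param gene_results an \code{\link{enrich_pathways}} result on the same
#'   pathway vocabulary.
#' @return data.frame with columns \code{pathway_id} plus the per-side
#'   \code{k}, \code{p}, \code{fdr}, \code{enrichment_factor} suffixed
#'   \code{_met} / \code{_gene}, sorted by the smaller of the two p-values.
#' @export
co_mapped_pathways <- function(metabolite_results, gene_results) {
  shared <- intersect(metabolite_results$pathway_id, gene_results$pathway_id)
  if (!length(shared))
    return(data.frame(pathway_id = character(), stringsAsFactors = FALSE))
  a <- metabolite_results[match(shared, metabolite_results$pathway_id), ]
  b <- gene_results[match(shared, gene_results$pathway_id), ]
  out <- data.frame(pathway_id = shared,
                    pathway_name = a$pathway_name,
                    k_met = a$k, p_met = a$p, fdr_met = a$fdr,
                    enrichment_factor_met = a$enrichment_factor,
                    k_gene = b$k, p_gene = b$p, fdr_gene = b$fdr,
                    enrichment_factor_gene = b$enrichment_factor,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(pmin(out$p_met, out$p_gene), out$pathway_id), , drop = FALSE]
}
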