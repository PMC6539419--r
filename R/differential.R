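#' Replace true zeros before ratio statistics
#'
#' Peak areas of undetected metabolites are recorded as 0, which makes fold
#' changes infinite. The default rule replaces every zero with half the
#' smallest positive value in the whole matrix; alternatively a constant
#' pseudocount is added to every cell.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param rule \code{"half_min_positive"} (default) or \code{"pseudocount"}.
#' @param pseudocount constant added when \code{rule = "pseudocount"}.
#' @return an \code{\link{abundance_matrix}} with no zero entries.
#' @export
impute_zeros <- function(x, rule = c("half_min_positive", "pseudocount"),
                         pseudocount = 1) {
  stopifnot(inherits(x, "abundance_matrix"))
  rule <- match.arg(rule)
  v <- x$values
  if (rule == "half_min_positive") {
    pos <- v[v > 0]
    if (!length(pos)) stop("all-zero matrix: cannot impute")
    v[v == 0] <- min(pos) / 2
  } else {
    v <- v + pseudocount
    if (any(v == 0)) stop("pseudocount left zero entries")
  }
  x$values <- v
  x
}

#' Per-feature fold change between two stages
#'
#' Fold change is the ratio of replicate means on the raw (imputed peak-area)
#' scale: \code{mean(test) / mean(ref)}, with \code{log2fc = log2(fc)}.
#'
#' @param x an imputed \code{\link{abundance_matrix}} (no zeros).
#' @param cmp a \code{\link{comparison_spec}}.
#' @return data.frame with columns \code{feature_id}, \code{fc},
#'   \code{log2fc}.
#' @export
fold_change <- function(x, cmp) {
  check_comparison(x, cmp)
  test_m <- rowMeans(x$values[, stage_columns(x, cmp$test_stage),
                              drop = FALSE])
  ref_m <- rowMeans(x$values[, stage_columns(x, cmp$ref_stage),
                             drop = FALSE])
  if (any(ref_m == 0))
    stop("zero reference-stage mean; run impute_zeros() first")
  fc <- test_m / ref_m
  data.frame(feature_id = rownames(x$values), fc = fc, log2fc = log2(fc),
             stringsAsFactors = FALSE, row.names = NULL)
}

# log2(x+1), mean-center, unit-variance scale (constant columns left centered)
plsda_preprocess <- function(values) {
  m <- t(log2p1(values))  # samples x features
  m <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(m, 2, sd)
  sds[sds == 0] <- 1
  sweep(m, 2, sds, "/")
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis of the two compared stages,
#' fitted by sequential NIPALS extraction on the log2(x+1), mean-centered,
#' unit-variance-scaled sample x feature matrix against the centered two-class
#' response. For a single response the NIPALS weight is the exact
#' \code{w = X'y / ||X'y||} direction; each component's score deflates both
#' the predictor block and the response. The sign convention makes the first
#' non-zero entry of each weight vector positive, so fits are deterministic.
#'
#' @param x an \code{\link{abundance_matrix}} (metabolome or transcriptome).
#' @param cmp a \code{\link{comparison_spec}}; both stages need >= 2
#'   replicates.
#' @param n_components number of latent components (default 2); truncated
#'   with a warning when the data rank is lower.
#' @return list of class \code{plsda_model} with \code{weights} (features x
#'   components, unit norm), \code{scores}, \code{loadings}, \code{ssy}
#'   (response sum of squares explained per component), \code{y} (centered
#'   response), \code{feature_id}, \code{samples}.
#' @export
fit_plsda <- function(x, cmp, n_components = 2) {
  check_comparison(x, cmp)
  cols <- c(stage_columns(x, cmp$test_stage), stage_columns(x, cmp$ref_stage))
  if (length(stage_columns(x, cmp$test_stage)) < 2 ||
      length(stage_columns(x, cmp$ref_stage)) < 2)
    stop("need >= 2 replicates per group for PLS-DA")
  X <- plsda_preprocess(x$values[, cols, drop = FALSE])
  grp <- colnames(x$values[, cols, drop = FALSE]) %in%
    stage_columns(x, cmp$test_stage)
  y <- ifelse(grp, 1, 0)
  y <- y - mean(y)
  p <- ncol(X)
  max_rank <- min(nrow(X) - 1L, p)
  if (n_components > max_rank) {
    warning("n_components reduced to data rank ", max_rank)
    n_components <- max_rank
  }
  W <- matrix(0, p, 0)
  TT <- matrix(0, nrow(X), 0)
  P <- matrix(0, p, 0)
  ssy <- numeric(0)
  Xr <- X
  yr <- y
  for (a in seq_len(n_components)) {
    wv <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break  # response variance exhausted
    wv <- wv / nw
    j <- which(abs(wv) > 1e-12)[1]
    if (wv[j] < 0) wv <- -wv
    tv <- drop(Xr %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(Xr, tv)) / tt
    cv <- sum(yr * tv) / tt
    ss_before <- sum(yr^2)
    yr <- yr - cv * tv
    Xr <- Xr - tcrossprod(tv, pv)
    W <- cbind(W, wv)
    TT <- cbind(TT, tv)
    P <- cbind(P, pv)
    ssy <- c(ssy, ss_before - sum(yr^2))
  }
  if (!ncol(W)) stop("no PLS component could be extracted")
  dimnames(W) <- list(colnames(X), paste0("comp", seq_len(ncol(W))))
  dimnames(P) <- dimnames(W)
  dimnames(TT) <- list(rownames(X), colnames(W))
  structure(list(weights = W, scores = TT, loadings = P, ssy = ssy,
                 y = y, residual = Xr, feature_id = colnames(X),
                 samples = rownames(X), comparison = cmp),
            class = "plsda_model")
}

#' Variable importance in projection (VIP)
#'
#' The standard Wold VIP over all extracted components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where p is the number of features and SSY_a the response sum of squares
#' explained by component a. Because the weight vectors are unit-norm, the
#' identity \eqn{\sum_j VIP_j^2 = p} holds exactly on every fit.
#'
#' @param model a \code{\link{fit_plsda}} model.
#' @return named numeric vector of VIP scores (one per feature).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (sum(model$ssy) <= 0)
    stop("model explains no response variance; VIP undefined")
  W <- model$weights  # already unit-norm columns
  p <- nrow(W)
  contrib <- sweep(W^2, 2, model$ssy, "*")
  vip <- sqrt(p * rowSums(contrib) / sum(model$ssy))
  stats::setNames(vip, rownames(W))
}

#' Per-feature two-group location test
#'
#' Two-sided t-test on \code{log2(x + 1)} replicate values, Welch (default)
#' or pooled-variance Student. Degenerate inputs use a deterministic
#' convention: when both groups have zero variance the p-value is 1 if the
#' group means are equal and 0 otherwise.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param cmp a \code{\link{comparison_spec}}.
#' @param test \code{"welch"} (default) or \code{"student"}.
#' @return data.frame with columns \code{feature_id}, \code{p}.
#' @export
feature_test <- function(x, cmp, test = c("welch", "student")) {
  check_comparison(x, cmp)
  test <- match.arg(test)
  a <- log2p1(x$values[, stage_columns(x, cmp$test_stage), drop = FALSE])
  b <- log2p1(x$values[, stage_columns(x, cmp$ref_stage), drop = FALSE])
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("need >= 2 replicates per group for the location test")
  p <- vapply(seq_len(nrow(a)), function(i) {
    ai <- a[i, ]; bi <- b[i, ]
    if (var(ai) == 0 && var(bi) == 0)
      return(if (isTRUE(all.equal(mean(ai), mean(bi)))) 1 else 0)
    t.test(ai, bi, var.equal = (test == "student"))$p.value
  }, numeric(1))
  data.frame(feature_id = rownames(x$values), p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign differential status from fold change, VIP and p-value
#'
#' A feature is \code{up} when \code{fc >= fc_up} and \code{vip >= vip_min}
#' (and \code{p < p_max} when the p-filter is on), \code{down} when
#' \code{fc <= fc_down} under the same VIP/p conditions, else
#' \code{unchanged}. All threshold boundaries are inclusive as stated
#' (\code{>= 2}, \code{<= 0.5}, \code{>= 1}); the p cut is strict
#' (\code{< 0.05}).
#'
#' @param fc numeric fold changes.
#' @param vip numeric VIP scores, or NULL to skip the VIP filter (gene side).
#' @param p numeric p-values (raw or adjusted), or NULL.
#' @param fc_up,fc_down,vip_min,p_max thresholds (defaults 2, 0.5, 1, 0.05).
#' @param use_p apply the p-filter (default TRUE when \code{p} is supplied).
#' @return character vector in \code{c("up","down","unchanged")}.
#' @export
call_status <- function(fc, vip = NULL, p = NULL,
                        fc_up = 2, fc_down = 0.5, vip_min = 1, p_max = 0.05,
                        use_p = !is.null(p)) {
  n <- length(fc)
  ok_vip <- if (is.null(vip)) rep(TRUE, n) else vip >= vip_min
  ok_p <- if (use_p) {
    if (is.null(p)) stop("use_p = TRUE but no p-values supplied")
    p < p_max
  } else rep(TRUE, n)
  ifelse(fc >= fc_up & ok_vip & ok_p, "up",
         ifelse(fc <= fc_down & ok_vip & ok_p, "down", "unchanged"))
}

#' Differential accumulation analysis of a metabolome comparison
#'
#' The complete per-comparison metabolite workflow: zero imputation, raw-scale
#' fold change, two-class PLS-DA VIP on normalized values, optional
#' location test, and status calls under the standard rule (fold change
#' >= 2 or <= 0.5 with VIP >= 1, optionally p < 0.05).
#'
#' @param x metabolite \code{\link{abundance_matrix}} (raw, may contain
#'   zeros).
#' @param cmp a \code{\link{comparison_spec}}.
#' @param n_components PLS-DA components for VIP (default 2).
#' @param use_p apply the p-filter (default TRUE).
#' @param test location test flavor, see \code{\link{feature_test}}.
#' @param fc_up,fc_down,vip_min,p_max thresholds.
#' @param impute_rule zero-handling rule, see \code{\link{impute_zeros}}.
#' @return data.frame of class \code{differential_result} with columns
#'   \code{feature_id}, \code{comparison}, \code{fc}, \code{log2fc},
#'   \code{vip}, \code{p}, \code{fdr} (BH across features), \code{status}.
#' @export
differential_analysis <- function(x, cmp, n_components = 2, use_p = TRUE,
                                  test = "welch",
                                  fc_up = 2, fc_down = 0.5,
                                  vip_min = 1, p_max = 0.05,
                                  impute_rule = "half_min_positive") {
  check_comparison(x, cmp)
  xi <- impute_zeros(x, rule = impute_rule)
  fcres <- fold_change(xi, cmp)
  model <- fit_plsda(xi, cmp, n_components = n_components)
  vip <- vip_scores(model)[fcres$feature_id]
  tst <- feature_test(xi, cmp, test = test)
  fdr <- p.adjust(tst$p, method = "BH")
  status <- call_status(fcres$fc, vip = vip, p = tst$p,
                        fc_up = fc_up, fc_down = fc_down,
                        vip_min = vip_min, p_max = p_max, use_p = use_p)
  out <- data.frame(feature_id = fcres$feature_id,
                    comparison = format(cmp),
                    fc = fcres$fc, log2fc = fcres$log2fc,
                    vip = unname(vip), p = tst$p, fdr = fdr,
                    status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Differential expression calls for the gene side
#'
#' Genes use the conventional |log2FC| >= 1 with BH-adjusted p < 0.05 rule
#' (no VIP). Alternatively a precomputed status table (columns
#' \code{feature_id}, \code{status}) is passed through unchanged, supporting
#' externally derived DEG sets.
#'
#' @param x gene \code{\link{abundance_matrix}}, or NULL when
#'   \code{precomputed} is given.
#' @param cmp a \code{\link{comparison_spec}}.
#' @param lfc_min minimum |log2FC| (default 1).
#' @param fdr_max BH-adjusted p threshold (default 0.05).
#' @param test location test flavor.
#' @param precomputed optional data.frame with \code{feature_id},
#'   \code{status} (and optionally \code{log2fc}) to pass through.
#' @return data.frame of class \code{differential_result} (columns as in
#'   \code{\link{differential_analysis}}, \code{vip} = NA).
#' @export
deg_analysis <- function(x, cmp, lfc_min = 1, fdr_max = 0.05,
                         test = "welch", precomputed = NULL) {
  if (!is.null(precomputed)) {
    need <- c("feature_id", "status")
    if (!all(need %in% names(precomputed)))
      stop("precomputed DEG table needs columns: ",
           paste(need, collapse = ", "))
    if (!all(precomputed$status %in% c("up", "down", "unchanged")))
      stop("invalid status in precomputed DEG table")
    out <- data.frame(
      feature_id = precomputed$feature_id,
      comparison = if (missing(cmp)) NA_character_ else format(cmp),
      fc = if ("log2fc" %in% names(precomputed)) 2^precomputed$log2fc
           else NA_real_,
      log2fc = if ("log2fc" %in% names(precomputed)) precomputed$log2fc
               else NA_real_,
      vip = NA_real_, p = NA_real_, fdr = NA_real_,
      status = precomputed$status,
      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("differential_result", "data.frame")
    return(out)
  }
  check_comparison(x, cmp)
  xi <- impute_zeros(x)
  fcres <- fold_change(xi, cmp)
  tst <- feature_test(xi, cmp, test = test)
  fdr <- p.adjust(tst$p, method = "BH")
  status <- ifelse(fcres$log2fc >= lfc_min & fdr < fdr_max, "up",
                   ifelse(fcres$log2fc <= -lfc_min & fdr < fdr_max, "down",
                          "unchanged"))
  out <- data.frame(feature_id = fcres$feature_id, comparison = format(cmp),
                    fc = fcres$fc, log2fc = fcres$log2fc, vip = NA_real_,
                    p = tst$p, fdr = fdr, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Three-way Venn partition of differential feature sets
#'
#' Splits the union of three differential sets (e.g. the DAMs of the three
#' stage comparisons) into the seven disjoint Venn regions.
#'
#' @param sets named list of three character vectors.
#' @return named list of seven disjoint character vectors; names are
#'   \code{"A_only"}-style labels built from the input names
#'   (\code{A}, \code{B}, \code{C} = the three list names).
#' @export
venn_partition <- function(sets) {
  if (length(sets) != 3) stop("venn_partition needs exactly 3 sets")
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c <- unique(sets[[3]])
  nm <- names(sets)
  out <- list(
    setdiff(setdiff(a, b), c),
    setdiff(setdiff(b, a), c),
    setdiff(setdiff(c, a), b),
    setdiff(intersect(a, b), c),
    setdiff(intersect(a, c), b),
    setdiff(intersect(b, c), a),
    intersect(intersect(a, b), c))
  names(out) <- c(paste0(nm, "_only"),
                  paste0(nm[1], "&", nm[2]),
                  paste0(nm[1], "&", nm[3]),
                  paste0(nm[2], "&", nm[3]),
                  paste(nm, collapse = "&"))
  out
}

#' Compound-class composition of a feature set
#'
#' Counts and fractions per compound class for a feature set (e.g. the DAMs
#' of one comparison), in descending count order. Features missing from the
#' annotation count as \code{"other"}.
#'
#' @param features character vector of feature ids.
#' @param annotation a \code{\link{feature_annotation}} data.frame.
#' @param top_k optionally keep only the k most frequent classes.
#' @return data.frame with columns \code{feature_class}, \code{count},
#'   \code{fraction} (fractions over the full set sum to 1 before
#'   \code{top_k} truncation).
#' @export
class_composition <- function(features, annotation, top_k = NULL) {
  features <- unique(features)
  if (!length(features))
    return(data.frame(feature_class = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  cls <- annotation$feature_class[match(features, annotation$feature_id)]
  cls[is.na(cls)] <- "other"
  tab <- sort(table(cls), decreasing = TRUE)
  out <- data.frame(feature_class = names(tab),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / length(features),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

# pairwise 1 - Pearson distance between matrix rows; constant rows are at
# the maximum distance (2) from everything else
correlation_distance <- function(m) {
  sds <- apply(m, 1, sd)
  d <- matrix(2, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  ok <- sds > 0
  if (sum(ok) >= 2)
    d[ok, ok] <- 1 - suppressWarnings(cor(t(m[ok, , drop = FALSE])))
  diag(d) <- 0
  d
}

#' Hierarchical clustering order for heat maps
#'
#' Agglomerative clustering of features (and optionally samples) with
#' 1 - Pearson correlation distance and average linkage, the common choice
#' for omics heat maps. Constant profiles sit at the maximum distance (2)
#' from all others. Returns the leaf orders and merge structure needed to
#' render a clustered heat map.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param features feature ids to cluster (default all); needs >= 2.
#' @param transform \code{"log"} (default) or \code{"none"}.
#' @param cluster_samples also cluster sample columns (default TRUE).
#' @return list with \code{feature_order}, \code{sample_order} (character
#'   vectors), and the underlying \code{stats::hclust} trees
#'   \code{feature_tree}, \code{sample_tree} (NULL when not clustered).
#' @export
hca_order <- function(x, features = NULL, transform = c("log", "none"),
                      cluster_samples = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- apply_transform(x$values, transform)
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("need >= 2 features to cluster")
  ft <- hclust(as.dist(correlation_distance(v)), method = "average")
  st <- NULL
  sample_order <- colnames(v)
  if (cluster_samples && ncol(v) >= 2) {
    st <- hclust(as.dist(correlation_distance(t(v))), method = "average")
    sample_order <- colnames(v)[st$order]
  }
  list(feature_order = rownames(v)[ft$order], sample_order = sample_order,
       feature_tree = ft, sample_tree = st)
}

#' Volcano-plot data table
#'
#' Plot-ready table of log2 fold change against -log10 p with the status
#' calls, one row per feature.
#'
#' @param result a \code{\link{differential_analysis}} result.
#' @return data.frame with \code{feature_id}, \code{log2fc},
#'   \code{neg_log10_p}, \code{status}.
#' @export
volcano_data <- function(result) {
  stopifnot(inherits(result, "differential_result"))
  data.frame(feature_id = result$feature_id, log2fc = result$log2fc,
             neg_log10_p = -log10(result$p), status = result$status,
             stringsAsFactors = FALSE, row.names = NULL)
}
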