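log2p1 <- function(x) log2(x + 1)

apply_transform <- function(values, transform = c("log", "none")) {
  transform <- match.arg(transform)
  if (transform == "log") log2p1(values) else values
}

#' Sample-sample Pearson correlation matrix
#'
#' Pairwise Pearson correlation between sample columns across all features,
#' the standard replicate-reproducibility check for targeted metabolomics.
#' Peak areas span orders of magnitude, so the default correlates
#' \code{log2(x + 1)} values.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param transform \code{"log"} (default, \code{log2(x+1)}) or \code{"none"}.
#' @return symmetric samples x samples matrix of Pearson r with unit diagonal.
#'   Pairs involving a constant sample column are \code{NA} (flagged
#'   undefined, never silently 0), with a warning naming the samples.
#' @export
sample_correlation_matrix <- function(x, transform = c("log", "none")) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- apply_transform(x$values, transform)
  if (nrow(v) < 2) stop("need >= 2 features for sample correlation")
  sds <- apply(v, 2, sd)
  const <- sds == 0
  if (any(const))
    warning("constant sample column(s), correlations undefined: ",
            paste(colnames(v)[const], collapse = ", "))
  r <- suppressWarnings(cor(v, method = "pearson"))
  diag(r) <- 1
  r
}

#' PCA variance decomposition of the sample cloud
#'
#' Singular-value decomposition of the (optionally log-transformed) centered
#' sample x feature matrix; the variance fraction of component k is
#' sigma_k^2 / sum(sigma^2). Used to report how much of the between-sample
#' variation the leading components capture and whether stages separate.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param transform \code{"log"} (default) or \code{"none"}.
#' @param center,scale. passed to the decomposition; defaults center TRUE,
#'   scale FALSE. Constant features are left unscaled when \code{scale.} is
#'   TRUE.
#' @param n_components number of components to report scores for (default all).
#' @return list of class \code{qc_report}: \code{variance_fractions} (all
#'   components, summing to 1), \code{scores} (samples x reported components),
#'   \code{sample_correlation} is not included here (see
#'   \code{\link{sample_correlation_matrix}}).
#' @export
pca_variance <- function(x, transform = c("log", "none"),
                         center = TRUE, scale. = FALSE,
                         n_components = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (ncol(x$values) < 2) stop("need >= 2 samples for PCA")
  m <- t(apply_transform(x$values, transform))  # samples x features
  m <- scale(m, center = center, scale = FALSE)
  if (isTRUE(scale.)) {
    sds <- apply(m, 2, sd)
    sds[sds == 0] <- 1
    m <- sweep(m, 2, sds, "/")
  }
  sv <- La.svd(m)
  ev <- sv$d^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  k <- min(if (is.null(n_components)) length(ev) else n_components,
           length(ev))
  scores <- m %*% t(sv$vt)[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(variance_fractions = frac, scores = scores),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  k <- min(5, length(x$variance_fractions))
  cat("PCA variance fractions (first ", k, "): ",
      paste(sprintf("%.1f%%", 100 * x$variance_fractions[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
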