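#' @importFrom stats cor sd var phyper p.adjust t.test hclust as.dist
#'   setNames rnorm
#' @importFrom utils read.delim write.table head
NULL

#' Construct a sample design
#'
#' A sample design describes the columns of an abundance matrix: one row per
#' sample, with an ordered developmental-stage factor and a replicate index.
#' The default stage order \code{NEC < PEC < GE} follows the three culture
#' stages of cotton somatic embryogenesis (nonembryogenic calli, primary
#' embryogenic calli, globular-stage embryos), but any ordered label set works.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param stage character vector of stage labels, same length.
#' @param replicate positive integer vector of replicate indices within stage.
#' @param stage_levels ordered set of stage labels; defaults to the unique
#'   stages in order of first appearance.
#' @return A \code{data.frame} of class \code{sample_design} with columns
#'   \code{sample_id}, \code{stage} (factor with the declared level order) and
#'   \code{replicate}.
#' @export
sample_design <- function(sample_id, stage, replicate,
                          stage_levels = unique(stage)) {
  sample_id <- as.character(sample_id)
  stage <- as.character(stage)
  if (length(sample_id) != length(stage) || length(stage) != length(replicate))
    stop("sample_id, stage and replicate must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (!all(stage %in% stage_levels))
    stop("stage labels outside declared stage_levels: ",
         paste(setdiff(stage, stage_levels), collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  d <- data.frame(sample_id = sample_id,
                  stage = factor(stage, levels = stage_levels),
                  replicate = replicate,
                  stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Construct a feature annotation table
#'
#' @param feature_id unique character identifiers (metabolite index ids such
#'   as \code{"pmb0981"}, or gene ids such as \code{"Gh_D05G1280"}).
#' @param name human-readable names (compound or gene names).
#' @param feature_class compound class (e.g. \code{"Flavonol"}) or
#'   \code{"gene"}.
#' @return data.frame with columns \code{feature_id}, \code{name},
#'   \code{feature_class}.
#' @export
feature_annotation <- function(feature_id,
                               name = feature_id,
                               feature_class = "other") {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop("duplicate feature_id: ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  data.frame(feature_id = feature_id,
             name = rep_len(as.character(name), length(feature_id)),
             feature_class = rep_len(as.character(feature_class),
                                     length(feature_id)),
             stringsAsFactors = FALSE)
}

#' Construct an abundance matrix
#'
#' The central container of the pipeline: a features x samples matrix of
#' non-negative measurements (metabolite peak areas or gene expression units)
#' together with feature annotation and the sample design. Values are aligned
#' to the design by \code{sample_id}, never by column position.
#'
#' @param values numeric matrix, features in rows, samples in columns; column
#'   names must equal the design's sample ids (any order), row names the
#'   feature ids.
#' @param annotation a \code{\link{feature_annotation}} data.frame covering all
#'   row names.
#' @param design a \code{\link{sample_design}}.
#' @return An object of class \code{abundance_matrix}: a list with elements
#'   \code{values} (matrix, columns ordered as in the design),
#'   \code{annotation} and \code{design}.
#' @export
abundance_matrix <- function(values, annotation, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in matrix rows")
  if (!setequal(colnames(values), design$sample_id))
    stop("matrix column names do not match design sample ids")
  bad <- !is.finite(values)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-finite value at feature '", rownames(values)[i[1]],
         "', sample '", colnames(values)[i[2]], "'")
  }
  if (any(values < 0)) {
    i <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value at feature '", rownames(values)[i[1]],
         "', sample '", colnames(values)[i[2]], "'")
  }
  if (!all(rownames(values) %in% annotation$feature_id))
    stop("features missing from annotation: ",
         paste(head(setdiff(rownames(values), annotation$feature_id)),
               collapse = ", "))
  # align: columns by design order, annotation by matrix row order
  values <- values[, design$sample_id, drop = FALSE]
  annotation <- annotation[match(rownames(values), annotation$feature_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(values = values, annotation = annotation, design = design),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("stages: ",
      paste(sprintf("%s(n=%d)", levels(x$design$stage),
                    tabulate(x$design$stage)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

stage_columns <- function(x, stage) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!stage %in% levels(x$design$stage))
    stop("unknown stage label '", stage, "'")
  x$design$sample_id[x$design$stage == stage]
}

#' Define a two-stage comparison
#'
#' @param test_stage numerator stage label (e.g. \code{"PEC"}).
#' @param ref_stage denominator stage label (e.g. \code{"NEC"}).
#' @return list of class \code{comparison_spec}; printed as
#'   \code{"TEST_vs_REF"}.
#' @export
comparison_spec <- function(test_stage, ref_stage) {
  test_stage <- as.character(test_stage)[1]
  ref_stage <- as.character(ref_stage)[1]
  if (identical(test_stage, ref_stage))
    stop("test and reference stage must differ")
  structure(list(test_stage = test_stage, ref_stage = ref_stage),
            class = "comparison_spec")
}

#' @export
format.comparison_spec <- function(x, ...)
  paste0(x$test_stage, "_vs_", x$ref_stage)

#' @export
print.comparison_spec <- function(x, ...) {
  cat("comparison: ", format(x), "\n", sep = "")
  invisible(x)
}

check_comparison <- function(x, cmp) {
  stopifnot(inherits(cmp, "comparison_spec"))
  for (s in c(cmp$test_stage, cmp$ref_stage))
    if (!s %in% levels(x$design$stage))
      stop("comparison stage '", s, "' not present in design")
  invisible(cmp)
}

# ---- readers / writers ------------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read a sample-design table
#'
#' Expects a tab-separated file with header \code{sample_id}, \code{stage},
#' \code{replicate}. Stage order is taken from first appearance unless
#' \code{stage_levels} is given.
#'
#' @param path file path.
#' @param stage_levels optional explicit stage order.
#' @return a \code{\link{sample_design}}.
#' @export
read_design <- function(path, stage_levels = NULL) {
  d <- read_tsv_checked(path)
  need <- c("sample_id", "stage", "replicate")
  if (!all(need %in% names(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (is.null(stage_levels)) stage_levels <- unique(d$stage)
  sample_design(d$sample_id, d$stage, d$replicate, stage_levels)
}

#' Read an abundance table
#'
#' Reads a tab-separated table whose leading columns are feature annotation
#' (at least \code{feature_id}; optionally \code{name} and
#' \code{feature_class}) followed by one numeric column per sample. Sample
#' columns are matched to the design by \code{sample_id}, so their order in
#' the file is irrelevant.
#'
#' @param path file path.
#' @param design a \code{\link{sample_design}} naming the expected samples.
#' @return an \code{\link{abundance_matrix}}.
#' @export
read_abundance <- function(path, design) {
  d <- read_tsv_checked(path)
  if (!"feature_id" %in% names(d))
    stop("abundance table must have a 'feature_id' column")
  if (anyDuplicated(d$feature_id))
    stop("duplicate feature_id in ", path, ": ",
         paste(unique(d$feature_id[duplicated(d$feature_id)]),
               collapse = ", "))
  miss <- setdiff(design$sample_id, names(d))
  if (length(miss))
    stop("sample columns missing from ", path, ": ",
         paste(miss, collapse = ", "))
  vals <- d[, design$sample_id, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v))) {
      i <- which(is.na(v))[1]
      stop("non-numeric or missing cell at feature '", d$feature_id[i],
           "', sample '", names(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- d$feature_id
  ann <- feature_annotation(
    d$feature_id,
    name = if ("name" %in% names(d)) d$name else d$feature_id,
    feature_class = if ("feature_class" %in% names(d)) d$feature_class
                    else "other")
  abundance_matrix(m, ann, design)
}

#' Write an abundance matrix to a TSV file
#'
#' Inverse of \code{\link{read_abundance}}: annotation columns first, then one
#' column per sample in design order.
#'
#' @param x an \code{\link{abundance_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  out <- cbind(x$annotation, as.data.frame(x$values, check.names = FALSE))
  write_table(out, path)
}

#' Read a feature-to-pathway map
#'
#' Two-column tab-separated file, one \code{(feature_id, pathway_id)} pair per
#' row, with or without a header. Features may occur on multiple rows.
#'
#' @param path file path.
#' @return a named list: \code{feature_id} to character vector of pathway ids.
#'   Features absent from the file are simply absent (treated as unannotated).
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 2L)) {
    bad <- which(nfld != 2L)[1]
    stop("malformed pathway map row at line ", bad, ": expected 2 columns, got ",
         nfld[bad])
  }
  m <- do.call(rbind, parts)
  # tolerate a header row
  if (identical(tolower(m[1, 1]), "feature_id")) m <- m[-1, , drop = FALSE]
  if (!nrow(m)) return(structure(list(), names = character()))
  split(m[, 2], factor(m[, 1], levels = unique(m[, 1])))
}

#' Write a result table
#'
#' Writes any result data.frame as UTF-8 tab-separated text with a header row
#' and stable column order; \code{\link{read_result_table}} reproduces it.
#'
#' @param records data.frame of results.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a result table written by \code{\link{write_table}}
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_result_table <- function(path) read_tsv_checked(path)
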