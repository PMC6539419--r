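#' Curated reference tables from the cotton somatic-embryogenesis literature
#'
#' Verbatim transcriptions of published worked-example tables for the
#' NEC/PEC/GE staged design, shipped as plain TSV under
#' \code{inst/extdata}:
#' \describe{
#'   \item{\code{purine_dams}}{differentially accumulated purine-metabolism
#'     metabolites of the embryogenic-differentiation comparison (PEC vs
#'     NEC), with printed fold change, log2 fold change and direction.}
#'   \item{\code{flavonoid_dams}}{differentially accumulated
#'     flavonoid-biosynthesis metabolites of the somatic-embryo-development
#'     comparison (GE vs PEC).}
#'   \item{\code{purine_pairs}}{classic somatic-embryogenesis gene to
#'     purine-metabolite correlation pairs (PEC vs NEC) with PCC of
#'     exactly +1 or -1; 81 pairs over 11 genes and 11 metabolites.}
#'   \item{\code{flavonoid_pairs}}{classic gene to flavonoid-metabolite
#'     pairs (GE vs PEC); 13 pairs over 5 genes and 7 metabolites.}
#'   \item{\code{purine_deg_pairs}}{representative upregulated genes paired
#'     with purine metabolites (PEC vs NEC).}
#' }
#' Values are kept exactly as printed, including one internally inconsistent
#' pair (the BBM gene carries a positive log2 fold change yet PCC = -1
#' against upregulated metabolites); no corrections are applied.
#'
#' The \code{log2fc} columns retain their printed precision: the returned
#' data.frame carries an attribute \code{printed_decimals} (for the DAM
#' tables) giving the number of printed decimal places per row, so worked
#' examples can be checked at exactly the published resolution.
#'
#' @param name one of \code{"purine_dams"}, \code{"flavonoid_dams"},
#'   \code{"purine_pairs"}, \code{"flavonoid_pairs"},
#'   \code{"purine_deg_pairs"}.
#' @return data.frame.
#' @export
reference_table <- function(name = c("purine_dams", "flavonoid_dams",
                                     "purine_pairs", "flavonoid_pairs",
                                     "purine_deg_pairs")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "metranet")
  if (!nzchar(path)) stop("packaged table not found: ", name)
  d <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE, quote = "",
                  colClasses = "character")
  num <- intersect(c("fc", "log2fc", "gene_log2fc", "metabolite_log2fc",
                     "pcc"), names(d))
  if ("log2fc" %in% names(d)) {
    dec <- vapply(d$log2fc, function(s) {
      dot <- regexpr(".", s, fixed = TRUE)
      if (dot < 0) 0L else nchar(s) - dot
    }, integer(1), USE.NAMES = FALSE)
    attr(d, "printed_decimals") <- dec
  }
  for (col in num) d[[col]] <- as.numeric(d[[col]])
  d
}
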