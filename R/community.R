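#' Convert an OTU count table to relative abundances
#'
#' @param counts Numeric matrix, samples x taxa, non-negative with positive
#'   row sums.
#' @return Matrix of the same shape; rows sum to 1.
#' @export
to_relative <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  counts / totals
}

#' Filter an OTU table for community analysis
#'
#' Removes taxa whose taxonomy path matches any of the organelle/eukaryote
#' labels (substring match), then removes taxa whose average relative
#' abundance across samples falls below `min_abundance` (0.1% by default;
#' the threshold is inclusive). Relative abundances used for the mean test
#' are recomputed after organelle removal but taxa abundances are not
#' renormalized afterwards unless counts are requested as relative.
#'
#' @param counts Numeric matrix, samples x taxa (counts or relative
#'   abundances), with taxa names in `colnames`.
#' @param taxonomy Character vector of taxonomy paths, one per taxon
#'   (defaults to `colnames(counts)`).
#' @param min_abundance Minimum mean relative abundance (default 0.001).
#' @param exclude_labels Labels marking non-bacterial taxa.
#' @return The filtered matrix with a `taxonomy` attribute.
#' @export
filter_taxa <- function(counts, taxonomy = colnames(counts),
                        min_abundance = 0.001,
                        exclude_labels = c("Chloroplast", "Mitochondria",
                                           "Eukaryota")) {
  if (is.null(taxonomy)) stop("taxonomy labels are required")
  stopifnot(length(taxonomy) == ncol(counts))
  organelle <- Reduce(`|`, lapply(exclude_labels, function(lab) {
    grepl(lab, taxonomy, fixed = TRUE)
  }))
  counts <- counts[, !organelle, drop = FALSE]
  taxonomy <- taxonomy[!organelle]
  rel <- to_relative(counts)
  keep <- colMeans(rel) >= min_abundance
  if (!any(keep)) stop("no taxa left after abundance filtering")
  out <- counts[, keep, drop = FALSE]
  attr(out, "taxonomy") <- taxonomy[keep]
  out
}

#' Log-transform and standardize environmental variables
#'
#' Applies the natural log and then a per-column z-score, the standard
#' preparation before Euclidean-distance ordination of environmental data.
#'
#' @param env Numeric matrix or data frame, samples x variables, strictly
#'   positive (or supply `offset`).
#' @param offset Constant added before the log for variables containing
#'   zeros; `NULL` (default) rejects non-positive values.
#' @return Matrix of transformed variables; each column has mean 0 and
#'   variance 1.
#' @export
transform_env <- function(env, offset = NULL) {
  env <- as.matrix(env)
  if (!is.null(offset)) env <- env + offset
  if (any(env <= 0))
    stop("environmental variables must be positive before log transform; ",
         "use `offset` if zeros are expected")
  lx <- log(env)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(env)[sds == 0], collapse = ", "))
  scale(lx)[, , drop = FALSE]
}
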