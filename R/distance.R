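#' Sample-by-sample dissimilarity matrix
#'
#' Builds the dissimilarities used throughout the pipeline: Euclidean for
#' environmental data, Hellinger for community data (Euclidean distance of
#' row-wise square-rooted proportions), and Bray-Curtis (optionally on
#' square-root transformed intensities) for DOM composition.
#'
#' @param x Numeric matrix, samples x variables.
#' @param metric One of `"euclidean"`, `"bray_curtis"`, `"hellinger"`.
#' @param transform Applied before the metric: `"none"`, `"sqrt"`, or
#'   `"hellinger"` (row-proportion square root).
#' @return A symmetric `matrix` of dissimilarities with sample labels.
#' @export
sample_distance <- function(x,
                            metric = c("euclidean", "bray_curtis",
                                       "hellinger"),
                            transform = c("none", "sqrt", "hellinger")) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples")
  if (metric %in% c("bray_curtis", "hellinger") && any(x < 0))
    stop("negative entries are not allowed for ", metric)
  x <- switch(transform,
              none = x,
              sqrt = sqrt(x),
              hellinger = vegan::decostand(x, method = "hellinger"))
  d <- switch(metric,
    euclidean = dist(x),
    bray_curtis = vegan::vegdist(x, method = "bray"),
    hellinger = dist(vegan::decostand(x, method = "hellinger"))
  )
  as.matrix(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of -d^2/2 followed by
#' eigen-decomposition. Axes are sorted by decreasing eigenvalue;
#' negative eigenvalues (possible for semi-metric input such as
#' Bray-Curtis) are reported unmodified and no correction is applied.
#'
#' @param d Symmetric dissimilarity matrix.
#' @return A list of class `ordination`: `coordinates` (samples x axes,
#'   scaled so squared axis norms equal the eigenvalues), `eigenvalues`,
#'   and `constrained = FALSE`. Only axes with eigenvalue above `1e-8 *`
#'   the largest eigenvalue carry coordinates.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-8
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 constrained = FALSE),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  kind <- if (isTRUE(x$constrained)) "Constrained ordination" else "PCoA"
  pos <- x$eigenvalues[x$eigenvalues > 0]
  cat(kind, "with", ncol(x$coordinates), "axes;",
      "first axis explains",
      sprintf("%.1f%%", 100 * pos[1] / sum(pos)), "\n")
  invisible(x)
}

# Gower-centered matrix G = -(I - 11'/n) d^2/2 (I - 11'/n)
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(d)
  rm_ <- rowMeans(a)
  a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
}
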