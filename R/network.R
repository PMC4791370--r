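#' Pairwise correlations among OTUs, DOM formulas and environment
#'
#' Computes all pairwise correlations between (and optionally within) the
#' supplied data blocks over their shared samples. Pearson p-values use
#' the exact t distribution; Spearman p-values use the t approximation on
#' the rank correlation for n >= 10 and exact enumeration of rank
#' permutations below. Zero-variance features are skipped.
#'
#' @param blocks Named list of numeric matrices (samples x features), all
#'   with identical row order; names give the node kind (e.g. `otu`,
#'   `formula`, `env`).
#' @param method `"pearson"` or `"spearman"`.
#' @param within Also correlate feature pairs inside the same block
#'   (default TRUE).
#' @return A data frame of correlation edges: `node_a`, `node_b`,
#'   `kind_a`, `kind_b`, `r`, `p`, `method`.
#' @export
pairwise_correlations <- function(blocks, method = c("pearson", "spearman"),
                                  within = TRUE) {
  method <- match.arg(method)
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  n <- nrow(blocks[[1]])
  if (n < 4) stop("need at least 4 shared samples")
  for (b in blocks) {
    if (nrow(b) != n) stop("blocks must share the same samples")
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    if (is.null(colnames(b))) colnames(b) <- paste0("v", seq_len(ncol(b)))
    b
  })
  kinds <- names(blocks)
  pairs <- list()
  for (i in seq_along(blocks)) {
    jmax <- if (within) i else i - 1L
    for (j in seq_len(jmax)) {
      pairs[[length(pairs) + 1L]] <-
        block_correlations(blocks[[i]], blocks[[j]], kinds[i], kinds[j],
                           method, same = i == j)
    }
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

block_correlations <- function(a, b, kind_a, kind_b, method, same) {
  keep_a <- apply(a, 2, var) > 0
  keep_b <- apply(b, 2, var) > 0
  a <- a[, keep_a, drop = FALSE]
  b <- b[, keep_b, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) return(NULL)
  n <- nrow(a)
  if (method == "spearman") {
    a <- apply(a, 2, rank)
    b <- apply(b, 2, rank)
  }
  r <- cor(a, b)
  p <- correlation_p(r, n, method)
  idx <- which(if (same) upper.tri(r) else matrix(TRUE, nrow(r), ncol(r)),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  data.frame(node_a = rownames(r)[idx[, 1]], node_b = colnames(r)[idx[, 2]],
             kind_a = kind_a, kind_b = kind_b,
             r = r[idx], p = p[idx], method = method)
}

correlation_p <- function(r, n, method) {
  if (method == "spearman" && n < 10) {
    return(apply_spearman_exact(r, n))
  }
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

# exact permutation null of the Spearman statistic for small n (no-tie
# reference distribution of the rank correlation)
apply_spearman_exact <- function(r, n) {
  ref <- spearman_exact_null(n)
  out <- r
  out[] <- vapply(as.vector(r), function(ri) {
    mean(abs(ref) >= abs(ri) - 1e-12)
  }, numeric(1))
  out
}

.spearman_null_cache <- new.env(parent = emptyenv())

spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]]))
    return(.spearman_null_cache[[key]])
  perms <- permutations_of(seq_len(n))
  base <- seq_len(n)
  vals <- apply(perms, 1, function(p) cor(base, p))
  .spearman_null_cache[[key]] <- vals
  vals
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

#' Holm-Bonferroni adjusted p-values
#'
#' Step-down family-wise error correction with enforced monotonicity,
#' clipped at 1.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Pivot table of significant correlations by coefficient magnitude
#'
#' Counts significant edges (p < alpha) in absolute-coefficient bins
#' `[0, 0.5) [0.5, 0.6) [0.6, 0.7) [0.7, 0.8) [0.8, 0.9) [0.9, 1]`,
#' split by node-kind pair and by correlation sign.
#'
#' @param edges Edge data frame from [pairwise_correlations()].
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per (kind pair, sign) plus per-pair
#'   totals: columns `pair`, `sign`, the six bins, `total`.
#' @export
pivot_bins <- function(edges, alpha = 0.05) {
  breaks <- c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  bin_names <- c("<0.5", "0.5-0.6", "0.6-0.7", "0.7-0.8", "0.8-0.9",
                 "0.9-1")
  sig <- edges[edges$p < alpha, , drop = FALSE]
  pair <- paste(pmin(sig$kind_a, sig$kind_b),
                pmax(sig$kind_a, sig$kind_b), sep = "-")
  bin <- cut(abs(sig$r), breaks = breaks, labels = bin_names,
             right = FALSE, include.lowest = TRUE)
  bin[abs(sig$r) >= 1] <- "0.9-1"  # |r| = 1 belongs to the closed top bin
  sign_ <- ifelse(sig$r >= 0, "pos", "neg")
  out <- list()
  for (pp in sort(unique(pair))) {
    for (ss in c("pos", "neg")) {
      sel <- pair == pp & sign_ == ss
      counts <- table(bin[sel])
      out[[length(out) + 1L]] <- data.frame(
        pair = pp, sign = ss, t(as.integer(counts[bin_names])),
        total = sum(sel))
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(pair = character(0), sign = character(0))
    for (bn in bin_names) res[[bn]] <- integer(0)
    res$total <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  names(res) <- c("pair", "sign", bin_names, "total")
  res[is.na(res)] <- 0L
  res
}

#' Build the high-correlation association network
#'
#' Keeps edges that are significant (p < alpha) and strong (|r| >=
#' r_threshold) and assembles them into an undirected graph whose nodes
#' are the incident features, annotated with node kind and optional
#' attributes (e.g. mean abundance for node size, compound class for node
#' color). Edge weight is |r| with a sign attribute.
#'
#' @param edges Edge data frame from [pairwise_correlations()].
#' @param r_threshold Absolute-correlation threshold (default 0.9).
#' @param alpha Significance level on the (optionally adjusted) p-values.
#' @param adjust `"none"` (default, raw p-values as in exploratory
#'   screening) or `"holm"` for family-wise correction.
#' @param node_attrs Optional data frame with column `node` plus arbitrary
#'   attribute columns to attach to the vertices.
#' @return An `igraph` graph (possibly empty); the multiplicity choice is
#'   recorded in the graph attribute `p_adjust`.
#' @export
build_network <- function(edges, r_threshold = 0.9, alpha = 0.05,
                          adjust = c("none", "holm"), node_attrs = NULL) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "holm") holm_bonferroni(edges$p) else edges$p
  keep <- p < alpha & abs(edges$r) >= r_threshold
  sel <- edges[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "p_adjust", adjust)
    return(g)
  }
  vertices <- unique(data.frame(
    name = c(sel$node_a, sel$node_b),
    kind = c(sel$kind_a, sel$kind_b)))
  if (!is.null(node_attrs)) {
    stopifnot("node" %in% names(node_attrs))
    vertices <- merge(vertices, node_attrs, by.x = "name", by.y = "node",
                      all.x = TRUE, sort = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sel$node_a, to = sel$node_b,
               weight = abs(sel$r), r = sel$r, p = p[keep],
               sign = ifelse(sel$r >= 0, "positive", "negative")),
    directed = FALSE, vertices = vertices)
  igraph::set_graph_attr(g, "p_adjust", adjust)
}

#' Export a network as GraphML plus node/edge TSV tables
#'
#' @param graph An `igraph` graph from [build_network()].
#' @param path Output path prefix; writes `<path>.graphml`,
#'   `<path>_nodes.tsv`, `<path>_edges.tsv`.
#' @return Invisibly, the three file paths.
#' @export
export_network <- function(graph, path) {
  graphml <- paste0(path, ".graphml")
  igraph::write_graph(graph, graphml, format = "graphml")
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  edges <- igraph::as_data_frame(graph, what = "edges")
  nodes_path <- paste0(path, "_nodes.tsv")
  edges_path <- paste0(path, "_edges.tsv")
  write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(graphml = graphml, nodes = nodes_path, edges = edges_path))
}

#' Report candidate collinear environmental variables
#'
#' Lists variable pairs whose Spearman correlation exceeds a threshold,
#' flagging multicollinearity ahead of distance-based modeling. Dropping
#' variables remains the analyst's decision.
#'
#' @param env Numeric matrix of environmental variables (samples x
#'   variables).
#' @param r_threshold Absolute Spearman correlation flagged (default 0.6).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of flagged pairs with `r` and `p`, strongest first.
#' @export
collinearity_report <- function(env, r_threshold = 0.6, alpha = 0.05) {
  edges <- pairwise_correlations(list(env = env), method = "spearman")
  flagged <- edges[abs(edges$r) > r_threshold & edges$p < alpha, ,
                   drop = FALSE]
  flagged <- flagged[order(-abs(flagged$r)),
                     c("node_a", "node_b", "r", "p"), drop = FALSE]
  rownames(flagged) <- NULL
  flagged
}
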