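# hat matrix of a centered predictor block (intercept implicit: G is
# centered, so predictors are centered rather than augmented)
hat_matrix <- function(x) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), q$pivot[seq_len(q$rank)])]
    stop("collinear predictor(s): ", paste(bad, collapse = ", "),
         "; drop collinear variables before modeling")
  }
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

distlm_r2 <- function(g, h) {
  r2 <- sum(h * g) / sum(diag(g))
  min(max(r2, 0), 1)  # guard rounding at saturated fits
}

adjusted_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

# pseudo-F from explained/residual traces; a saturated fit gives +Inf
pseudo_f <- function(tr_model, tr_total, m, df_resid) {
  resid <- max(tr_total - tr_model, 0)
  if (resid == 0) return(Inf)
  (tr_model / m) / (resid / df_resid)
}

#' Distance-based linear modeling (DistLM)
#'
#' Multivariate multiple regression of a dissimilarity matrix on
#' predictor variables. The Gower-centered matrix G is regressed on hat
#' matrices of predictor subsets: R^2 = tr(HGH)/tr(G), pseudo-F =
#' (tr(HGH)/m) / (tr((I-H)G(I-H))/(n-m-1)). Marginal (single-predictor)
#' tests use permutation of the sample identities of G; model building is
#' stepwise (alternating forward addition and backward elimination)
#' accepting moves that increase the adjusted R^2, stopping at a local
#' optimum.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param x Numeric matrix or data frame of predictors (samples x
#'   variables); columns must not be collinear.
#' @param permutations Permutations for the marginal and sequential tests.
#' @param seed Optional integer seed.
#' @return A list of class `distlm` with elements `selected` (ordered
#'   predictor names), `steps` (per-step data frame: predictor, pseudo-F,
#'   p, R2, adjusted R2), `marginal` (per-predictor data frame: pseudo-F,
#'   p, R2), `r2`, `adj_r2`, `n`, `permutations`, `seed`.
#' @export
distlm <- function(d, x, permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  x <- as.matrix(x)
  n <- nrow(d)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) >= n - 1)
    stop("number of predictors must be below n - 1")
  hat_matrix(x)  # validates full column rank, errors naming columns
  with_seed(seed)
  g <- gower_center(d)
  trg <- sum(diag(g))

  # marginal tests: each predictor alone
  marginal <- do.call(rbind, lapply(colnames(x), function(v) {
    h <- hat_matrix(x[, v, drop = FALSE])
    r2 <- distlm_r2(g, h)
    tr_obs <- sum(h * g)
    f_obs <- pseudo_f(tr_obs, trg, 1, n - 2)
    exceed <- 0L
    for (b in seq_len(permutations)) {
      p <- sample.int(n)
      tr_b <- sum(h * g[p, p])
      fb <- pseudo_f(tr_b, trg, 1, n - 2)
      if (fb >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    data.frame(predictor = v, pseudo_f = f_obs,
               p = (exceed + 1) / (permutations + 1), r2 = r2)
  }))

  # stepwise selection on adjusted R^2
  selected <- character(0)
  steps <- NULL
  best_adj <- 0  # empty model: R^2 = 0, adjusted R^2 = 0
  repeat {
    moved <- FALSE
    # forward: best addition
    remaining <- setdiff(colnames(x), selected)
    if (length(remaining) > 0 && length(selected) + 1 < n - 1) {
      adds <- vapply(remaining, function(v) {
        h <- hat_matrix(x[, c(selected, v), drop = FALSE])
        adjusted_r2(distlm_r2(g, h), n, length(selected) + 1)
      }, numeric(1))
      v <- remaining[which.max(adds)]
      if (max(adds) > best_adj + 1e-12) {
        step <- sequential_test(g, x, selected, v, n, trg, permutations)
        selected <- c(selected, v)
        best_adj <- max(adds)
        steps <- rbind(steps, step)
        moved <- TRUE
      }
    }
    # backward: best drop
    if (length(selected) > 1) {
      drops <- vapply(selected, function(v) {
        keep <- setdiff(selected, v)
        h <- hat_matrix(x[, keep, drop = FALSE])
        adjusted_r2(distlm_r2(g, h), n, length(keep))
      }, numeric(1))
      v <- selected[which.max(drops)]
      if (max(drops) > best_adj + 1e-12) {
        selected <- setdiff(selected, v)
        best_adj <- max(drops)
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  if (length(selected) > 0) {
    h <- hat_matrix(x[, selected, drop = FALSE])
    r2 <- distlm_r2(g, h)
    adj <- adjusted_r2(r2, n, length(selected))
  } else {
    r2 <- 0
    adj <- 0
  }
  structure(list(selected = selected, steps = steps, marginal = marginal,
                 r2 = r2, adj_r2 = adj, n = n,
                 permutations = permutations,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "distlm")
}

# permutation test for adding `v` to `selected`
sequential_test <- function(g, x, selected, v, n, trg, permutations) {
  m1 <- length(selected) + 1
  h1 <- hat_matrix(x[, c(selected, v), drop = FALSE])
  h0 <- if (length(selected) > 0)
    hat_matrix(x[, selected, drop = FALSE]) else matrix(0, n, n)
  f_obs <- pseudo_f(sum(h1 * g) - sum(h0 * g), trg - sum(h0 * g),
                    1, n - m1 - 1)
  exceed <- 0L
  for (b in seq_len(permutations)) {
    p <- sample.int(n)
    gp <- g[p, p]
    fb <- pseudo_f(sum(h1 * gp) - sum(h0 * gp), trg - sum(h0 * gp),
                   1, n - m1 - 1)
    if (fb >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  r2 <- sum(h1 * g) / trg
  data.frame(predictor = v, pseudo_f = f_obs,
             p = (exceed + 1) / (permutations + 1),
             r2 = r2, adj_r2 = adjusted_r2(r2, n, m1))
}

#' @export
print.distlm <- function(x, ...) {
  cat("DistLM (stepwise, adjusted R^2,", x$permutations,
      "permutations)\n")
  if (length(x$selected) == 0) {
    cat("  no predictors selected\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = " + "), "\n")
    cat("  R^2 =", format(x$r2, digits = 4),
        " adjusted R^2 =", format(x$adj_r2, digits = 4), "\n")
  }
  invisible(x)
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Constrained ordination of a dissimilarity matrix on selected
#' predictors: eigen-decomposition of H G H where G is the Gower-centered
#' matrix and H the hat matrix of the (centered) predictors. Typically run
#' on the predictor set chosen by [distlm()].
#'
#' @param d Symmetric dissimilarity matrix.
#' @param x Predictor matrix (samples x selected variables); must be
#'   non-empty.
#' @return An `ordination` (see [pcoa()]) with `constrained = TRUE`;
#'   coordinates are the fitted sample scores on the constrained axes.
#' @export
dbrda <- function(d, x) {
  d <- as.matrix(d)
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("empty predictor selection")
  g <- gower_center(d)
  h <- hat_matrix(x)
  e <- eigen(h %*% g %*% h, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-8
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("dbRDA", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 constrained = TRUE),
            class = "ordination")
}
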