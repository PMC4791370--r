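test_that("distance metrics match their closed forms", {
  x <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  rownames(x) <- c("a", "b", "c")
  bc <- sample_distance(x, "bray_curtis")
  expect_equal(bc["a", "b"], 1)          # disjoint support
  expect_equal(bc["a", "c"], 0)          # identical rows
  he <- sample_distance(rbind(a = c(1, 0), b = c(0.25, 0.75)), "hellinger")
  expect_equal(he[1, 2],
               sqrt((1 - sqrt(0.25))^2 + (0 - sqrt(0.75))^2),
               tolerance = 1e-12)
  expect_error(sample_distance(rbind(a = c(-1, 2), b = c(1, 1)),
                               "bray_curtis"), "negative")
  # sqrt transform feeds the metric the square roots
  sq <- sample_distance(rbind(a = c(4, 0), b = c(0, 9)), "euclidean",
                        transform = "sqrt")
  expect_equal(sq[1, 2], sqrt(4 + 9))
})

test_that("distance and ANOSIM agree with vegan", {
  set.seed(21)
  x <- matrix(rexp(12 * 8), 12)
  rownames(x) <- paste0("s", 1:12)
  d <- sample_distance(x, "bray_curtis", "sqrt")
  expect_equal(unname(d[lower.tri(d)]),
               as.vector(vegan::vegdist(sqrt(x), "bray")),
               tolerance = 1e-12)
  g <- factor(rep(c("A", "B"), each = 6))
  expect_equal(anosim_r(d, g),
               unname(vegan::anosim(as.dist(d), g,
                                    permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(3)
  pts <- matrix(rnorm(10 * 2), 10)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:10)
  ord <- pcoa(d)
  expect_false(ord$constrained)
  expect_equal(as.matrix(dist(ord$coordinates[, 1:2])), d,
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues sorted, and their sum equals the centered trace
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  g <- -0.5 * d^2
  g <- sweep(sweep(g, 1, rowMeans(g)), 2, colMeans(-0.5 * d^2)) +
    mean(-0.5 * d^2)
  expect_equal(sum(ord$eigenvalues), sum(diag(g)), tolerance = 1e-8)
})

test_that("PCoA of collinear points has a single positive axis", {
  pts <- cbind(seq_len(6), 2 * seq_len(6))   # rank-1 configuration
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  expect_identical(ncol(ord$coordinates), 1L)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1L, ignore_attr = TRUE)
})

test_that("ANOSIM R hits its boundary values", {
  cl <- two_cloud_distance(n_per = 4, sep = 50)
  expect_equal(anosim_r(cl$d, cl$groups), 1)        # perfect separation
  tied <- matrix(1, 6, 6) - diag(6)
  expect_equal(anosim_r(tied, rep(c("A", "B"), 3)), 0)  # total tie
  expect_error(anosim_r(tied, rep("A", 6)), "two groups")
  # random instances stay within [-1, 1]
  for (s in 1:50) {
    d <- random_distance(8, s)
    g <- factor(sample(rep(c("A", "B"), 4)))
    r <- anosim_r(d, g)
    expect_true(r >= -1 - 1e-12 && r <= 1 + 1e-12)
  }
})

test_that("ANOSIM matches a hand-ranked 4-sample case", {
  # distances: within {1,2}: 1 (rank 1); within {3,4}: 2 (rank 2);
  # between: 5,6,7,8 (ranks 3..6)
  d <- matrix(0, 4, 4)
  d[1, 2] <- 1; d[3, 4] <- 2
  d[1, 3] <- 5; d[1, 4] <- 6; d[2, 3] <- 7; d[2, 4] <- 8
  d <- d + t(d)
  # mean between rank 4.5, mean within 1.5, M/2 = 3 -> R = 1
  expect_equal(anosim_r(d, c("A", "A", "B", "B")), 1)
  # swap one pair so ranks interleave: hand recomputation
  d2 <- d
  d2[1, 2] <- 5.5
  d2[2, 1] <- 5.5
  # sorted: 2(r1) 5(r2) 5.5(r3) 6(r4) 7(r5) 8(r6)
  # within ranks {3, 1} mean 2; between {2,4,5,6} mean 4.25
  # R = (4.25 - 2) / 3 = 0.75
  expect_equal(anosim_r(d2, c("A", "A", "B", "B")), 0.75)
})

test_that("k-R clustering equals exhaustive search on small instances", {
  for (s in 1:20) {
    d <- random_distance(sample(7:10, 1), seed = 100 + s)
    fit <- kr_cluster(d, k = 2, restarts = 30, seed = s)
    ref <- kr_exhaustive_k2(d)
    expect_equal(fit$r, ref$r, tolerance = 1e-12)
  }
})

test_that("k-R clustering recovers planted partitions and is invariant", {
  cl <- two_cloud_distance(n_per = 6, sep = 30, seed = 9)
  fit <- kr_cluster(cl$d, k = 2, restarts = 25, seed = 4)
  expect_equal(fit$r, 1)
  expect_equal(adjusted_rand_index(fit$groups, cl$groups), 1)
  # permuting sample order leaves the optimal R unchanged
  perm <- sample(nrow(cl$d))
  fit2 <- kr_cluster(cl$d[perm, perm], k = 2, restarts = 25, seed = 5)
  expect_equal(fit2$r, fit$r)
  # determinism under a fixed seed
  fit3 <- kr_cluster(cl$d, k = 2, restarts = 25, seed = 4)
  expect_identical(fit3$groups, fit$groups)
  expect_error(kr_cluster(cl$d, k = 1), "k must be")
  expect_error(kr_cluster(matrix(0, 4, 4), k = 2), "degenerate")
})

test_that("PERMANOVA matches vegan and its boundary behavior", {
  set.seed(31)
  x <- matrix(rexp(12 * 6), 12)
  rownames(x) <- paste0("s", 1:12)
  d <- sample_distance(x, "bray_curtis")
  g <- factor(rep(c("A", "B", "C"), each = 4))
  fit <- permanova(d, g, permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 2)
  expect_equal(fit$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$n_permutations, 99)
  expect_true(fit$p_value >= 1 / 100)

  # maximal separation: p hits the permutation floor (groups large
  # enough that a random relabelling virtually never recreates them)
  cl <- two_cloud_distance(n_per = 10, sep = 100)
  sep <- permanova(cl$d, cl$groups, permutations = 999, seed = 2)
  expect_equal(sep$p_value, 1 / 1000)
})

test_that("PERMANOVA pseudo-F matches hand-computed sums of squares", {
  d <- matrix(0, 6, 6)
  d[lower.tri(d)] <- c(1, 2, 7, 8, 9,
                       3, 7, 8, 9,
                       7, 8, 9,
                       1, 2,
                       3)
  d <- d + t(d)
  g <- rep(c("A", "B"), each = 3)
  # SS_total = sum(d^2)/6 ; SS_within = (1+4+9)/3 + (1+4+9)/3
  ss_total <- sum(d[lower.tri(d)]^2) / 6
  ss_within <- 14 / 3 + 14 / 3
  f_hand <- (ss_total - ss_within) / (ss_within / 4)
  fit <- permanova(d, g, permutations = 19, seed = 1)
  expect_equal(fit$statistic, f_hand, tolerance = 1e-12)
})

test_that("one-way ANOVA reduces to t^2 for two groups", {
  set.seed(41)
  v <- rnorm(14)
  g <- factor(rep(c("A", "B"), each = 7))
  fit <- anova_oneway(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(fit$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  # identical group means: F ~ 0
  flat <- anova_oneway(rep(1:7, 2), factor(rep(c("A", "B"), each = 7)))
  expect_lt(flat$f, 1e-20)
  # planted large shift
  shift <- anova_oneway(c(rnorm(7), rnorm(7, 10)), g)
  expect_lt(shift$p, 1e-3)
})

test_that("RELATE is a rank matrix correlation with permutation p", {
  d1 <- random_distance(10, 51)
  expect_equal(relate(d1, d1, permutations = 99, seed = 1)$statistic, 1)
  # monotone transform leaves the statistic at 1
  d2 <- d1^2
  expect_equal(relate(d1, d2, permutations = 99, seed = 1)$statistic, 1)
  # agreement with vegan::mantel spearman statistic
  d3 <- random_distance(10, 52)
  rownames(d3) <- colnames(d3) <- rownames(d1)
  fit <- relate(d1, d3, permutations = 99, seed = 2)
  ref <- vegan::mantel(as.dist(d1), as.dist(d3), method = "spearman",
                       permutations = 0)
  expect_equal(fit$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_error(relate(d1, d3[1:9, 1:9]), "dimensions")
})

test_that("DistLM recovers a generating predictor and refuses collinearity", {
  set.seed(61)
  n <- 25
  x <- cbind(driver = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  d <- as.matrix(dist(x[, "driver", drop = FALSE]))
  rownames(d) <- colnames(d) <- rownames(x)
  fit <- distlm(d, x, permutations = 199, seed = 1)
  expect_identical(fit$selected[1], "driver")
  expect_equal(fit$marginal$p[fit$marginal$predictor == "driver"],
               1 / 200)
  expect_gt(fit$marginal$r2[fit$marginal$predictor == "driver"], 0.9)
  # adjusted R^2 never exceeds R^2 and both are in [0, 1]
  expect_true(fit$adj_r2 <= fit$r2 + 1e-12)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # collinear columns are refused by name
  bad <- cbind(x, dup = 2 * x[, "driver"])
  expect_error(distlm(d, bad, permutations = 19), "dup")
})

test_that("a saturating orthonormal basis explains all variation", {
  d <- random_distance(8, 71)
  basis <- diag(8)[, 1:7]    # centered rank n-1: full fit
  rownames(basis) <- rownames(d)
  colnames(basis) <- paste0("b", 1:7)
  full <- domnet::dbrda(d, basis)
  expect_equal(sum(full$eigenvalues), sum(pcoa(d)$eigenvalues),
               tolerance = 1e-8)
})

test_that("dbRDA obeys rank bounds and matches PCoA when saturated", {
  cl <- two_cloud_distance(n_per = 5, sep = 8, seed = 81)
  binary <- matrix(as.numeric(cl$groups == "A"), ncol = 1,
                   dimnames = list(rownames(cl$d), "group"))
  ord <- domnet::dbrda(cl$d, binary)
  expect_true(ord$constrained)
  expect_identical(ncol(ord$coordinates), 1L)  # single binary predictor
  # constrained eigenvalue sum never exceeds the unconstrained total
  expect_lte(sum(ord$eigenvalues[ord$eigenvalues > 0]),
             sum(pcoa(cl$d)$eigenvalues[pcoa(cl$d)$eigenvalues > 0]) +
               1e-10)
  # saturated basis: eigenvalues equal the PCoA eigenvalues
  basis <- diag(10)[, 1:9]
  rownames(basis) <- rownames(cl$d)
  sat <- domnet::dbrda(cl$d, basis)
  expect_equal(sort(sat$eigenvalues[sat$eigenvalues > 1e-8],
                    decreasing = TRUE),
               sort(pcoa(cl$d)$eigenvalues[pcoa(cl$d)$eigenvalues > 1e-8],
                    decreasing = TRUE),
               tolerance = 1e-8)
  expect_error(domnet::dbrda(cl$d, basis[, 0]), "empty")
})
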