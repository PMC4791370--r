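#' Modified aromaticity index
#'
#' AI_mod = (1 + C - O/2 - S - H/2) / (C - O/2 - S - N - P), an estimate of
#' aromatic character that counts half the oxygen as carbonyl-like. When
#' the denominator is non-positive or the numerator negative the index is
#' undefined for a C,H,O composition and is clamped to 0.
#'
#' @param f A formula table.
#' @return Numeric AI_mod values in `[0, Inf)`; 0 for aliphatic and
#'   degenerate compositions.
#' @export
ai_mod <- function(f) {
  num <- 1 + f$c - f$o / 2 - f$s - f$h / 2
  den <- f$c - f$o / 2 - f$s - f$n - f$p
  out <- ifelse(den > 0 & num > 0, num / den, 0)
  pmax(out, 0)
}

#' Van Krevelen coordinates of a formula
#'
#' @param f A formula table with `c >= 1`.
#' @return A data frame with columns `oc_ratio` (O/C) and `hc_ratio` (H/C).
#' @export
van_krevelen <- function(f) {
  if (any(f$c < 1)) stop("van Krevelen ratios require at least one carbon")
  data.frame(oc_ratio = f$o / f$c, hc_ratio = f$h / f$c)
}

COMPOUND_CLASSES <- c("saturated_fatty_acid", "polycyclic_aromatic",
                      "polyphenol", "peptide_like", "unsaturated_aliphatic",
                      "highly_unsaturated", "unspecified")

#' Categorize formulas into DOM compound classes
#'
#' Applies, in fixed precedence order, the elemental-ratio and aromaticity
#' rules that partition the van Krevelen plane:
#' \enumerate{
#'   \item H/C >= 2.0 or O/C >= 0.9: saturated fatty acid
#'   \item AI_mod > 0.66: polycyclic aromatic
#'   \item 0.5 < AI_mod <= 0.66: polyphenol
#'   \item 2.0 > H/C >= 1.5 with N > 0: peptide-like
#'   \item 2.0 > H/C >= 1.5: unsaturated aliphatic
#'   \item AI_mod <= 0.5 and H/C < 1.5: highly unsaturated
#'   \item otherwise: unspecified
#' }
#' The precedence makes the classification total and deterministic even
#' where the individual published rules overlap. Boundaries are
#' configurable through `bounds`.
#'
#' @param f A formula table.
#' @param bounds Named list of class boundaries: `hc_fatty` (2.0),
#'   `oc_fatty` (0.9), `ai_aromatic` (0.66), `ai_polyphenol` (0.5),
#'   `hc_aliphatic` (1.5).
#' @return Factor of compound classes, one per formula.
#' @export
classify_compound <- function(f, bounds = list(hc_fatty = 2.0,
                                               oc_fatty = 0.9,
                                               ai_aromatic = 0.66,
                                               ai_polyphenol = 0.5,
                                               hc_aliphatic = 1.5)) {
  hc <- f$h / f$c
  oc <- f$o / f$c
  ai <- ai_mod(f)
  cls <- rep("unspecified", nrow(f))
  rules <- list(
    saturated_fatty_acid = hc >= bounds$hc_fatty | oc >= bounds$oc_fatty,
    polycyclic_aromatic = ai > bounds$ai_aromatic,
    polyphenol = ai > bounds$ai_polyphenol & ai <= bounds$ai_aromatic,
    peptide_like = hc < bounds$hc_fatty & hc >= bounds$hc_aliphatic & f$n > 0,
    unsaturated_aliphatic = hc < bounds$hc_fatty & hc >= bounds$hc_aliphatic,
    highly_unsaturated = ai <= bounds$ai_polyphenol & hc < bounds$hc_aliphatic
  )
  unset <- rep(TRUE, nrow(f))
  for (name in names(rules)) {
    hit <- unset & rules[[name]]
    cls[hit] <- name
    unset <- unset & !hit
  }
  factor(cls, levels = COMPOUND_CLASSES)
}

#' Per-formula descriptor table
#'
#' Computes DBE, AI_mod, elemental ratios and compound class for every
#' formula in a DOM table (or a bare formula table).
#'
#' @param x A `dom_table` or formula table.
#' @return A data frame with one row per formula: `formula`, `mass`,
#'   element counts, `dbe`, `ai_mod`, `hc_ratio`, `oc_ratio`,
#'   `compound_class`.
#' @export
describe_formulas <- function(x) {
  f <- if (inherits(x, "dom_table")) attr(x, "formulas") else x
  vk <- van_krevelen(f)
  data.frame(formula = f$formula, mass = f$mass,
             f[, ELEMENTS, drop = FALSE],
             dbe = dbe(f), ai_mod = ai_mod(f),
             hc_ratio = vk$hc_ratio, oc_ratio = vk$oc_ratio,
             compound_class = classify_compound(f),
             row.names = NULL)
}

#' Intensity-weighted average mass per sample
#'
#' @param dom A `dom_table` (rows sum to 1).
#' @return Named numeric vector of weighted average neutral masses (Da).
#' @export
weighted_average_mass <- function(dom) {
  masses <- attr(dom, "formulas")$mass
  drop(unclass(dom) %*% masses)
}

#' Per-sample compound-class relative abundances
#'
#' Sums relative intensities within each compound class per sample.
#'
#' @param dom A `dom_table`.
#' @return Matrix samples x compound classes; rows sum to 1.
#' @export
class_abundances <- function(dom) {
  cls <- classify_compound(attr(dom, "formulas"))
  out <- sapply(COMPOUND_CLASSES, function(k) {
    rowSums(unclass(dom)[, cls == k, drop = FALSE])
  })
  matrix(out, nrow = nrow(dom),
         dimnames = list(rownames(dom), COMPOUND_CLASSES))
}
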