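#' @importFrom stats anova cor dist kruskal.test lm p.adjust pf pt
#'   quantile rbinom rgamma rlnorm rmultinom rnorm runif sd setNames var
#'   rbeta aggregate
#' @importFrom utils head read.delim write.table combn
NULL

# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
ATOMIC_MASS <- c(
  c = 12.0,
  h = 1.00782503207,
  n = 14.0030740048,
  o = 15.9949146196,
  s = 31.97207100,
  p = 30.97376163
)

#' Physical constants used in mass arithmetic
#'
#' Mass differences that the assignment pipeline relies on: the proton mass
#' used to convert a deprotonated ion m/z to a neutral mass, the CH2 spacing
#' of homologous series, and the 13C-12C spacing of isotopologs.
#'
#' @format A named numeric vector with elements `proton`, `ch2`, `c13`.
#' @export
mass_constants <- c(
  proton = 1.007276466,
  ch2 = 14.01565006,
  c13 = 1.003354838
)

ELEMENTS <- c("c", "h", "n", "o", "s", "p")

#' Neutral monoisotopic mass of a molecular formula
#'
#' @param c,h,n,o,s,p Non-negative integer element counts (vectorized).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' formula_mass(c = 6, h = 12, o = 6) # glucose, 180.0634 Da
#' @export
formula_mass <- function(c = 0, h = 0, n = 0, o = 0, s = 0, p = 0) {
  c * ATOMIC_MASS[["c"]] + h * ATOMIC_MASS[["h"]] + n * ATOMIC_MASS[["n"]] +
    o * ATOMIC_MASS[["o"]] + s * ATOMIC_MASS[["s"]] + p * ATOMIC_MASS[["p"]]
}

#' Convert a singly charged negative-mode m/z to a neutral mass
#'
#' Assumes the deprotonated molecular ion [M-H]-; the neutral mass is the
#' measured m/z plus the proton mass (electron mass folded into the
#' constant).
#'
#' @param mz Measured mass-to-charge ratio in Da; must be positive.
#' @return Neutral mass in Da.
#' @export
neutral_mass_from_mz <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive")
  mz + mass_constants[["proton"]]
}

#' Convert a neutral mass to its [M-H]- m/z
#' @param mass Neutral monoisotopic mass in Da.
#' @return m/z of the singly charged deprotonated ion.
#' @export
mz_from_neutral_mass <- function(mass) {
  mass - mass_constants[["proton"]]
}

#' Build a molecular-formula table from element counts
#'
#' The package represents sets of molecular formulas as data frames with
#' integer columns `c`, `h`, `n`, `o`, `s`, `p`, the derived neutral
#' monoisotopic `mass`, and a `formula` string in Hill-like order (C, H,
#' then alphabetical).
#'
#' @param c,h,n,o,s,p Non-negative integer element counts, recycled to a
#'   common length.
#' @return A `data.frame` with one row per formula.
#' @examples
#' formula_table(c = c(6, 16), h = c(12, 18), o = c(6, 9))
#' @export
formula_table <- function(c = 0L, h = 0L, n = 0L, o = 0L, s = 0L, p = 0L) {
  d <- data.frame(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                  o = as.integer(o), s = as.integer(s), p = as.integer(p))
  if (any(d < 0)) stop("element counts must be non-negative")
  d$mass <- formula_mass(d$c, d$h, d$n, d$o, d$s, d$p)
  d$formula <- formula_string(d)
  d
}

#' Render formulas as strings in Hill-like order
#' @param f A formula table (see [formula_table()]).
#' @return Character vector like `"C27H30O15"`.
#' @export
formula_string <- function(f) {
  part <- function(sym, count) {
    ifelse(count == 0L, "",
           ifelse(count == 1L, sym, paste0(sym, count)))
  }
  paste0(part("C", f$c), part("H", f$h), part("N", f$n),
         part("O", f$o), part("P", f$p), part("S", f$s))
}

#' Parse formula strings back into element counts
#' @param x Character vector like `"C6H12O6"`.
#' @return A formula table (see [formula_table()]).
#' @export
parse_formula <- function(x) {
  get_count <- function(s, sym) {
    m <- regmatches(s, regexec(paste0(sym, "([0-9]*)([A-Z]|$)"), s))
    vapply(m, function(g) {
      if (length(g) == 0L) return(0L)
      if (g[2] == "") 1L else as.integer(g[2])
    }, integer(1))
  }
  formula_table(c = get_count(x, "C"), h = get_count(x, "H"),
                n = get_count(x, "N"), o = get_count(x, "O"),
                s = get_count(x, "S"), p = get_count(x, "P"))
}

ppm_window <- function(mass, ppm) mass * ppm * 1e-6
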