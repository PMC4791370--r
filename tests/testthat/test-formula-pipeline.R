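test_that("neutral mass conversion handles the [M-H]- convention", {
  expect_error(neutral_mass_from_mz(0), "positive")
  expect_error(neutral_mass_from_mz(-10), "positive")
  # glucose: ion at 179.0561 corresponds to the C6H12O6 neutral
  glucose <- formula_mass(c = 6, h = 12, o = 6)
  expect_equal(neutral_mass_from_mz(179.056105), 180.063381,
               tolerance = 1e-7)
  expect_equal(neutral_mass_from_mz(mz_from_neutral_mass(glucose)),
               glucose, tolerance = 1e-9)
})

test_that("enumerate_candidates agrees with exhaustive enumeration", {
  set.seed(11)
  masses <- runif(100, 150, 450)
  for (m in masses) {
    got <- enumerate_candidates(m, tolerance_ppm = 3,
                                ranges = small_ranges())
    expect_identical(sort(got$formula), oracle_enumerate(m, 3))
  }
})

test_that("enumeration finds known formulas and respects tolerance", {
  glucose <- formula_mass(c = 6, h = 12, o = 6)
  got <- enumerate_candidates(glucose, 0.5)
  expect_true("C6H12O6" %in% got$formula)
  expect_true(all(abs(got$error_ppm) <= 0.5))
  # far from every candidate at vanishing tolerance
  off <- glucose * (1 + 10e-6)
  expect_identical(nrow(enumerate_candidates(off, 0.01)), 0L)
  # widening ranges never removes a candidate
  narrow <- enumerate_candidates(glucose, 5, ranges = small_ranges())
  wide <- enumerate_candidates(glucose, 5, ranges = element_ranges())
  expect_true(all(narrow$formula %in% wide$formula))
})

test_that("chemical filters implement the plausibility rules", {
  benzene <- formula_table(c = 6, h = 6)
  expect_true(chemical_filters(benzene))            # DBE 4
  odd_h <- formula_table(c = 10, h = 11)            # half-integer DBE
  expect_false(chemical_filters(odd_h))
  high_oc <- formula_table(c = 1, h = 4, o = 2)     # O/C = 2
  expect_false(chemical_filters(high_oc))
  low_hc <- formula_table(c = 20, h = 4)            # H/C = 0.2
  expect_false(chemical_filters(low_hc))
  no_carbon <- formula_table(c = 0, h = 2, o = 1)
  expect_false(chemical_filters(no_carbon))
})

test_that("heteroatom exclusion matches the listed signatures", {
  expect_true(heteroatom_exclusion(formula_table(c = 10, h = 12, n = 2,
                                                 s = 1)))        # N2S
  expect_true(heteroatom_exclusion(formula_table(c = 10, h = 13, n = 1,
                                                 s = 1, p = 1))) # NSP
  expect_true(heteroatom_exclusion(formula_table(c = 10, h = 13, s = 2,
                                                 p = 1)))        # PS2
  expect_false(heteroatom_exclusion(formula_table(c = 10, h = 13, n = 1,
                                                  s = 1)))       # NS: kept
  expect_false(heteroatom_exclusion(formula_table(c = 10, h = 12)))
  expect_false(heteroatom_exclusion(formula_table(c = 10, h = 12, n = 4)))
})

test_that("alignment groups masses across samples by tolerance", {
  base <- data.frame(mz = c(200.0000, 350.5000, 500.1), intensity = 10,
                     resolution = 4e5, sn = 30)
  peaks <- do.call(rbind, lapply(c("a", "b", "c"), function(s) {
    d <- base
    d$sample_id <- s
    d
  }))
  tab <- align_masses(peaks, 0.5)
  expect_identical(length(tab$mz), 3L)
  expect_true(all(colSums(tab$intensity > 0) == 3))

  # two masses 10 ppm apart stay separate at 0.5 ppm
  two <- data.frame(sample_id = "a", mz = c(300, 300 * (1 + 10e-6)),
                    intensity = 1, resolution = 4e5, sn = 10)
  expect_identical(length(align_masses(two, 0.5)$mz), 2L)

  # single sample: columns are its peaks
  one <- base
  one$sample_id <- "only"
  expect_identical(length(align_masses(one, 0.5)$mz), 3L)

  # duplicate within a sample: higher intensity wins, conflict logged
  dup <- data.frame(sample_id = "a", mz = c(400, 400 + 400 * 0.1e-6),
                    intensity = c(5, 50), resolution = 4e5, sn = 10)
  tab <- align_masses(dup, 0.5)
  expect_identical(length(tab$mz), 1L)
  expect_equal(max(tab$intensity), 50)
  expect_identical(nrow(tab$conflicts), 1L)
})

test_that("occurrence filter keeps >2 samples or rare high-S/N masses", {
  make_tab <- function(occurrence, sn_value, n = 17) {
    peaks <- do.call(rbind, lapply(seq_len(occurrence), function(i) {
      data.frame(sample_id = sprintf("s%02d", i), mz = 321.0,
                 intensity = 1, resolution = 4e5, sn = sn_value)
    }))
    # pad remaining samples with an unrelated anchor mass so n is known
    pad <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(sample_id = sprintf("s%02d", i), mz = 700.0,
                 intensity = 1, resolution = 4e5, sn = 30)
    }))
    align_masses(rbind(peaks, pad), 0.5)
  }
  kept_mz <- function(tab) cross_sample_filter(tab)$mz
  expect_true(any(abs(kept_mz(make_tab(3, 5)) - 321) < 1e-6))    # occ 3
  expect_true(any(abs(kept_mz(make_tab(2, 25)) - 321) < 1e-6))   # rescued
  expect_false(any(abs(kept_mz(make_tab(2, 10)) - 321) < 1e-6))  # removed
})

test_that("sub-threshold S/N peaks are never assigned", {
  glucose_mz <- mz_from_neutral_mass(formula_mass(c = 6, h = 12, o = 6))
  peaks <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(sample_id = paste0("s", i), mz = glucose_mz,
               intensity = 10, resolution = 4e5, sn = 3.9)
  }))
  tab <- sn_filter(align_masses(peaks, 0.5), 4)
  expect_identical(length(tab$mz), 0L)
})

test_that("double assignments drop the mass entirely", {
  # C3 vs SH4 differ by ~3.4 mDa; craft a mass admitting two candidates
  # by using a generous tolerance on a real formula mass
  m <- formula_mass(c = 15, h = 22, o = 8)
  cand <- enumerate_candidates(m, 40)
  cand <- cand[chemical_filters(cand) & !heteroatom_exclusion(cand), ]
  expect_gt(nrow(cand), 1)  # fixture premise: ambiguous at 40 ppm
  peaks <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(sample_id = paste0("s", i), mz = mz_from_neutral_mass(m),
               intensity = 10, resolution = 4e5, sn = 30)
  }))
  tab <- cross_sample_filter(sn_filter(align_masses(peaks, 0.5), 4))
  amb <- assign_and_resolve(tab, tolerance_ppm = 40)
  expect_identical(nrow(amb$formulas), 0L)
  expect_identical(amb$n_ambiguous, 1L)
  # at 0.5 ppm the same mass is unique and assigned
  uni <- assign_and_resolve(tab, tolerance_ppm = 0.5)
  expect_identical(uni$formulas$formula, "C15H22O8")
})

test_that("contaminant removal covers series and isotopologs", {
  base <- 301.2345
  masses <- c(base,
              base + mass_constants[["ch2"]],        # homolog
              base - 2 * mass_constants[["ch2"]],    # homolog below
              base + mass_constants[["c13"]],        # isotopolog of base
              base + 5.0)                            # unrelated
  fake <- structure(list(
    formulas = formula_table(c = rep(10, 5), h = rep(12, 5))[, ],
    intensity = matrix(1, 2, 5, dimnames = list(c("a", "b"), NULL)),
    sn = matrix(30, 2, 5), mz = mz_from_neutral_mass(masses),
    samples = c("a", "b"), n_ambiguous = 0L),
    class = "formula_assignments")
  fake$formulas$mass <- masses  # override to the constructed masses
  out <- remove_contaminants(fake, base)
  expect_identical(out$formulas$mass, base + 5.0)
  # empty contaminant list: identity
  out2 <- remove_contaminants(fake, numeric(0))
  expect_identical(out2$formulas$mass, masses)
})

test_that("normalization yields unit row sums and scale invariance", {
  fake <- structure(list(
    formulas = formula_table(c = c(6, 10), h = c(12, 14), o = c(6, 2)),
    intensity = rbind(a = c(1, 3), b = c(10, 30)),
    sn = matrix(30, 2, 2), mz = c(100, 200),
    samples = c("a", "b"), n_ambiguous = 0L),
    class = "formula_assignments")
  dom <- normalize_intensities(fake)
  expect_equal(unname(dom["a", ]), c(0.25, 0.75))
  expect_equal(unname(dom["a", ]), unname(dom["b", ]))  # scale invariance
  expect_equal(unname(rowSums(dom)), c(1, 1), tolerance = 1e-12)

  fake$intensity["a", ] <- 0
  expect_error(normalize_intensities(fake), "a")
})

test_that("peak list and table io round-trips through TSV", {
  dir <- withr::local_tempdir()
  peaks <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                      mz = c(200.1, 300.2, 200.1, 300.2),
                      intensity = c(1, 2, 3, 4),
                      resolution = 4e5, sn = 30)
  f <- file.path(dir, "peaks.tsv")
  write.table(peaks, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_peak_lists(f)$mz, peaks$mz)

  u <- formula_table(c = c(6, 10), h = c(12, 14), o = c(6, 2))
  dom <- dom_table(matrix(c(0.25, 0.75, 0.5, 0.5), 2, byrow = TRUE,
                          dimnames = list(c("s1", "s2"), u$formula)), u)
  p <- file.path(dir, "dom.tsv")
  write_dom_table(dom, p)
  back <- read_dom_table(p)
  expect_equal(unclass(back), unclass(dom), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "formulas")$mass, u$mass)
})
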