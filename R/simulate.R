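#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulated study: a daily time series of
#' coastal surface-water samples profiled by negative-mode FT-ICR-MS and
#' 16S amplicon sequencing, with a two-group structure planted across the
#' series. Defaults mirror a 17-sample campaign with ~100 genus-level
#' OTUs and a formula universe of a few hundred DOM compounds.
#'
#' @param n_samples Number of samples (default 17).
#' @param n_true_formulas Number of planted molecular formulas (200).
#' @param mass_range Neutral-mass window hosting the universe, Da.
#' @param mass_error_ppm Gaussian m/z error standard deviation, ppm (0.1).
#' @param tolerance_ppm Assignment tolerance the planted universe is
#'   calibrated against (0.5).
#' @param unique_assignment Keep only formulas that are uniquely
#'   assignable at `tolerance_ppm` (default TRUE), so planted ground
#'   truth is unambiguous in the same way noise peaks are kept clear of
#'   valid masses; mass-degenerate formula pairs are exercised by
#'   dedicated tests rather than planted.
#' @param presence_prob Probability a true formula is detected in a given
#'   sample (0.9).
#' @param isotopolog_fraction Fraction of true formulas that carry a 13C
#'   isotopolog partner peak at +1.00336 Da (0.2).
#' @param n_noise_peaks Noise peaks per sample, kept at least 5 ppm away
#'   from any chemically valid candidate mass (30).
#' @param n_contaminants Number of injected CH2-homologous contaminant
#'   series (1); `contaminant_length` members each (6).
#' @param contaminant_length Members per contaminant series.
#' @param sn_meanlog,sn_sdlog Log-normal S/N distribution of true peaks.
#' @param noise_sn_meanlog,noise_sn_sdlog Log-normal S/N of noise peaks.
#' @param n_otus Number of bacterial OTUs (98).
#' @param n_organelles Organelle/eukaryote taxa added to exercise taxon
#'   filtering (3).
#' @param depth_meanlog,depth_sdlog Log-normal sequencing depth (around
#'   1e5 reads).
#' @param dm_concentration Dirichlet-multinomial concentration; lower
#'   values mean more overdispersion (200).
#' @param group_assignment Factor of sample group labels `A`/`B`; default
#'   splits the series in half.
#' @param n_differential_otus OTUs with a planted group effect (10).
#' @param log_fold_effect Natural-log fold change of differential OTUs in
#'   group B (default `log(4)`).
#' @param env_vars Names of environmental variables.
#' @param collinearity_spec List of `list(var_a, var_b, r)` target rank
#'   correlations planted among environmental variables.
#' @param planted_edges List of `list(otu, formula, r)` target Pearson
#'   correlations planted between OTUs and DOM formulas.
#' @param seed Integer seed controlling all draws.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 17,
                              n_true_formulas = 200,
                              mass_range = c(150, 800),
                              mass_error_ppm = 0.1,
                              tolerance_ppm = 0.5,
                              unique_assignment = TRUE,
                              presence_prob = 0.9,
                              isotopolog_fraction = 0.2,
                              n_noise_peaks = 30,
                              n_contaminants = 1,
                              contaminant_length = 6,
                              sn_meanlog = log(50), sn_sdlog = 0.8,
                              noise_sn_meanlog = log(8),
                              noise_sn_sdlog = 0.6,
                              n_otus = 98,
                              n_organelles = 3,
                              depth_meanlog = log(1e5),
                              depth_sdlog = 0.3,
                              dm_concentration = 200,
                              group_assignment = NULL,
                              n_differential_otus = 10,
                              log_fold_effect = log(4),
                              env_vars = c("salinity", "temperature",
                                           "tdn", "doc", "o2", "chla",
                                           "po4", "no3"),
                              collinearity_spec = list(),
                              planted_edges = list(),
                              seed = 1) {
  if (any(c(n_samples, n_true_formulas, n_noise_peaks, n_otus) <= 0))
    stop("counts must be positive")
  if (mass_error_ppm < 0) stop("mass_error_ppm must be non-negative")
  if (presence_prob <= 0 || presence_prob > 1)
    stop("presence_prob must lie in (0, 1]")
  for (e in c(collinearity_spec, planted_edges)) {
    if (abs(e[[3]]) > 1) stop("target correlations must lie in [-1, 1]")
  }
  if (is.null(group_assignment)) {
    group_assignment <- factor(rep(c("A", "B"),
                                   c(ceiling(n_samples / 2),
                                     floor(n_samples / 2))))
  }
  if (length(group_assignment) != n_samples)
    stop("group_assignment must have one label per sample")
  arg_names <- names(formals(simulation_config))
  structure(mget(arg_names), class = "simulation_config")
}

sample_ids <- function(cfg) sprintf("s%02d", seq_len(cfg$n_samples))

#' Generate a universe of chemically valid molecular formulas
#'
#' Draws random CHNOSP compositions with DOM-like elemental ratios,
#' keeping only formulas that pass [chemical_filters()], are not excluded
#' heteroatom combinations, fall in the configured mass window, and are
#' distinct. Fails explicitly when the window cannot host the requested
#' number of formulas.
#'
#' @param cfg A [simulation_config()].
#' @param ranges Element ranges the formulas must respect.
#' @return A formula table with `cfg$n_true_formulas` rows.
#' @export
generate_formula_universe <- function(cfg, ranges = element_ranges()) {
  with_seed(cfg$seed)
  wanted <- cfg$n_true_formulas
  got <- empty_candidates()[, c(ELEMENTS, "mass", "formula")]
  max_tries <- 400L
  for (round in seq_len(max_tries)) {
    m <- wanted * 2L
    c_ <- sample(6:40, m, replace = TRUE)
    hc <- runif(m, 0.5, 2.2)
    h_ <- pmax(round(c_ * hc), 1L)
    o_ <- pmin(round(c_ * runif(m, 0.05, 1.0)), ranges$o[2])
    n_ <- sample(0:3, m, replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05))
    s_ <- rbinom(m, 1, 0.08)
    p_ <- rbinom(m, 1, 0.05)
    # integer DBE requires h = n + p (mod 2)
    h_ <- h_ + (h_ + n_ + p_) %% 2
    f <- formula_table(c = c_, h = h_, n = n_, o = o_, s = s_, p = p_)
    ok <- chemical_filters(f, ranges) & !heteroatom_exclusion(f) &
      f$mass >= cfg$mass_range[1] & f$mass <= cfg$mass_range[2]
    f <- f[ok, , drop = FALSE]
    if (isTRUE(cfg$unique_assignment) && nrow(f) > 0) {
      unique_ok <- vapply(f$mass, function(m) {
        cand <- enumerate_candidates(m, cfg$tolerance_ppm, ranges)
        sum(chemical_filters(cand, ranges) &
              !heteroatom_exclusion(cand)) == 1L
      }, logical(1))
      f <- f[unique_ok, , drop = FALSE]
    }
    got <- rbind(got, f)
    got <- got[!duplicated(got$formula), , drop = FALSE]
    if (nrow(got) >= wanted) break
  }
  if (nrow(got) < wanted)
    stop("mass window too narrow to host ", wanted, " distinct formulas")
  out <- got[seq_len(wanted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate per-sample mass-peak lists with known ground truth
#'
#' Each planted formula appears (with probability `presence_prob` per
#' sample) as its [M-H]- ion with Gaussian m/z error; a configured
#' fraction of formulas carries a lower-intensity 13C isotopolog partner
#' at +1.00336 Da; CH2-homologous contaminant series are injected in
#' every sample; and noise peaks are placed at least 5 ppm away from any
#' chemically valid candidate mass. Signal-to-noise ratios are drawn from
#' stated log-normal distributions.
#'
#' @param universe Formula table from [generate_formula_universe()].
#' @param cfg A [simulation_config()].
#' @param ranges Element ranges defining "valid" masses for the noise
#'   exclusion zone.
#' @return A list: `peaks` (long data frame: `sample_id`, `mz`,
#'   `intensity`, `resolution`, `sn`, `kind`), `contaminant_masses`
#'   (neutral base masses to feed [remove_contaminants()]),
#'   `isotopolog_formulas` (formula strings carrying partners).
#' @export
generate_peak_lists <- function(universe, cfg, ranges = element_ranges()) {
  if (nrow(universe) == 0L) stop("empty formula universe")
  with_seed(cfg$seed + 1L)
  ids <- sample_ids(cfg)
  nf <- nrow(universe)
  base_int <- rlnorm(nf, meanlog = log(1e7), sdlog = 0.8)
  iso <- runif(nf) < cfg$isotopolog_fraction
  out <- vector("list", cfg$n_samples)

  contaminant_bases <- numeric(0)
  if (cfg$n_contaminants > 0) {
    # synthetic contaminant base masses, placed inside the window
    contaminant_bases <- runif(cfg$n_contaminants,
                               cfg$mass_range[1] + 50,
                               cfg$mass_range[2] / 2)
  }

  for (i in seq_len(cfg$n_samples)) {
    present <- runif(nf) < cfg$presence_prob
    f <- universe[present, , drop = FALSE]
    ion_mz <- mz_from_neutral_mass(f$mass)
    mz <- ion_mz * (1 + rnorm(nrow(f), 0, cfg$mass_error_ppm * 1e-6))
    intensity <- base_int[present] * rlnorm(nrow(f), 0, 0.3)
    sn <- rlnorm(nrow(f), cfg$sn_meanlog, cfg$sn_sdlog)
    peaks <- data.frame(sample_id = ids[i], mz = mz,
                        intensity = intensity,
                        resolution = 4e5, sn = sn, kind = "formula")
    # 13C isotopolog partners
    which_iso <- which(iso[present])
    if (length(which_iso) > 0) {
      ratio <- pmin(0.011 * f$c[which_iso], 0.5)
      peaks <- rbind(peaks, data.frame(
        sample_id = ids[i],
        mz = mz[which_iso] + 1.00336,
        intensity = intensity[which_iso] * ratio,
        resolution = 4e5,
        sn = pmax(sn[which_iso] * ratio, 1),
        kind = "isotopolog"))
    }
    # contaminant homologous series, present in every sample
    if (length(contaminant_bases) > 0) {
      series <- unlist(lapply(contaminant_bases, function(m) {
        m + mass_constants[["ch2"]] * seq(0, cfg$contaminant_length - 1)
      }))
      peaks <- rbind(peaks, data.frame(
        sample_id = ids[i],
        mz = mz_from_neutral_mass(series) *
          (1 + rnorm(length(series), 0, cfg$mass_error_ppm * 1e-6)),
        intensity = rlnorm(length(series), log(5e6), 0.2),
        resolution = 4e5,
        sn = rlnorm(length(series), log(60), 0.3),
        kind = "contaminant"))
    }
    # noise peaks, kept clear of all assignable masses
    noise_mz <- draw_noise_masses(cfg$n_noise_peaks, cfg$mass_range, ranges)
    peaks <- rbind(peaks, data.frame(
      sample_id = ids[i],
      mz = noise_mz,
      intensity = rlnorm(cfg$n_noise_peaks, log(2e6), 0.5),
      resolution = 4e5,
      sn = rlnorm(cfg$n_noise_peaks, cfg$noise_sn_meanlog,
                  cfg$noise_sn_sdlog),
      kind = "noise"))
    out[[i]] <- peaks
  }
  list(peaks = do.call(rbind, out),
       contaminant_masses = contaminant_bases,
       isotopolog_formulas = universe$formula[iso])
}

# rejection-sample m/z values whose neutral mass has no valid candidate
# within 5 ppm
draw_noise_masses <- function(n, mass_range, ranges) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- runif(2 * (n - length(out)), mass_range[1], mass_range[2])
    ok <- vapply(m, function(mi) {
      cand <- enumerate_candidates(mi, tolerance_ppm = 5, ranges = ranges)
      if (nrow(cand) == 0L) return(TRUE)
      keep <- chemical_filters(cand, ranges) & !heteroatom_exclusion(cand)
      !any(keep)
    }, logical(1))
    out <- c(out, m[ok])
  }
  mz_from_neutral_mass(out[seq_len(n)])
}

#' Generate an OTU count table with planted group structure
#'
#' Counts follow a Dirichlet-multinomial: log-normal base proportions,
#' per-sample Dirichlet draws at the configured concentration, and
#' multinomial sampling at log-normal depth around 1e5 reads. A chosen
#' set of OTUs has its group-B abundance shifted by `log_fold_effect`;
#' organelle/eukaryote taxa are appended to exercise taxonomy filtering.
#'
#' @param cfg A [simulation_config()].
#' @return A count matrix (samples x taxa) with attributes `taxonomy`
#'   (character vector), `differential` (names of shifted OTUs), and
#'   `groups` (the group factor).
#' @export
generate_otu_table <- function(cfg) {
  with_seed(cfg$seed + 2L)
  n <- cfg$n_samples
  groups <- cfg$group_assignment
  base <- rlnorm(cfg$n_otus, 0, 1.5)
  base <- base / sum(base)
  diff_idx <- sample.int(cfg$n_otus, min(cfg$n_differential_otus,
                                         cfg$n_otus))
  otu_names <- sprintf("otu_%03d", seq_len(cfg$n_otus))
  phyla <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria",
             "Cyanobacteria", "Verrucomicrobia")
  taxonomy <- paste0("Bacteria;", sample(phyla, cfg$n_otus, replace = TRUE),
                     ";", otu_names)

  counts <- matrix(0L, nrow = n, ncol = cfg$n_otus,
                   dimnames = list(sample_ids(cfg), otu_names))
  depth <- round(rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog))
  for (i in seq_len(n)) {
    p <- base
    if (groups[i] == "B")
      p[diff_idx] <- p[diff_idx] * exp(cfg$log_fold_effect)
    p <- p / sum(p)
    alpha <- p * cfg$dm_concentration
    gam <- rgamma(cfg$n_otus, shape = alpha)
    if (sum(gam) == 0) gam <- p
    counts[i, ] <- drop(rmultinom(1, depth[i], gam / sum(gam)))
  }
  if (cfg$n_organelles > 0) {
    org_labels <- rep(c("Eukaryota;Chloroplast;unknown",
                        "Bacteria;Cyanobacteria;Chloroplast",
                        "Eukaryota;Mitochondria;unknown"),
                      length.out = cfg$n_organelles)
    org_names <- sprintf("org_%02d", seq_len(cfg$n_organelles))
    org <- matrix(rbinom(n * cfg$n_organelles, 50, 0.5),
                  nrow = n, dimnames = list(sample_ids(cfg), org_names))
    counts <- cbind(counts, org)
    taxonomy <- c(taxonomy, org_labels)
  }
  attr(counts, "taxonomy") <- taxonomy
  attr(counts, "differential") <- otu_names[diff_idx]
  attr(counts, "groups") <- groups
  counts
}

#' Generate environmental covariates with planted collinearity
#'
#' Draws variables through a Gaussian copula whose correlation matrix
#' carries the configured pairwise targets, then exponentiates the
#' marginals (log-normal) so every variable is strictly positive and the
#' log transform of [transform_env()] is defined.
#'
#' @param cfg A [simulation_config()].
#' @return A numeric matrix samples x variables, all entries > 0.
#' @export
generate_env_table <- function(cfg) {
  with_seed(cfg$seed + 3L)
  vars <- cfg$env_vars
  k <- length(vars)
  rho <- diag(k)
  for (e in cfg$collinearity_spec) {
    i <- match(e[[1]], vars)
    j <- match(e[[2]], vars)
    if (is.na(i) || is.na(j)) stop("unknown variable in collinearity_spec")
    rho[i, j] <- rho[j, i] <- e[[3]]
  }
  ch <- tryCatch(chol(rho), error = function(e)
    stop("infeasible correlation targets (matrix not positive definite)"))
  z <- matrix(rnorm(cfg$n_samples * k), ncol = k) %*% ch
  # log-normal marginals with modest spread keep the copula correlation
  # nearly intact after exponentiation
  env <- exp(sweep(z * 0.25, 2,
                   rep_len(log(c(32, 18, 15, 100, 280, 1, 0.4, 5)), k),
                   `+`))
  dimnames(env) <- list(sample_ids(cfg), vars)
  env
}

#' Generate a DOM relative-intensity table directly from a universe
#'
#' Convenience generator that skips peak simulation: log-normal base
#' intensities with per-sample noise, sum-normalized per sample. Useful
#' for association and effect-size simulations where the assignment
#' cascade itself is not under study.
#'
#' @param universe Formula table.
#' @param cfg A [simulation_config()].
#' @return A `dom_table` (samples x formulas).
#' @export
generate_dom_table <- function(universe, cfg) {
  with_seed(cfg$seed + 4L)
  n <- cfg$n_samples
  nf <- nrow(universe)
  base <- rlnorm(nf, log(1e7), 0.8)
  raw <- matrix(rlnorm(n * nf, 0, 0.3), nrow = n) %*% diag(base)
  rel <- raw / rowSums(raw)
  dimnames(rel) <- list(sample_ids(cfg), universe$formula)
  dom_table(rel, universe)
}

#' Plant OTU-molecule correlations into generated tables
#'
#' For each configured edge, the DOM formula's column is rewritten as a
#' positive affine image of `r * z(otu) + sqrt(1 - r^2) * noise`, where
#' `z(otu)` is the standardized relative abundance of the named OTU, and
#' the DOM rows are re-normalized. Untouched columns are unaffected up to
#' the (small) re-normalization.
#'
#' @param otu OTU count matrix from [generate_otu_table()].
#' @param dom A `dom_table`.
#' @param cfg A [simulation_config()] with `planted_edges`.
#' @return A list `otu`, `dom` with the planted structure.
#' @export
plant_correlations <- function(otu, dom, cfg) {
  if (length(cfg$planted_edges) == 0L) return(list(otu = otu, dom = dom))
  with_seed(cfg$seed + 5L)
  pair_keys <- vapply(cfg$planted_edges, function(e)
    paste(e[[1]], e[[2]]), character(1))
  target_keys <- vapply(cfg$planted_edges, function(e) e[[2]], character(1))
  if (anyDuplicated(pair_keys) || anyDuplicated(target_keys))
    stop("conflicting planted edges on the same formula")
  rel_otu <- to_relative(otu)
  m <- unclass(dom)
  for (e in cfg$planted_edges) {
    otu_id <- e[[1]]
    formula_id <- e[[2]]
    r <- e[[3]]
    if (!otu_id %in% colnames(otu)) stop("unknown OTU: ", otu_id)
    if (!formula_id %in% colnames(m)) stop("unknown formula: ", formula_id)
    zx <- drop(scale(rel_otu[, otu_id]))
    y <- r * zx + sqrt(1 - r^2) * rnorm(length(zx))
    y <- y - min(y) + 0.5                # positive affine map keeps r
    old <- m[, formula_id]
    m[, formula_id] <- y / mean(y) * mean(old)
  }
  m <- m / rowSums(m)
  list(otu = otu, dom = dom_table(m, attr(dom, "formulas")))
}

#' Simulate a complete coupled dataset
#'
#' Runs every generator with a shared configuration and returns all
#' tables plus the ground-truth manifest.
#'
#' @param cfg A [simulation_config()].
#' @param peak_lists Also simulate raw peak lists (slower); default TRUE.
#' @return A list: `config`, `universe`, `peaks` (or NULL),
#'   `contaminant_masses`, `isotopolog_formulas`, `otu`, `env`, `dom`,
#'   `groups`, `truth` (differential OTUs, planted edges).
#' @export
simulate_dataset <- function(cfg = simulation_config(), peak_lists = TRUE) {
  universe <- generate_formula_universe(cfg)
  pk <- if (peak_lists) generate_peak_lists(universe, cfg) else NULL
  otu <- generate_otu_table(cfg)
  env <- generate_env_table(cfg)
  dom <- generate_dom_table(universe, cfg)
  planted <- plant_correlations(otu, dom, cfg)
  list(config = cfg,
       universe = universe,
       peaks = pk$peaks,
       contaminant_masses = pk$contaminant_masses,
       isotopolog_formulas = pk$isotopolog_formulas,
       otu = planted$otu,
       env = env,
       dom = planted$dom,
       groups = cfg$group_assignment,
       truth = list(differential_otus = attr(otu, "differential"),
                    planted_edges = cfg$planted_edges))
}

#' Write a simulated dataset to TSV files
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peaks = file.path(dir, "peaks.tsv"),
    otu = file.path(dir, "otu_table.tsv"),
    env = file.path(dir, "env_table.tsv"),
    dom = file.path(dir, "dom_table.tsv"),
    contaminants = file.path(dir, "contaminants.txt"),
    truth = file.path(dir, "truth.yml"))
  if (!is.null(sim$peaks))
    write.table(sim$peaks, paths["peaks"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  write.table(data.frame(sample = rownames(sim$otu), sim$otu,
                         check.names = FALSE),
              paths["otu"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rownames(sim$env), sim$env,
                         check.names = FALSE),
              paths["env"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rownames(sim$dom),
                         unclass(sim$dom), check.names = FALSE),
              paths["dom"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(sim$contaminant_masses, digits = 10),
             paths["contaminants"])
  truth <- c(
    paste0("seed: ", sim$config$seed),
    paste0("groups: [", paste(sim$groups, collapse = ", "), "]"),
    paste0("differential_otus: [",
           paste(sim$truth$differential_otus, collapse = ", "), "]"),
    paste0("planted_formulas: [",
           paste(sim$universe$formula, collapse = ", "), "]"))
  writeLines(truth, paths["truth"])
  invisible(paths)
}
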