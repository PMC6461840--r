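#' Simulation design for a two-species decomposition time course
#'
#' Describes one fungal culture series: the chemistry sampling grid and the
#' count-matrix design (four analysis time points, replicated cultures).
#' Defaults emulate a design with four selected time points and n = 3
#' replicate cultures per time point.
#'
#' @param species_label Label for the fungal species (free text).
#' @param sampling_times Chemistry sampling times in hours, strictly
#'   increasing.
#' @param n_timepoints Number of analysis time points for the count design.
#' @param n_replicates Replicate cultures per time point.
#' @param seed Integer seed used by the simulators that take this design.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(species_label = "species_A",
                       sampling_times = seq(50, 700, by = 50),
                       n_timepoints = 4L,
                       n_replicates = 3L,
                       seed = 1L) {
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) < 2L || any(diff(sampling_times) <= 0)) {
    stop("invalid design: sampling times must be strictly increasing")
  }
  if (n_timepoints < 2L) stop("invalid design: n_timepoints must be >= 2")
  if (n_replicates < 2L) stop("invalid design: n_replicates must be >= 2")
  structure(
    list(species_label = species_label,
         sampling_times = sampling_times,
         n_timepoints = as.integer(n_timepoints),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_design")
}

#' Parameters of the closed-form chemistry curves
#'
#' Glucose-C and ammonium-N follow logistic decay; biomass follows logistic
#' growth with a species switch for the post-glucose-depletion behaviour
#' (`"decline"` emulates a mycelium that autolyses under prolonged carbon
#' starvation, `"plateau"` one that arrests growth).  Depletion times are
#' stated as the time at which the curve crosses its detection threshold
#' (1 mg glucose-C L^-1; `ammonium_detect_frac` of the initial ammonium-N).
#'
#' @param glucose0 Initial glucose concentration, mg C L^-1.
#' @param glucose_depletion Time (h) at which glucose crosses
#'   `glucose_threshold`.
#' @param glucose_tau Logistic time constant of the glucose decay, h.
#' @param glucose_threshold Glucose detection limit, mg C L^-1.
#' @param ammonium0,ammonium_depletion,ammonium_tau Analogous parameters for
#'   ammonium-N (mg N L^-1).
#' @param ammonium_detect_frac Ammonium detection limit as a fraction of
#'   `ammonium0`.
#' @param organic_n0 Initial organic N, mg N L^-1.
#' @param organic_n_loss Fraction of organic N mobilised by the end of the
#'   incubation.
#' @param organic_n_mid,organic_n_tau Midpoint (h) and time constant (h) of
#'   the organic-N mobilisation curve.
#' @param biomass_max Asymptotic biomass, mg.
#' @param biomass_mid,biomass_tau Midpoint and time constant of biomass
#'   growth, h.
#' @param post_depletion `"decline"` or `"plateau"`: biomass behaviour after
#'   glucose depletion.
#' @param decline_rate Exponential biomass decline rate after glucose
#'   depletion (h^-1), used when `post_depletion = "decline"`.
#' @param noise_cv Replicate-level coefficient of variation (multiplicative
#'   Gaussian noise).
#' @return A list of class `chem_params`.
#' @export
chem_params <- function(glucose0 = 2000, glucose_depletion = 400,
                        glucose_tau = 15, glucose_threshold = 1,
                        ammonium0 = 40, ammonium_depletion = 200,
                        ammonium_tau = 12, ammonium_detect_frac = 0.02,
                        organic_n0 = 60, organic_n_loss = 0.4,
                        organic_n_mid = 350, organic_n_tau = 80,
                        biomass_max = 50, biomass_mid = 150, biomass_tau = 40,
                        post_depletion = c("decline", "plateau"),
                        decline_rate = 0.002,
                        noise_cv = 0.05) {
  post_depletion <- match.arg(post_depletion)
  if (ammonium_depletion >= glucose_depletion) {
    stop("invalid design: ammonium must deplete before glucose")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(as.list(environment()), class = "chem_params")
}

#' Noiseless mean chemistry curves
#'
#' The generator's own mean functions, exposed so that Monte-Carlo checks
#' can compare replicate draws against them.
#'
#' @param times Numeric vector of times, hours.
#' @param params A [chem_params()] object.
#' @return data.frame with columns time, glucose_C, ammonium_N, total_N,
#'   biomass.
#' @export
chem_mean_curves <- function(times, params = chem_params()) {
  p <- params
  # logistics positioned so each curve falls just below its detection
  # threshold (1% margin) at the stated depletion time; thresholding a
  # sampled grid then selects the stated time deterministically rather
  # than sitting on a knife-edge equality
  margin <- 0.99
  c_g <- p$glucose_depletion +
    p$glucose_tau * stats::qlogis(margin * p$glucose_threshold / p$glucose0)
  c_a <- p$ammonium_depletion +
    p$ammonium_tau * stats::qlogis(margin * p$ammonium_detect_frac)
  glucose <- p$glucose0 * stats::plogis(-(times - c_g) / p$glucose_tau)
  ammonium <- p$ammonium0 * stats::plogis(-(times - c_a) / p$ammonium_tau)
  organic_n <- p$organic_n0 *
    (1 - p$organic_n_loss *
       stats::plogis((times - p$organic_n_mid) / p$organic_n_tau))
  biomass <- p$biomass_max * stats::plogis((times - p$biomass_mid) / p$biomass_tau)
  if (p$post_depletion == "decline") {
    biomass <- biomass * exp(-p$decline_rate * pmax(0, times - p$glucose_depletion))
  }
  data.frame(time = times,
             glucose_C = glucose,
             ammonium_N = ammonium,
             total_N = organic_n + ammonium,
             biomass = biomass)
}

#' Simulate replicate chemistry trajectories
#'
#' Draws `design$n_replicates` trajectories around the closed-form mean
#' curves with multiplicative Gaussian noise (`noise_cv`), clamped at zero.
#'
#' @param design A [sim_design()].
#' @param params A [chem_params()].
#' @param seed Seed; defaults to the design seed.
#' @return data.frame (one row per replicate x time) with columns species,
#'   replicate, time, glucose_C, ammonium_N, total_N, biomass.
#' @export
simulate_chemistry <- function(design = sim_design(), params = chem_params(),
                               seed = design$seed) {
  set.seed(seed)
  mu <- chem_mean_curves(design$sampling_times, params)
  out <- do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
    noisy <- mu
    for (col in c("glucose_C", "ammonium_N", "total_N", "biomass")) {
      eps <- stats::rnorm(nrow(mu), 0, params$noise_cv)
      noisy[[col]] <- pmax(0, mu[[col]] * (1 + eps))
    }
    cbind(species = design$species_label, replicate = r, noisy)
  }))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Gene templates and count simulation

#' The default qualitative response patterns seeded by the generator
#'
#' Fifteen distinct ordered triples over \{U, D, S\} giving the state at the
#' ND, CD and pCD transitions.  They include the archetypes described for
#' the two fungi (temporary upregulation at ND; upregulation during ND and
#' CD; sustained at ND then upregulated during CD/pCD; sustained at ND then
#' downregulated; gradually decreasing) plus further patterns so the
#' classifier's full range is exercised.  Patterns are chosen so that no
#' sustained stretch sits below 1/8 of the gene's starting level: repeated
#' four-fold declines push counts toward the detection floor, where calls
#' on the remaining transitions are unreliable at n = 3 and a gene would be
#' classified into a noisy variant of its pattern instead.
#'
#' @return Character vector of 15 three-letter patterns.
#' @export
default_patterns <- function() {
  c("UDS", "USS", "UUS", "UUU", "USD",
    "SUU", "SUS", "SUD", "SDD", "SDS",
    "SSU", "SSD", "DSS", "DSD", "DUS")
}

#' Build a gene-template table
#'
#' Each template row defines a gene: its qualitative pattern (states at the
#' ND, CD and pCD transitions), log2 fold-change magnitude applied at U/D
#' transitions, expected count at t1, NB dispersion (variance = mu +
#' alpha * mu^2) and an annotation path.  Null genes are flat and carry the
#' path `"null"`.
#'
#' @param patterns Character vector of three-letter patterns over U/D/S.
#' @param n_per_pattern Genes per pattern.
#' @param n_null Flat unannotated genes.
#' @param lfc Log2 fold-change magnitude at each changing transition.
#' @param base_mean_range Range for the log-uniform draw of expected t1
#'   counts.  The defaults emulate the gene set that actually enters
#'   response-type classification in this kind of study — annotated,
#'   highly expressed and strongly changing genes — rather than the
#'   transcriptome at large, hence the high floor.
#' @param dispersion NB dispersion alpha; the default reflects the low
#'   biological variability of replicate liquid cultures for highly
#'   expressed genes.
#' @param som_fraction Fraction of each pattern's genes annotated to the
#'   SOM-interaction branch (the rest go to metabolism).
#' @param seed Seed for the base-mean draws and annotation assignment.
#' @return data.frame with columns gene_id, pattern, lfc_magnitude,
#'   base_mean, dispersion, category_path.
#' @export
gene_templates <- function(patterns = default_patterns(),
                           n_per_pattern = 20, n_null = 100,
                           lfc = 2, base_mean_range = c(200, 2000),
                           dispersion = 0.02, som_fraction = 0.5,
                           seed = 1L) {
  stopifnot(n_per_pattern >= 1, lfc >= 0, dispersion >= 0,
            all(base_mean_range > 0))
  bad <- patterns[!grepl("^[UDS]{3}$", patterns)]
  if (length(bad)) {
    stop("invalid template: patterns must be 3 characters over {U,D,S}: ",
         paste(bad, collapse = ", "))
  }
  set.seed(seed)
  som_leaves <- c("SOM/CAZyme/GH28", "SOM/CAZyme/AA9", "SOM/oxidoreductase/AA1",
                  "SOM/peptidase/A01", "SOM/Ntransport/OPT")
  met_leaves <- c("MET/carbohydrate/glycolysis", "MET/aminoacid/biosynthesis",
                  "MET/lipid/betaoxidation", "MET/energy/TCA")
  rows <- list()
  gid <- 0L
  for (p in patterns) {
    n_som <- round(som_fraction * n_per_pattern)
    for (i in seq_len(n_per_pattern)) {
      gid <- gid + 1L
      path <- if (i <= n_som) {
        som_leaves[1L + (gid %% length(som_leaves))]
      } else {
        met_leaves[1L + (gid %% length(met_leaves))]
      }
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), pattern = p,
        lfc_magnitude = lfc, base_mean = NA_real_,
        dispersion = dispersion, category_path = path)
    }
  }
  for (i in seq_len(n_null)) {
    gid <- gid + 1L
    rows[[gid]] <- data.frame(
      gene_id = sprintf("g%04d", gid), pattern = "SSS",
      lfc_magnitude = 0, base_mean = NA_real_,
      dispersion = dispersion, category_path = "null")
  }
  out <- do.call(rbind, rows)
  out$base_mean <- exp(stats::runif(nrow(out),
                                    log(base_mean_range[1]),
                                    log(base_mean_range[2])))
  out
}

#' Expected counts per time point implied by a template table
#'
#' The NB mean at time point j is `base_mean * 2^(cumulative signed lfc
#' through transition j)`, with U adding +lfc, D adding -lfc and S adding 0.
#'
#' @param templates A [gene_templates()] table.
#' @param n_timepoints Number of time points.
#' @return Matrix genes x time points of expected (unscaled) counts.
#' @export
template_means <- function(templates, n_timepoints = 4L) {
  bad <- templates$pattern[!grepl("^[UDS]+$", templates$pattern) |
                             nchar(templates$pattern) != n_timepoints - 1L]
  if (length(bad)) {
    stop("invalid template: pattern must have ", n_timepoints - 1L,
         " states over {U,D,S}; offending: ", paste(unique(bad), collapse = ", "))
  }
  states <- do.call(rbind, strsplit(templates$pattern, ""))
  signed <- (states == "U") * 1 - (states == "D") * 1
  signed <- signed * templates$lfc_magnitude
  cum <- cbind(0, t(apply(signed, 1L, cumsum)))
  mu <- templates$base_mean * 2^cum
  rownames(mu) <- templates$gene_id
  colnames(mu) <- paste0("t", seq_len(n_timepoints))
  mu
}

#' Simulate a count matrix under the template model
#'
#' Negative-binomial counts (variance = mu + alpha mu^2) around the
#' template means, with per-sample library-size factors drawn log-uniform
#' in `lib_size_range` and applied multiplicatively, so normalisation is
#' non-trivial downstream.
#'
#' @param design A [sim_design()].
#' @param templates A [gene_templates()] table.
#' @param lib_size_range Range of the log-uniform library-size factors.
#' @param seed Seed; defaults to the design seed.
#' @return List of class `count_sim`: `counts` (genes x samples integer
#'   matrix), `metadata` (sample_id, time_point, replicate), `templates`,
#'   `lib_factors`, `mu` (true unscaled means).
#' @export
simulate_counts <- function(design = sim_design(), templates = gene_templates(),
                            lib_size_range = c(0.5, 2), seed = design$seed) {
  mu <- template_means(templates, design$n_timepoints)
  set.seed(seed)
  tp <- paste0("t", seq_len(design$n_timepoints))
  meta <- expand.grid(replicate = seq_len(design$n_replicates),
                      time_point = tp, stringsAsFactors = FALSE)
  meta <- meta[order(meta$time_point, meta$replicate), c("time_point", "replicate")]
  meta$sample_id <- sprintf("%s_r%d", meta$time_point, meta$replicate)
  rownames(meta) <- NULL
  lib <- exp(stats::runif(nrow(meta), log(lib_size_range[1]), log(lib_size_range[2])))
  names(lib) <- meta$sample_id
  counts <- matrix(0L, nrow(mu), nrow(meta),
                   dimnames = list(rownames(mu), meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    m <- mu[, meta$time_point[j]] * lib[j]
    a <- templates$dispersion
    pois <- a <= 0
    x <- numeric(nrow(mu))
    if (any(pois)) x[pois] <- stats::rpois(sum(pois), m[pois])
    if (any(!pois)) {
      x[!pois] <- stats::rnbinom(sum(!pois), mu = m[!pois], size = 1 / a[!pois])
    }
    counts[, j] <- as.integer(x)
  }
  structure(list(counts = counts, metadata = meta, templates = templates,
                 lib_factors = lib, mu = mu),
            class = "count_sim")
}

# ---------------------------------------------------------------------------
# Spectral ground truth and spectra simulation

gaussian_band <- function(axis, center, width, height = 1) {
  height * exp(-(axis - center)^2 / (2 * width^2))
}

#' Four-component spectral ground truth
#'
#' Builds non-negative component spectra from Gaussian bands on a mid-IR
#' wavenumber axis and smooth non-negative concentration profiles over an
#' incubation time grid: two components decay (polysaccharide- and
#' ammonium-like, tracking nutrient uptake) and two grow (carbonyl- and
#' aromatic/amide-like, tracking oxidation products).
#'
#' By default the series is augmented with one reference-standard spectrum
#' per component (a sample containing that component alone), emulating the
#' chemometric practice of measuring standards alongside the unknowns.
#' Without such (near-)pure samples a bilinear model with only
#' non-negativity constraints is rotationally ambiguous — mixtures of the
#' true factors reproduce the data equally well — and component recovery
#' cannot be expected beyond the ambiguity bounds.
#'
#' @param n_samples Number of sampled spectra (time grid length), excluding
#'   standards.
#' @param axis Wavenumber axis, cm^-1, strictly monotone.
#' @param noise_sd Gaussian noise SD added by [simulate_spectra()];
#'   default 0.1% of the maximum noiseless intensity.
#' @param include_standards Append one single-component standard per
#'   component.
#' @return List of class `spectral_ground_truth`: `S_true` (channels x 4),
#'   `C_true` (samples x 4), `axis`, `times` (series times; standards carry
#'   `NA`), `n_standards`, `noise_sd`.
#' @export
spectral_ground_truth <- function(n_samples = 12,
                                  axis = seq(900, 1800, by = 3),
                                  noise_sd = NULL,
                                  include_standards = TRUE) {
  times <- seq(0, 700, length.out = n_samples)
  S <- cbind(
    polysaccharide = gaussian_band(axis, 1030, 60) +
      gaussian_band(axis, 1080, 40, 0.7) + gaussian_band(axis, 1150, 30, 0.5),
    ammonium = gaussian_band(axis, 1400, 50) + gaussian_band(axis, 1450, 35, 0.6),
    carbonyl = gaussian_band(axis, 1720, 30) + gaussian_band(axis, 1600, 40, 0.5),
    aromatic_amide = gaussian_band(axis, 1510, 25) +
      gaussian_band(axis, 1650, 35, 0.8) + gaussian_band(axis, 1270, 40, 0.6))
  C <- cbind(
    polysaccharide = 1.2 * stats::plogis(-(times - 400) / 60),
    ammonium = 1.5 * stats::plogis(-(times - 150) / 40),
    carbonyl = 1.0 * stats::plogis((times - 200) / 50),
    aromatic_amide = 0.9 * stats::plogis((times - 500) / 60))
  n_standards <- 0L
  if (include_standards) {
    C <- rbind(C, diag(0.8, 4))
    n_standards <- 4L
  }
  if (is.null(noise_sd)) noise_sd <- 0.001 * max(C %*% t(S))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(S_true = S, C_true = C, axis = axis, times = times,
                 n_standards = n_standards, noise_sd = noise_sd),
            class = "spectral_ground_truth")
}

#' Simulate a spectra matrix from a ground truth
#'
#' Returns `C_true %*% t(S_true)` plus i.i.d. Gaussian noise.
#'
#' @param truth A [spectral_ground_truth()].
#' @param seed Seed for the noise draw.
#' @return List of class `spectra_matrix`: `axis`, `intensities`
#'   (samples x channels), `sample_ids`.
#' @export
simulate_spectra <- function(truth = spectral_ground_truth(), seed = 1L) {
  if (truth$noise_sd < 0) stop("noise_sd must be >= 0")
  if (ncol(truth$C_true) != ncol(truth$S_true)) {
    stop("C_true and S_true are not conformable")
  }
  set.seed(seed)
  D <- truth$C_true %*% t(truth$S_true)
  if (truth$noise_sd > 0) {
    D <- D + matrix(stats::rnorm(length(D), 0, truth$noise_sd), nrow(D))
  }
  ids <- sprintf("s%02d", seq_len(nrow(D)))
  rownames(D) <- ids
  structure(list(axis = truth$axis, intensities = D, sample_ids = ids),
            class = "spectra_matrix")
}

#' Simulate an Fe K-edge pre-edge spectrum
#'
#' Two unit-area Gaussian peaks at the ferrous (7112.1 eV) and ferric
#' (7113.5 eV) reference energies, mixed by area fraction, over a linear
#' baseline, with optional Gaussian noise.
#'
#' @param ferrous_area_fraction Fraction of the pre-edge area in the
#'   ferrous peak, in \[0, 1\].
#' @param peak_width Gaussian sigma of both peaks, eV.
#' @param baseline_params `c(intercept, slope)` of the linear baseline
#'   (slope per eV, relative to the low-energy end of the grid).
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param energy Energy grid, eV.
#' @param centers `c(ferrous, ferric)` peak centers, eV.
#' @param seed Seed for the noise draw.
#' @return data.frame with columns `energy`, `intensity`.
#' @export
simulate_preedge <- function(ferrous_area_fraction, peak_width = 0.7,
                             baseline_params = c(0.02, 0.001),
                             noise_sd = 0,
                             energy = seq(7105, 7120, by = 0.05),
                             centers = c(ferrous = 7112.1, ferric = 7113.5),
                             seed = 1L) {
  f <- ferrous_area_fraction
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("ferrous_area_fraction must be in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  base <- baseline_params[1] + baseline_params[2] * (energy - min(energy))
  peak <- f * stats::dnorm(energy, centers[[1]], peak_width) +
    (1 - f) * stats::dnorm(energy, centers[[2]], peak_width)
  y <- base + peak
  if (noise_sd > 0) y <- y + stats::rnorm(length(energy), 0, noise_sd)
  data.frame(energy = energy, intensity = y)
}
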