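#' Fit the Fe K-edge pre-edge peak and compute its centroid
#'
#' The centroid energy of the baseline-subtracted pre-edge feature tracks
#' the iron oxidation state: a pure-ferrous feature sits near 7112.1 eV and
#' a pure-ferric one near 7113.5 eV.  A baseline is fitted to two flanking
#' sub-windows (default 1 eV wide at each end of the window) and
#' interpolated beneath the peak; the net intensity is then fitted with up
#' to two symmetric Gaussian peaks.  The centroid is the area-weighted mean
#' of the fitted peak centers (equivalently `int E I(E) dE / int I(E) dE`
#' over the fitted peaks), and the integrated area is the summed peak area.
#'
#' @param spectrum data.frame or matrix with energy (eV) and intensity
#'   columns, as from [simulate_preedge()].
#' @param window `c(lo, hi)` fit window in eV; must contain >= 20 points.
#' @param n_peaks 1 or 2 symmetric peaks.
#' @param baseline_model `"linear"` or `"cubic"` baseline over the flanks.
#' @param flank_width Width of each flanking baseline sub-window, eV.
#' @param ref_ferrous,ref_ferric Reference centroid energies used both as
#'   starting centers and for [ferrous_fraction()].
#' @return Object of class `preedge_result`: `centroid` (eV),
#'   `integrated_area`, `peaks` (data.frame center/width/area/amplitude),
#'   `baseline` (coefficients), `ferrous_fraction`, `window`.
#' @export
fit_preedge <- function(spectrum, window = c(7109, 7117), n_peaks = 2,
                        baseline_model = c("linear", "cubic"),
                        flank_width = 1,
                        ref_ferrous = 7112.1, ref_ferric = 7113.5) {
  baseline_model <- match.arg(baseline_model)
  spectrum <- as.data.frame(spectrum)
  names(spectrum)[1:2] <- c("energy", "intensity")
  inw <- spectrum$energy >= window[1] & spectrum$energy <= window[2]
  if (sum(inw) < 20) stop("fewer than 20 points in the fit window")
  E <- spectrum$energy[inw]
  y <- spectrum$intensity[inw]
  flank <- E <= window[1] + flank_width | E >= window[2] - flank_width
  bfit <- if (baseline_model == "linear") {
    stats::lm(y ~ E, subset = flank)
  } else {
    stats::lm(y ~ poly(E, 3), subset = flank)
  }
  base <- stats::predict(bfit, newdata = data.frame(E = E))
  net <- y - base
  if (all(net <= 0) || max(net) <= 1e-9 * max(abs(y), 1e-300)) {
    stop("no-peak: baseline-subtracted intensity is nowhere positive")
  }

  fit_n <- function(np) {
    amp0 <- max(net)
    if (np == 1L) {
      start <- list(a1 = amp0, c1 = E[which.max(net)], w1 = 0.7)
      lower <- c(0, window[1], 0.1)
      upper <- c(Inf, window[2], 5)
      form <- net ~ a1 * exp(-(E - c1)^2 / (2 * w1^2))
    } else {
      start <- list(a1 = amp0 / 2, c1 = ref_ferrous, w1 = 0.7,
                    a2 = amp0 / 2, c2 = ref_ferric, w2 = 0.7)
      lower <- c(0, window[1], 0.1, 0, window[1], 0.1)
      upper <- c(Inf, window[2], 5, Inf, window[2], 5)
      form <- net ~ a1 * exp(-(E - c1)^2 / (2 * w1^2)) +
        a2 * exp(-(E - c2)^2 / (2 * w2^2))
    }
    minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(fit_n(n_peaks), error = function(e) e)
  if (inherits(fit, "error") && n_peaks == 2L) {
    # a redundant second component on a one-peak feature can be singular;
    # refit with the reduced model
    fit <- tryCatch(fit_n(1L), error = function(e) e)
  }
  if (inherits(fit, "error")) {
    stop("pre-edge peak fit did not converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  np <- length(cf) / 3L
  peaks <- data.frame(
    amplitude = cf[paste0("a", seq_len(np))],
    center = cf[paste0("c", seq_len(np))],
    width = cf[paste0("w", seq_len(np))])
  peaks$area <- peaks$amplitude * peaks$width * sqrt(2 * pi)
  # discard numerically empty components so they cannot bias the centroid
  peaks <- peaks[peaks$area > 1e-8 * max(sum(peaks$area), .Machine$double.eps), ,
                 drop = FALSE]
  if (!nrow(peaks) || sum(peaks$area) <= 0) {
    stop("no-peak: fitted peak area is zero")
  }
  centroid <- sum(peaks$area * peaks$center) / sum(peaks$area)
  structure(
    list(centroid = centroid,
         integrated_area = sum(peaks$area),
         peaks = peaks,
         baseline = stats::coef(bfit),
         ferrous_fraction = ferrous_fraction(centroid, ref_ferrous, ref_ferric),
         window = window),
    class = "preedge_result")
}

#' Ferrous area fraction from a pre-edge centroid
#'
#' Linear interpolation between the ferric and ferrous reference centroid
#' energies, clipped to \[0, 1\].  This is a first-order approximation; the
#' centroid-composition relation can be non-linear for some mineral
#' mixtures, but it is adequate between two symmetric end-member peaks.
#'
#' @param centroid Centroid energy, eV.
#' @param ref_ferrous,ref_ferric Reference centroids, eV
#'   (`ref_ferrous < ref_ferric`).
#' @return Ferrous fraction in \[0, 1\].
#' @export
ferrous_fraction <- function(centroid, ref_ferrous = 7112.1,
                             ref_ferric = 7113.5) {
  if (any(!is.finite(centroid))) stop("non-finite centroid")
  if (ref_ferrous >= ref_ferric) stop("ref_ferrous must be < ref_ferric")
  pmin(1, pmax(0, (ref_ferric - centroid) / (ref_ferric - ref_ferrous)))
}

#' One-way ANOVA on pre-edge centroids across treatments
#'
#' @param groups Named list of numeric centroid vectors, one per treatment
#'   group (>= 2 groups with >= 2 values each).
#' @return List with `F`, `p`, `df` (between, within).
#' @export
compare_centroids <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  sst <- sum((unlist(groups) - mean(unlist(groups)))^2)
  if (ssw <= 1e-12 * max(sst, 1e-300)) {
    stop("degenerate: zero within-group variance in all groups")
  }
  # center the values: F is location-invariant, and absolute energies in
  # the thousands of eV would otherwise trip lm's perfect-fit heuristics
  vals <- unlist(groups, use.names = FALSE)
  df <- data.frame(
    value = vals - mean(vals),
    group = factor(rep(names(groups), vapply(groups, length, 1L))))
  an <- stats::anova(stats::lm(value ~ group, data = df))
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1], df = an$Df)
}

#' Relative abundances of N K-edge pi* transitions
#'
#' Converts per-sample peak areas of the four pi* transitions (pyridine,
#' nitrile, amide, pyrrole) into relative abundances summing to one.  The
#' attached transition energies are literature-typical configuration
#' defaults, not fitted values.
#'
#' @param areas Matrix or data.frame (samples x 4) of non-negative peak
#'   areas, or a single numeric vector of length 4.
#' @param transition_energies Named energies (eV) attached as an attribute.
#' @return data.frame of per-sample relative abundances with attribute
#'   `transition_energies`.
#' @export
n_speciation <- function(areas,
                         transition_energies = c(pyridine = 398.8,
                                                 nitrile = 399.7,
                                                 amide = 401.2,
                                                 pyrrole = 402.6)) {
  if (is.vector(areas) && is.numeric(areas)) areas <- matrix(areas, nrow = 1)
  areas <- as.matrix(areas)
  if (ncol(areas) != 4) stop("expected areas for 4 pi* transitions")
  if (any(areas < 0)) stop("areas must be >= 0")
  tot <- rowSums(areas)
  if (any(tot == 0)) stop("all-zero areas in at least one sample")
  rel <- sweep(areas, 1, tot, "/")
  colnames(rel) <- names(transition_energies)
  out <- as.data.frame(rel)
  attr(out, "transition_energies") <- transition_energies
  out
}

#' PCA ordination of N-speciation tables
#'
#' Principal component analysis of the column-centered relative-abundance
#' table; with all axes retained, `scores %*% t(loadings)` reconstructs the
#' centered table.
#'
#' @param tables Samples x transitions matrix or data.frame of relative
#'   abundances (>= 3 samples).
#' @return List with `scores`, `loadings`, `variance_explained` (percent
#'   per axis) and `center`.
#' @export
pca_ordination <- function(tables) {
  X <- as.matrix(tables)
  if (nrow(X) < 3) stop("need >= 3 samples for ordination")
  if (all(apply(X, 2, stats::sd) < 1e-12)) {
    warning("degenerate: constant table, all axes have zero variance")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pr$x,
       loadings = pr$rotation,
       variance_explained = 100 * pr$sdev^2 / sum(pr$sdev^2),
       center = pr$center)
}
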