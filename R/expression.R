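#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples.  Reference genes are
#' those with nonzero counts in every sample; if none exist, setting
#' `pseudo_reference = TRUE` adds 0.5 to all counts for the reference
#' computation.
#'
#' @param counts Genes x samples matrix of non-negative integers.
#' @param pseudo_reference Use a 0.5 pseudocount when no gene is nonzero in
#'   all samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  use <- rowSums(counts == 0) == 0
  work <- counts
  if (!any(use)) {
    if (!pseudo_reference) {
      stop("no gene with nonzero counts in all samples; ",
           "set pseudo_reference = TRUE to use a pseudo-reference")
    }
    work <- counts + 0.5
    use <- rep(TRUE, nrow(work))
  }
  lg <- log(work[use, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-positive size factor")
  sf
}

row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Moderated method-of-moments NB dispersion
#'
#' On normalised counts x = y / sf, the within-group variance satisfies
#' approximately `v = q * mean(1/sf) + alpha * q^2`; the gene-wise alpha is
#' pooled across groups with weights (n_g - 1).  Because a per-gene moment
#' estimate from a handful of replicates is very noisy (and makes both the
#' LRT and Wald tests anticonservative), the raw estimate is shrunk toward
#' the cohort median with `prior_df` pseudo-degrees of freedom,
#' `alpha = (d * alpha_gene + prior_df * alpha_cohort) / (d + prior_df)`
#' where d is the pooled residual degrees of freedom, then floored.
#'
#' @param counts Genes x samples counts.
#' @param sf Size factors.
#' @param groups Factor of group labels per sample.
#' @param floor Minimum dispersion.
#' @param prior_df Weight of the cohort median in the shrinkage.
#' @return Numeric vector of gene-wise dispersions.
#' @export
estimate_dispersion <- function(counts, sf, groups, floor = 0.01,
                                prior_df = 20) {
  counts <- as.matrix(counts)
  x <- sweep(counts, 2, sf, "/")
  groups <- as.factor(groups)
  num <- den <- numeric(nrow(counts))
  d <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    xg <- x[, idx, drop = FALSE]
    m <- rowMeans(xg)
    v <- row_vars(xg)
    cg <- mean(1 / sf[idx])
    w <- length(idx) - 1
    num <- num + w * (v - m * cg)
    # E[m^2] = q^2 + var(m); subtract v/n so the denominator estimates q^2
    # without upward bias (which would bias alpha downward)
    den <- den + w * pmax(m^2 - v / length(idx), 0)
    d <- d + w
  }
  alpha <- ifelse(den > 0, num / den, NA_real_)
  alpha[!is.finite(alpha)] <- NA_real_
  # cohort center: totals ratio, robust to the right skew of per-gene
  # moment estimates (a median would sit below the shared true value)
  alpha0 <- if (sum(den) > 0) sum(num) / sum(den) else floor
  if (!is.finite(alpha0)) alpha0 <- floor
  alpha[is.na(alpha)] <- alpha0
  shrunk <- (d * alpha + prior_df * alpha0) / (d + prior_df)
  pmin(pmax(shrunk, floor), 20)
}

nb_loglik <- function(counts, mu, alpha) {
  size <- matrix(1 / alpha, nrow(counts), ncol(counts))
  mu <- pmax(mu, 1e-12)
  rowSums(stats::dnbinom(counts, size = size, mu = mu, log = TRUE))
}

group_q <- function(counts, sf, groups) {
  groups <- as.factor(groups)
  q <- sapply(levels(groups), function(g) {
    idx <- which(groups == g)
    rowSums(counts[, idx, drop = FALSE]) / sum(sf[idx])
  })
  matrix(q, nrow = nrow(counts), dimnames = list(rownames(counts), levels(groups)))
}

#' Likelihood-ratio test for overall change across the time course
#'
#' Per gene, compares an NB model with one mean per time point against an
#' intercept-only model, with size factors as multiplicative offsets and a
#' gene-wise moderated moment-estimated dispersion (see
#' [estimate_dispersion()]; the moderation keeps the chi-squared reference
#' with (T - 1) degrees of freedom calibrated at n = 3 replicates).
#' All-zero genes are untestable and get p = 1.
#'
#' @param counts Genes x samples matrix of counts.
#' @param metadata data.frame with `sample_id` and `time_point`, one row
#'   per column of `counts` (in column order).
#' @param sf Size factors; computed from `counts` if `NULL`.
#' @param min_dispersion Dispersion floor.
#' @param alpha Adjusted-p cutoff for the time-DEG flag.
#' @return data.frame: gene_id, stat, df, p, p_adj, time_deg, testable,
#'   plus mean normalised expression per time point (`mean_t1`, ...).
#' @export
test_time_course <- function(counts, metadata, sf = NULL,
                             min_dispersion = 0.01, prior_df = 20,
                             alpha = 0.01) {
  counts <- as.matrix(counts)
  groups <- as.factor(metadata$time_point)
  if (nlevels(groups) < 2) stop("need >= 2 time points")
  if (length(groups) != ncol(counts)) stop("metadata rows must match count columns")
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersion(counts, sf, groups, floor = min_dispersion,
                              prior_df = prior_df)
  qg <- group_q(counts, sf, groups)
  q0 <- rowSums(counts) / sum(sf)
  mu_full <- qg[, as.character(groups), drop = FALSE] *
    matrix(sf, nrow(counts), ncol(counts), byrow = TRUE)
  mu_null <- q0 %o% sf
  ll_full <- nb_loglik(counts, mu_full, disp)
  ll_null <- nb_loglik(counts, mu_null, disp)
  stat <- pmax(0, 2 * (ll_full - ll_null))
  df <- nlevels(groups) - 1L
  testable <- rowSums(counts) > 0
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p[!testable] <- 1
  p_adj <- adjust_bh(p)
  means <- sweep(counts, 2, sf, "/")
  group_means <- sapply(levels(groups), function(g) {
    rowMeans(means[, groups == g, drop = FALSE])
  })
  out <- data.frame(gene_id = rownames(counts), stat = stat, df = df,
                    p = p, p_adj = p_adj,
                    time_deg = testable & p_adj < alpha,
                    testable = testable)
  gm <- as.data.frame(group_means)
  names(gm) <- paste0("mean_", levels(groups))
  cbind(out, gm)
}

#' Wald test for a pairwise contrast
#'
#' Estimates the log2 fold-change of normalised means between two time
#' points with a 0.5 pseudocount (so genes absent from one group get a
#' finite estimate), a delta-method standard error under the NB variance
#' `mu + alpha mu^2` with the moderated dispersion of
#' [estimate_dispersion()], and a two-sided normal reference for
#' `lfc / se(lfc)`.  Genes with zero counts in both groups are untestable.
#'
#' @param counts Genes x samples matrix of counts.
#' @param metadata data.frame with `time_point` per column of `counts`.
#' @param tx Numerator time point (e.g. "t2").
#' @param tref Denominator time point (default "t1").
#' @param sf Size factors; computed from the full matrix if `NULL`.
#' @param pseudocount Pseudocount on the normalised-mean scale.
#' @param min_dispersion Dispersion floor.
#' @return data.frame: gene_id, lfc, se, stat, p, p_adj, mean_tx,
#'   mean_tref, testable.
#' @export
test_pairwise <- function(counts, metadata, tx, tref = "t1", sf = NULL,
                          pseudocount = 0.5, min_dispersion = 0.01,
                          prior_df = 20) {
  counts <- as.matrix(counts)
  tp <- as.character(metadata$time_point)
  if (!all(c(tx, tref) %in% tp)) stop("time points not present: ", tx, " vs ", tref)
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  keep <- tp %in% c(tx, tref)
  sub <- counts[, keep, drop = FALSE]
  sfk <- sf[keep]
  grp <- factor(tp[keep], levels = c(tref, tx))
  disp <- estimate_dispersion(sub, sfk, grp, floor = min_dispersion,
                              prior_df = prior_df)
  q <- group_q(sub, sfk, grp)
  q_ref <- q[, tref]
  q_x <- q[, tx]
  var_q <- function(qv, idx) {
    ssf <- sum(sfk[idx]); ssf2 <- sum(sfk[idx]^2)
    (qv * ssf + disp * qv^2 * ssf2) / ssf^2
  }
  v_ref <- var_q(q_ref, which(grp == tref))
  v_x <- var_q(q_x, which(grp == tx))
  lfc <- log2((q_x + pseudocount) / (q_ref + pseudocount))
  ln2sq <- log(2)^2
  se <- sqrt(v_x / ((q_x + pseudocount)^2 * ln2sq) +
               v_ref / ((q_ref + pseudocount)^2 * ln2sq))
  testable <- rowSums(sub) > 0
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  p[!testable] <- 1
  data.frame(gene_id = rownames(counts), lfc = lfc, se = se, stat = stat,
             p = p, p_adj = adjust_bh(p),
             mean_tx = q_x, mean_tref = q_ref, testable = testable)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in input order.
#'
#' @param p Vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select onset genes (highly expressed and upregulated at t2)
#'
#' Genes whose mean normalised expression at t2 is in the top
#' `top_quantile` of the expression universe, with a pairwise t2 vs t1
#' log2 fold-change above `log2(min_fold)` at `p_adj < alpha`.  The
#' quantile is computed over genes with nonzero total count.
#'
#' @param de [test_pairwise()] result for the t2 vs t1 contrast.
#' @param expr_t2 Named vector of mean normalised t2 expression per gene.
#' @param total_counts Optional named vector of total counts defining the
#'   nonzero universe; defaults to `expr_t2 > 0`.
#' @param top_quantile Fraction defining "most highly expressed".
#' @param min_fold Minimum fold-change.
#' @param alpha Adjusted-p cutoff.
#' @return Character vector of gene ids.
#' @export
select_onset_genes <- function(de, expr_t2, total_counts = NULL,
                               top_quantile = 0.20, min_fold = 2,
                               alpha = 0.01) {
  if (is.null(names(expr_t2))) names(expr_t2) <- de$gene_id
  universe <- if (is.null(total_counts)) {
    names(expr_t2)[expr_t2 > 0]
  } else {
    names(total_counts)[total_counts > 0]
  }
  universe <- intersect(universe, names(expr_t2))
  if (!length(universe)) stop("empty gene universe")
  thr <- stats::quantile(expr_t2[universe], 1 - top_quantile, names = FALSE)
  ok <- de$gene_id[expr_t2[de$gene_id] >= thr &
                     de$lfc > log2(min_fold) &
                     de$p_adj < alpha]
  ok[!is.na(ok)]
}
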