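#' Non-negative least squares for many right-hand sides
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` for every column `b` of
#' `B`, with a shared design matrix `A`.  For small numbers of components
#' (k <= 12, the regime of curve-resolution models) the exact optimum is
#' found by enumerating active sets: for each support the unconstrained
#' normal-equation solution is computed for all columns at once, and the
#' best feasible support per column is kept.  The global NNLS optimum is
#' itself the unconstrained solution on its own support, so the minimum
#' over feasible supports is exact.  For k > 12 the Lawson-Hanson solver
#' (`pracma::lsqnonneg`) is used column by column.
#'
#' @param A m x k design matrix.
#' @param B m x n matrix of right-hand sides (or a vector).
#' @return k x n matrix of non-negative coefficients.
#' @export
nnls_multi <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows")
  k <- ncol(A)
  n <- ncol(B)
  if (k > 12) {
    X <- vapply(seq_len(n), function(j) pracma::lsqnonneg(A, B[, j])$x,
                numeric(k))
    return(matrix(X, nrow = k))
  }
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  bb <- colSums(B^2)
  best_rss <- bb               # empty support: x = 0
  X <- matrix(0, k, n)
  for (mask in seq_len(2^k - 1L)) {
    P <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    sol <- tryCatch(solve(AtA[P, P, drop = FALSE], AtB[P, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    feas <- colSums(sol < -1e-10) == 0
    if (!any(feas)) next
    rss <- bb - colSums(sol * AtB[P, , drop = FALSE])
    upd <- feas & rss < best_rss
    if (any(upd)) {
      X[, upd] <- 0
      X[P, upd] <- pmax(sol[, upd, drop = FALSE], 0)
      best_rss[upd] <- rss[upd]
    }
  }
  X
}

as_spectra_matrix <- function(D) {
  if (inherits(D, "spectra_matrix")) return(D)
  D <- as.matrix(D)
  structure(list(axis = seq_len(ncol(D)), intensities = D,
                 sample_ids = rownames(D)),
            class = "spectra_matrix")
}

#' Percent variance of a spectra matrix explained by bilinear factors
#'
#' `100 * (1 - ||D - C S'||_F^2 / ||D||_F^2)`.
#'
#' @param D Spectra matrix (samples x channels) or `spectra_matrix` object.
#' @param C Samples x k concentration matrix.
#' @param S Channels x k spectra matrix.
#' @return Percent explained variance.
#' @export
explained_variance <- function(D, C, S) {
  D <- as_spectra_matrix(D)$intensities
  if (nrow(C) != nrow(D) || nrow(S) != ncol(D) || ncol(C) != ncol(S)) {
    stop("non-conformable factor dimensions")
  }
  tot <- sum(D^2)
  if (tot == 0) stop("degenerate input: D has zero norm")
  100 * (1 - sum((D - C %*% t(S))^2) / tot)
}

# purest-variable initialisation: channels of maximal relative standard
# deviation, sequentially corrected for orthogonality to channels already
# selected (SIMPLISMA-flavoured)
purest_init <- function(D, k, noise_frac = 0.05) {
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  purity <- sdv / (mu + noise_frac * max(mu))
  norms <- sqrt(colSums(D^2))
  sel <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1L) {
      w <- rep(1, ncol(D))
    } else {
      Q <- qr.Q(qr(D[, sel, drop = FALSE]))
      resid <- D - Q %*% crossprod(Q, D)
      w <- sqrt(colSums(resid^2)) / (norms + .Machine$double.eps)
    }
    score <- purity * w
    score[sel] <- -Inf
    sel <- c(sel, which.max(score))
  }
  pmax(D[, sel, drop = FALSE], 0)
}

als_run <- function(D, C0, tol, max_iter) {
  C <- C0
  rss_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  St <- NULL
  for (it in seq_len(max_iter)) {
    St <- nnls_multi(C, D)                 # k x channels, D ~ C St
    C <- t(nnls_multi(t(St), t(D)))        # samples x k
    rss <- sum((D - C %*% St)^2)
    trace <- c(trace, rss)
    if (is.finite(rss_prev) &&
        (rss_prev - rss) <= tol * max(rss_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  list(C = C, S = t(St), rss = trace[length(trace)], rss_trace = trace,
       n_iter = length(trace), converged = converged)
}

#' Fit a multivariate curve resolution model by alternating least squares
#'
#' Factorises a samples x channels spectra matrix as `D ~ C S'` with
#' non-negativity on both the concentration profiles `C` and the component
#' spectra `S`.  Each half-step is an exact non-negative least-squares
#' solve, so the residual sum of squares is non-increasing across
#' iterations.  The first restart uses purest-variable initialisation; the
#' remaining restarts are seeded-random.  The best restart (lowest residual)
#' is returned, with spectra normalised to unit maximum and the scale
#' absorbed into `C`.
#'
#' @param D A `spectra_matrix` (see [simulate_spectra()]) or plain
#'   samples x channels matrix.
#' @param k Number of components, `1 <= k <= min(dim(D))`.
#' @param init `"purest"` (default) or `"random"` for the first restart.
#' @param tol Relative change in residual sum of squares below which the
#'   iteration stops.
#' @param max_iter Maximum ALS iterations per restart.
#' @param n_restarts Total restarts (including the purest-variable one).
#' @param seed Seed for the random restarts.
#' @return Object of class `mcr_result`: `C`, `S`, `axis`, `k`,
#'   `explained_variance` (percent), `rss`, `rss_trace`, `n_iter`,
#'   `converged`, `restart`.
#' @export
fit_mcr <- function(D, k, init = c("purest", "random"),
                    tol = 1e-8, max_iter = 500, n_restarts = 5, seed = 1L) {
  init <- match.arg(init)
  sm <- as_spectra_matrix(D)
  X <- sm$intensities
  if (any(!is.finite(X))) stop("spectra contain non-finite values")
  if (sum(X^2) == 0) stop("degenerate input: all-zero spectra matrix")
  if (k < 1 || k > min(dim(X))) {
    stop("k must be between 1 and min(samples, channels) = ", min(dim(X)))
  }
  best <- NULL
  best_restart <- NA_integer_
  for (r in seq_len(max(1L, n_restarts))) {
    if (r == 1L && init == "purest") {
      C0 <- purest_init(X, k)
      # degenerate purest columns (all zero) fall back to random
      zero_cols <- colSums(C0) == 0
      if (any(zero_cols)) {
        set.seed(seed)
        C0[, zero_cols] <- matrix(stats::runif(nrow(X) * sum(zero_cols),
                                               0, max(X)),
                                  nrow(X))
      }
    } else {
      set.seed(seed + r)
      C0 <- matrix(stats::runif(nrow(X) * k, 0, max(X)), nrow(X), k)
    }
    fit <- als_run(X, C0, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$rss < best$rss) {
      best <- fit
      best_restart <- r
    }
  }
  C <- best$C
  S <- best$S
  scale <- apply(S, 2, max)
  scale[scale <= 0] <- 1
  S <- sweep(S, 2, scale, "/")
  C <- sweep(C, 2, scale, "*")
  colnames(S) <- colnames(C) <- paste0("comp", seq_len(k))
  rownames(C) <- sm$sample_ids
  structure(
    list(C = C, S = S, axis = sm$axis, k = k,
         explained_variance = explained_variance(X, C, S),
         rss = best$rss, rss_trace = best$rss_trace,
         n_iter = best$n_iter, converged = best$converged,
         restart = best_restart),
    class = "mcr_result")
}

#' Select the number of spectral components
#'
#' Fits models with k = 1, 2, ... and returns the smallest k whose best
#' fit reaches `ev_threshold` percent explained variance.  If no k up to
#' `k_max` reaches the threshold, `k_max` is returned with a warning and
#' the attribute `reached = FALSE`.
#'
#' @param D Spectra matrix.
#' @param k_max Largest number of components to try.
#' @param ev_threshold Percent explained variance required.
#' @param ... Passed to [fit_mcr()].
#' @return Integer k, with attributes `ev_trace` (percent EV for each k
#'   tried) and `reached` (logical).
#' @export
select_components <- function(D, k_max = 6, ev_threshold = 99.9, ...) {
  if (k_max < 1) stop("k_max must be >= 1")
  evs <- numeric(0)
  for (k in seq_len(k_max)) {
    fit <- fit_mcr(D, k, ...)
    evs[k] <- fit$explained_variance
    if (fit$explained_variance >= ev_threshold) {
      return(structure(k, ev_trace = evs, reached = TRUE))
    }
  }
  warning("explained-variance threshold ", ev_threshold,
          "% not reached at k_max = ", k_max)
  structure(k_max, ev_trace = evs, reached = FALSE)
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("MCR-ALS fit: k = %d, explained variance = %.4f%%, %d iterations (%s), restart %d\n",
              x$k, x$explained_variance, x$n_iter,
              if (x$converged) "converged" else "max_iter reached", x$restart))
  invisible(x)
}
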