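#' Detect the four nutritional phases from a chemistry trajectory
#'
#' The incubation passes through active growth (AG, both glucose and
#' ammonium present), ammonium depletion (ND), carbon depletion (CD, glucose
#' below its detection limit of 1 mg glucose-C L^-1) and prolonged carbon
#' depletion (pCD).  One sampled time is selected per phase:
#' \itemize{
#'   \item t1 (AG): the latest sampled time with glucose above
#'     `glucose_threshold` and ammonium above `ammonium_threshold`;
#'   \item t2 (ND): the earliest time with ammonium at or below its
#'     threshold while glucose is still above its threshold;
#'   \item t3 (CD): the earliest time with glucose at or below its
#'     threshold;
#'   \item t4 (pCD): the earliest sampled time at least `pcd_lag` hours
#'     after t3.
#' }
#' Replicate trajectories are averaged per time point before thresholding.
#'
#' @param traj Chemistry data.frame as returned by [simulate_chemistry()]
#'   (columns time, glucose_C, ammonium_N; replicate optional).
#' @param glucose_threshold Glucose detection limit, mg C L^-1.
#' @param ammonium_threshold Ammonium depletion threshold, mg N L^-1.
#'   Default: 2% of the ammonium concentration at the first sampled time
#'   (scale-free, since depletion is reported graphically in this kind of
#'   assay).
#' @param pcd_lag Hours after t3 defining "prolonged" carbon limitation.
#' @return Object of class `phase_assignment`: numeric `times` (t1..t4),
#'   `labels` c("AG","ND","CD","pCD"), and the thresholds used.
#' @export
detect_phases <- function(traj, glucose_threshold = 1,
                          ammonium_threshold = NULL, pcd_lag = 150) {
  need <- c("time", "glucose_C", "ammonium_N")
  if (!all(need %in% names(traj))) {
    stop("trajectory must have columns: ", paste(need, collapse = ", "))
  }
  avg <- stats::aggregate(traj[c("glucose_C", "ammonium_N")],
                          by = list(time = traj$time), FUN = mean)
  avg <- avg[order(avg$time), ]
  if (any(diff(avg$time) <= 0)) stop("invalid trajectory: times must be strictly increasing")
  if (is.null(ammonium_threshold)) {
    ammonium_threshold <- 0.02 * avg$ammonium_N[1]
  }
  tt <- avg$time
  glc_up <- avg$glucose_C > glucose_threshold
  amm_up <- avg$ammonium_N > ammonium_threshold

  if (!any(!glc_up)) {
    stop("incomplete-phase: glucose never depleted, no CD phase reached")
  }
  if (!any(!amm_up)) {
    stop("incomplete-phase: ammonium never depleted, no ND phase reached")
  }
  t_cd <- min(tt[!glc_up])
  t_nd_candidates <- tt[!amm_up & glc_up]
  if (!length(t_nd_candidates) || min(tt[!amm_up]) >= t_cd) {
    stop("phase-order error: ammonium depletes after (or with) glucose")
  }
  t_nd <- min(t_nd_candidates)
  ag_candidates <- tt[glc_up & amm_up]
  if (!length(ag_candidates)) {
    stop("incomplete-phase: no AG phase (both nutrients present) observed")
  }
  t_ag <- max(ag_candidates)
  pcd_candidates <- tt[tt >= t_cd + pcd_lag]
  if (!length(pcd_candidates)) {
    stop("incomplete-phase: trajectory ends before the pCD phase")
  }
  t_pcd <- min(pcd_candidates)
  times <- c(t1 = t_ag, t2 = t_nd, t3 = t_cd, t4 = t_pcd)
  if (any(diff(times) <= 0)) {
    stop("phase-order error: selected times are not strictly increasing")
  }
  structure(
    list(times = times,
         labels = c("AG", "ND", "CD", "pCD"),
         glucose_threshold = glucose_threshold,
         ammonium_threshold = ammonium_threshold,
         pcd_lag = pcd_lag),
    class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("Nutritional phases:\n")
  for (i in seq_along(x$times)) {
    cat(sprintf("  %-4s %s = %g h\n", x$labels[i], names(x$times)[i], x$times[i]))
  }
  cat(sprintf("  thresholds: glucose <= %g mg C/L, ammonium <= %g mg N/L; pCD lag %g h\n",
              x$glucose_threshold, x$ammonium_threshold, x$pcd_lag))
  invisible(x)
}
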