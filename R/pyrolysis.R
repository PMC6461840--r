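#' Lignin side-chain oxidation marker Ox/C3-G
#'
#' Ratio of the 4-acetylguaiacol (Ox-G) to trans-propenylguaiacol (C3-G)
#' pyrolysis peak areas, corrected for total organic carbon and normalised
#' to an unincubated control extract.  Per sample,
#' `raw = ox_g / c3g`; the TOC correction divides (default) or multiplies
#' the raw ratio by `toc_sample / toc_control`; the reported value is the
#' corrected ratio divided by the control's raw ratio, so the control maps
#' to 1 by construction.  When several control replicates are flagged,
#' their mean raw ratio and mean TOC are used.
#'
#' @param markers data.frame with columns `sample_id`, `ox_g`, `c3g`,
#'   `toc`, and logical `control` (at least one control row unless
#'   `control` rows are passed separately via `control_data`).
#' @param control_data Optional data.frame of control rows with the same
#'   columns (overrides the `control` flag).
#' @param toc_mode `"divide"` (default) or `"multiply"`: direction of the
#'   TOC correction.
#' @return data.frame with columns `sample_id`, `raw_ratio`, `ratio`
#'   (TOC-corrected, control-normalised).
#' @export
ox_c3g <- function(markers, control_data = NULL,
                   toc_mode = c("divide", "multiply")) {
  toc_mode <- match.arg(toc_mode)
  markers <- as.data.frame(markers)
  need <- c("sample_id", "ox_g", "c3g", "toc")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(control_data)) {
    if (!"control" %in% names(markers)) stop("no control rows identified")
    control_data <- markers[markers$control, , drop = FALSE]
    markers <- markers[!markers$control, , drop = FALSE]
  }
  if (!nrow(control_data)) stop("no control rows identified")
  if (any(markers$c3g <= 0) || any(control_data$c3g <= 0)) {
    stop("undefined-ratio: zero or negative C3-G peak area")
  }
  if (any(markers$toc <= 0) || any(control_data$toc <= 0)) {
    stop("zero or negative TOC")
  }
  ctrl_raw <- mean(control_data$ox_g / control_data$c3g)
  ctrl_toc <- mean(control_data$toc)
  raw <- markers$ox_g / markers$c3g
  rel_toc <- markers$toc / ctrl_toc
  corrected <- if (toc_mode == "divide") raw / rel_toc else raw * rel_toc
  data.frame(sample_id = markers$sample_id,
             raw_ratio = raw,
             ratio = corrected / ctrl_raw)
}
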