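#' Colony-screen counts
#'
#' A colony that grows on permissive medium but not under antibiotic
#' selection is scored as having lost the plasmid.
#'
#' @param n_total colonies screened.
#' @param n_lost colonies scored as plasmid-free.
#' @return object of class `assay_counts`.
#' @export
assay_counts <- function(n_total, n_lost) {
  n_total <- as.integer(n_total); n_lost <- as.integer(n_lost)
  stopifnot(n_total >= 1L, n_lost >= 0L, n_lost <= n_total)
  structure(list(n_total = n_total, n_lost = n_lost),
            class = "assay_counts")
}

#' Plasmid-loss fraction with Wilson 95% interval
#'
#' @param counts an [assay_counts()] object (or list with `n_total`,
#'   `n_lost`).
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n_total`, `n_lost`.
#' @export
loss_fraction <- function(counts, conf = 0.95) {
  ci <- wilson_ci(counts$n_lost, counts$n_total, conf)
  c(ci, list(n_total = counts$n_total, n_lost = counts$n_lost))
}

#' Phage titer from plaque counts
#'
#' Titer per admissible plate is `count * 10^-dilution_exponent /
#' plated_volume_ml` pfu/ml; only plates with 30-300 plaques are used and
#' the reported titer is their mean. Inadmissible plates are reported, not
#' used.
#'
#' @param records data.frame with `plaque_count` and `dilution_exponent`
#'   (the exponent of the dilution plated, e.g. -6 for a 10^-6 dilution).
#' @param plated_volume_ml volume plated per plate (default 0.1 ml).
#' @param min_plaques,max_plaques admissibility window (default 30-300).
#' @return list with `titer_pfu_per_ml`, `n_used`, `per_plate` (titers of
#'   admissible plates), `rejected` (row indices of inadmissible plates).
#' @export
titer_from_counts <- function(records, plated_volume_ml = 0.1,
                              min_plaques = 30L, max_plaques = 300L) {
  stopifnot(nrow(records) >= 1L)
  ok <- records$plaque_count >= min_plaques &
        records$plaque_count <= max_plaques
  if (!any(ok)) {
    stop(sprintf("no plate with %d-%d plaques; titer not estimable",
                 min_plaques, max_plaques))
  }
  per_plate <- records$plaque_count[ok] *
    10^(-records$dilution_exponent[ok]) / plated_volume_ml
  list(titer_pfu_per_ml = mean(per_plate),
       n_used = sum(ok),
       per_plate = per_plate,
       rejected = which(!ok))
}

#' Log reduction in phage titer and efficiency of plaquing
#'
#' `log_reduction = log10(titer_sensitive / titer_resistant)` and
#' `EOP = titer_resistant / titer_sensitive`, so `EOP * 10^log_reduction`
#' is exactly 1. A zero resistant-strain titer is censored at the assay's
#' detection limit rather than reported as infinite.
#'
#' @param titer_sensitive titer on the sensitive host (pfu/ml).
#' @param titer_resistant titer on the test strain (pfu/ml).
#' @param detection_limit smallest detectable titer (pfu/ml); required
#'   when `titer_resistant` is zero.
#' @return list with `log_reduction`, `eop`, `censored` (logical) and
#'   `display` (e.g. `"> 5.0 logs"` for censored results).
#' @export
log_reduction <- function(titer_sensitive, titer_resistant,
                          detection_limit = NULL) {
  stopifnot(titer_sensitive > 0, titer_resistant >= 0)
  if (titer_resistant == 0) {
    if (is.null(detection_limit) || detection_limit <= 0) {
      stop("zero resistant titer: supply detection_limit to report a bound")
    }
    bound <- log10(titer_sensitive / detection_limit)
    return(list(log_reduction = bound, eop = detection_limit / titer_sensitive,
                censored = TRUE,
                display = sprintf("> %.1f logs", bound)))
  }
  lr <- log10(titer_sensitive / titer_resistant)
  list(log_reduction = lr, eop = titer_resistant / titer_sensitive,
       censored = FALSE, display = sprintf("%.1f logs", lr))
}
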