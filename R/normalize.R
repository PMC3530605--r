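#' MA transformation of two-channel intensities
#'
#' Computes, per probe and array, `M = log2(sample / reference)` and
#' `A = 0.5 * log2(sample * reference)`. M is always sample minus
#' reference regardless of which dye the sample carried; the dye
#' orientation lives in the design and is not folded into M (the
#' emulated design has no dye swap). Probes failing QC or with
#' non-positive intensities are skipped and counted in the `skipped`
#' attribute.
#'
#' @param probes Probe tibble (see [read_probe_table()]).
#' @param design Optional design tibble; when given, only arrays present
#'   in the design are transformed.
#' @return Tibble with columns `array_id`, `probe_id`, `cluster_id`,
#'   `is_control`, `M`, `A`, plus attribute `skipped` (number of probes
#'   dropped for QC or non-positive intensities).
#' @examples
#' p <- tibble::tibble(array_id = "a1", probe_id = "p1", cluster_id = "c1",
#'                     is_control = FALSE, sample_intensity = 200,
#'                     reference_intensity = 100, qc_ok = TRUE)
#' ma_transform(p)$M  # 1
#' @export
ma_transform <- function(probes, design = NULL) {
  if (!is.null(design)) {
    probes <- probes[probes$array_id %in% design$array_id, ]
  }
  ok <- probes$qc_ok & probes$sample_intensity > 0 &
    probes$reference_intensity > 0
  skipped <- sum(!ok)
  kept <- probes[ok, ]
  out <- tibble::tibble(
    array_id = kept$array_id,
    probe_id = kept$probe_id,
    cluster_id = kept$cluster_id,
    is_control = kept$is_control,
    M = log2(kept$sample_intensity / kept$reference_intensity),
    A = 0.5 * log2(kept$sample_intensity * kept$reference_intensity)
  )
  attr(out, "skipped") <- skipped
  out
}

#' Within-array LOWESS dye-bias correction
#'
#' Removes the intensity-dependent dye bias per array by fitting a
#' robust locally weighted regression of M on A over the non-control
#' probes and subtracting the fit: `M_corrected = M - lowess(M ~ A)`.
#' The fit is Cleveland's robust LOWESS ([stats::lowess]) over the
#' non-control probes; control/spike-in probes are corrected by the fit
#' (linear interpolation at their A) but never influence it, so they
#' remain an independent benchmark. Two numerical guards stabilize the
#' correction where data are sparse: the fit-subtract step is applied
#' `passes` times per array (later passes remove the residual structure
#' a single local pass leaves where the bias curvature is strongest),
#' and outside the central `1 - 2 * boundary_clamp` quantile range of A
#' the correction is held constant at its boundary value rather than
#' extrapolated. A values are never modified.
#'
#' @param ratios MA tibble from [ma_transform()].
#' @param span LOWESS span (fraction of probes in the local window), in
#'   (0, 1].
#' @param iterations Robustifying iterations of each fit.
#' @param passes Number of fit-subtract passes (default 3).
#' @param boundary_clamp Quantile of A (per tail, over the fit probes)
#'   beyond which the fitted correction is clamped to its boundary
#'   value.
#' @return Tibble of the same rows with `M` replaced by the corrected
#'   values.
#' @export
lowess_correct <- function(ratios, span = 0.4, iterations = 3L,
                           passes = 3L, boundary_clamp = 0.01) {
  stopifnot(span > 0, span <= 1, iterations >= 0, passes >= 1,
            boundary_clamp >= 0, boundary_clamp < 0.5)
  arrays <- split(seq_len(nrow(ratios)), ratios$array_id)
  M <- ratios$M
  A <- ratios$A
  for (idx in arrays) {
    is_fit <- !ratios$is_control[idx]
    if (sum(is_fit) < 20) {
      abort(sprintf(
        "array %s has only %d non-control probes (>= 20 required for LOWESS)",
        ratios$array_id[idx[1]], sum(is_fit)),
        class = "crmarray_normalization_error")
    }
    a_fit <- A[idx][is_fit]
    qlo <- stats::quantile(a_fit, boundary_clamp, names = FALSE)
    qhi <- stats::quantile(a_fit, 1 - boundary_clamp, names = FALSE)
    for (p in seq_len(passes)) {
      m_fit <- M[idx][is_fit]
      lw <- stats::lowess(a_fit, m_fit, f = span, iter = 0)
      resid0 <- m_fit[order(a_fit)] - lw$y
      # bisquare robustness needs a meaningful residual scale; on
      # (near-)noise-free data it would freeze genuine tail structure
      if (stats::median(abs(resid0)) >= 0.01 && iterations > 0) {
        lw <- stats::lowess(a_fit, m_fit, f = span, iter = iterations)
      }
      keep <- lw$x >= qlo & lw$x <= qhi
      fit <- stats::approx(lw$x[keep], lw$y[keep], xout = A[idx],
                           rule = 2, ties = "ordered")$y
      M[idx] <- M[idx] - fit
    }
  }
  out <- ratios
  out$M <- M
  out
}

#' Normalize all arrays
#'
#' Convenience wrapper: [ma_transform()] followed by [lowess_correct()].
#'
#' @param probes Probe tibble.
#' @param design Design tibble.
#' @param cfg A [pipeline_config()] supplying `loess_span` and
#'   `loess_iterations`.
#' @return Normalized MA tibble.
#' @export
normalize_arrays <- function(probes, design, cfg = pipeline_config()) {
  lowess_correct(ma_transform(probes, design),
                 span = cfg$loess_span,
                 iterations = cfg$loess_iterations)
}

#' Replicate M values for a treatment contrast
#'
#' With a common reference in every second channel, the
#' treatment-vs-treatment log-ratio of a probe is the difference of its
#' mean treatment-vs-reference log-ratios: `mean(M_g1) - mean(M_g2)`.
#' This returns the per-probe replicate M values of the two groups of a
#' named contrast within one stage, in wide form, ready for the ANOVA.
#'
#' @param ratios Normalized MA tibble.
#' @param design Design tibble.
#' @param stage `"diploid"` or `"haploid"`.
#' @param contrast One of [contrast_labels()].
#' @return Tibble with one row per non-control probe: `probe_id`,
#'   `cluster_id`, list-columns `m_g1` and `m_g2` of replicate M values,
#'   `log2fc = mean(m_g1) - mean(m_g2)`, and `unbalanced` flagging
#'   unequal replicate counts.
#' @export
contrast_ratios <- function(ratios, design, stage,
                            contrast = contrast_labels()) {
  contrast <- match.arg(contrast)
  spec <- .contrasts[[contrast]]
  d <- design[design$stage == stage, ]
  d$group <- .group_key(d$pco2_pa, d$light_umol)
  a1 <- d$array_id[d$group == spec$g1]
  a2 <- d$array_id[d$group == spec$g2]
  if (length(a1) == 0 || length(a2) == 0) {
    abort(sprintf("contrast %s in stage %s: a group has no replicates",
                  contrast, stage),
          class = "crmarray_contrast_error")
  }
  r <- ratios[!ratios$is_control & ratios$array_id %in% c(a1, a2), ]
  r$side <- ifelse(r$array_id %in% a1, "g1", "g2")
  wide <- dplyr::summarise(
    dplyr::group_by(r, .data$probe_id, .data$cluster_id),
    m_g1 = list(.data$M[.data$side == "g1"]),
    m_g2 = list(.data$M[.data$side == "g2"]),
    .groups = "drop"
  )
  n1 <- vapply(wide$m_g1, length, integer(1))
  n2 <- vapply(wide$m_g2, length, integer(1))
  wide$log2fc <- vapply(wide$m_g1, mean, numeric(1)) -
    vapply(wide$m_g2, mean, numeric(1))
  wide$unbalanced <- n1 != n2
  wide
}
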