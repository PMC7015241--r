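#' Relative expression by the delta-delta-Ct method
#'
#' For each test sample, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}};
#' \eqn{\Delta\Delta Ct} subtracts the mean calibrator \eqn{\Delta Ct}; the
#' fold change is \eqn{E^{-\Delta\Delta Ct}} with amplification efficiency
#' E = 2 by default (plain delta-delta-Ct, no efficiency correction).
#' When samples are replicated, `aggregate = TRUE` returns the geometric
#' mean of fold changes per sample (fold changes are ratios, so the
#' geometric mean is the natural average).
#'
#' @param ct Data frame with columns `sample`, `target_ct`, `ref_ct`,
#'   `group` (one group must equal `calibrator`).
#' @param calibrator Calibrator group label.
#' @param efficiency Amplification efficiency (default 2).
#' @param aggregate Geometric-mean fold per (sample, group).
#' @return Data frame with `sample`, `group`, `dct`, `ddct`, `fold`
#'   (per row), or aggregated `sample`, `group`, `fold`.
#' @examples
#' fx <- reference_fixtures(seed = 1)
#' ddct(fx$ddct_2p5fold$data$ct)
#' @export
ddct <- function(ct, calibrator = "calibrator", efficiency = 2,
                 aggregate = FALSE) {
  stopifnot(all(c("sample", "target_ct", "ref_ct", "group") %in% names(ct)))
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$ref_ct)) ||
      any(ct$target_ct <= 0) || any(ct$ref_ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  check_positive(efficiency = efficiency)
  cal <- ct$group == calibrator
  if (!any(cal)) stop("no calibrator rows found", call. = FALSE)
  dct <- ct$target_ct - ct$ref_ct
  ddct_val <- dct - mean(dct[cal])
  out <- data.frame(sample = ct$sample, group = ct$group, dct = dct,
                    ddct = ddct_val, fold = efficiency^(-ddct_val),
                    stringsAsFactors = FALSE)
  if (aggregate) {
    agg <- stats::aggregate(fold ~ sample + group, data = out,
                            FUN = function(x) exp(mean(log(x))))
    return(agg)
  }
  out
}

#' Dual-luciferase reporter normalization
#'
#' Firefly luciferase activity divided by Renilla luciferase activity
#' (transfection-efficiency control). With `condition` supplied, returns
#' per-condition mean ratios; with `control` also supplied, those means are
#' expressed relative to the control condition (control maps to 1).
#'
#' @param firefly,renilla Luminescence readings; `renilla` must be > 0.
#' @param condition Optional condition labels (one per reading).
#' @param control Optional control condition label for relative reporting.
#' @return Ratios per reading, or a data frame of per-condition means.
#' @examples
#' luciferase_ratio(1000, 500)
#' @export
luciferase_ratio <- function(firefly, renilla, condition = NULL,
                             control = NULL) {
  check_nonneg(firefly, "firefly")
  check_positive(renilla = renilla)
  ratio <- firefly / renilla
  if (is.null(condition)) return(ratio)
  means <- stats::aggregate(ratio ~ condition,
                            data = data.frame(ratio = ratio,
                                              condition = condition),
                            FUN = mean)
  names(means)[2] <- "mean_ratio"
  if (!is.null(control)) {
    if (!control %in% means$condition) {
      stop("control condition not found", call. = FALSE)
    }
    means$relative <- means$mean_ratio /
      means$mean_ratio[means$condition == control]
  }
  means
}

#' Densitometry normalization and group folds
#'
#' Band densities are divided lane-wise by the loading-control density.
#' With group labels, per-group means are reported and, given a control
#' group, folds relative to it.
#'
#' @param band Band densities (>= 0).
#' @param loading_control Loading-control densities (> 0).
#' @param group Optional group labels.
#' @param control_group Optional control group label.
#' @return Normalized values, or a list with `normalized` and `groups`
#'   (per-group means and folds).
#' @examples
#' densitometry_ratio(c(10, 20), c(5, 5))
#' @export
densitometry_ratio <- function(band, loading_control, group = NULL,
                               control_group = NULL) {
  check_nonneg(band, "band")
  check_positive(loading_control = loading_control)
  normalized <- band / loading_control
  if (is.null(group)) return(normalized)
  means <- stats::aggregate(normalized ~ group,
                            data = data.frame(normalized = normalized,
                                              group = group),
                            FUN = mean)
  names(means)[2] <- "mean_normalized"
  if (!is.null(control_group)) {
    if (!control_group %in% means$group) {
      stop("control group not found", call. = FALSE)
    }
    means$fold <- means$mean_normalized /
      means$mean_normalized[means$group == control_group]
  }
  list(normalized = normalized, groups = means)
}

#' Myosin heavy chain isoform distribution
#'
#' Converts MHC gel band densities to a percent distribution across
#' isoforms (sums to 100 by construction).
#'
#' @param band_densities Named or unnamed band densities (>= 0, not all 0).
#' @return Percentages in the same order/names as the input.
#' @examples
#' mhc_distribution(c(`2B` = 30, `2X` = 50, `2A` = 20))
#' @export
mhc_distribution <- function(band_densities) {
  check_nonneg(band_densities, "band_densities")
  if (sum(band_densities) == 0) stop("all band densities zero", call. = FALSE)
  100 * band_densities / sum(band_densities)
}
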