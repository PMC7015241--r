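#' Z-line width at the base of an averaged density profile
#'
#' Operationalizes "width at the base" of the averaged electron-micrograph
#' density peak: the background is the median intensity of the outer 20% of
#' positions (the Z-line sits centred in the boxed region), the base is the
#' contiguous region around the peak where intensity exceeds
#' `background + threshold_frac * (peak - background)`, and the width is the
#' extent of that region with the two edge crossings located by linear
#' interpolation between samples (sub-sample precision on resolved edges).
#'
#' @param profile Data frame with columns `position_nm`, `intensity`, or a
#'   numeric position vector.
#' @param intensity Intensities when `profile` is a position vector.
#' @param threshold_frac Fraction of the background-subtracted peak height
#'   defining the base (default 0.05).
#' @return Object of class `zline_width`: `width_nm`, `background`, `peak`,
#'   `threshold`, `edges` (nm).
#' @examples
#' pr <- gen_zline_profile(width_nm = 60, seed = 1)
#' zline_width(pr)$width_nm
#' @export
zline_width <- function(profile, intensity = NULL, threshold_frac = 0.05) {
  if (is.data.frame(profile)) {
    intensity <- profile$intensity
    pos <- profile$position_nm
  } else {
    pos <- profile
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  n <- length(pos)
  k <- max(1L, floor(0.1 * n))
  outer_idx <- c(seq_len(k), seq(n - k + 1, n))
  background <- stats::median(intensity[outer_idx])
  peak <- max(intensity)
  if (peak <= background) {
    stop("no peak rises above the background estimate", call. = FALSE)
  }
  thr <- background + threshold_frac * (peak - background)
  above <- intensity > thr
  ipk <- which.max(intensity)
  if (!above[ipk]) stop("no region exceeds the threshold", call. = FALSE)
  il <- ipk
  while (il > 1 && above[il - 1]) il <- il - 1
  ir <- ipk
  while (ir < n && above[ir + 1]) ir <- ir + 1
  cross <- function(i0, i1) {
    # linear interpolation of the threshold crossing between samples
    if (intensity[i1] == intensity[i0]) return(pos[i0])
    pos[i0] + (thr - intensity[i0]) / (intensity[i1] - intensity[i0]) *
      (pos[i1] - pos[i0])
  }
  left <- if (il > 1) cross(il, il - 1) else pos[1]
  right <- if (ir < n) cross(ir, ir + 1) else pos[n]
  out <- list(width_nm = right - left, background = background, peak = peak,
              threshold = thr, threshold_frac = threshold_frac,
              edges = c(left, right))
  class(out) <- "zline_width"
  out
}

#' @export
print.zline_width <- function(x, ...) {
  cat(sprintf("Z-line width at base: %.4g nm (threshold %.0f%% above background %.3g)\n",
              x$width_nm, 100 * x$threshold_frac, x$background))
  invisible(x)
}

#' Width summary over several Z-line profiles
#'
#' Either measures each profile and averages the widths (`"per_profile"`) or
#' averages the aligned profiles first and measures once (`"pooled"`); both
#' conventions appear in practice for ">100 Z-lines per muscle" style
#' reporting.
#'
#' @param profiles List of profile data frames on a common position grid.
#' @param mode `"per_profile"` or `"pooled"`.
#' @inheritParams zline_width
#' @return Mean width (nm) with per-profile widths as attribute `"widths"`
#'   for the per-profile mode.
#' @export
zline_width_summary <- function(profiles, mode = c("per_profile", "pooled"),
                                threshold_frac = 0.05) {
  mode <- match.arg(mode)
  if (mode == "per_profile") {
    w <- vapply(profiles, function(p) {
      zline_width(p, threshold_frac = threshold_frac)$width_nm
    }, numeric(1))
    out <- mean(w)
    attr(out, "widths") <- w
    out
  } else {
    pos <- profiles[[1]]$position_nm
    mean_int <- rowMeans(vapply(profiles, function(p) p$intensity,
                                numeric(length(pos))))
    zline_width(data.frame(position_nm = pos, intensity = mean_int),
                threshold_frac = threshold_frac)$width_nm
  }
}

#' Summarize a fibre population by type and genotype
#'
#' Per (muscle, fibre type, genotype) cell: fibre counts and mean CSA; plus
#' a genotype comparison against a reference genotype giving the percent
#' change of mean CSA and of fibre number. Empty cells are flagged with NA
#' rather than dropped. Reductions read naturally as
#' `100 * (1 - test/ref)`; the signed change `100 * (test/ref - 1)` is also
#' reported.
#'
#' @param pop Data frame with columns `csa_um2`, `fibre_type`, `muscle`,
#'   `genotype`.
#' @param reference Reference genotype label (default `"WT"`).
#' @return Object of class `fibre_summary`: `by_cell` data frame,
#'   `comparison` data frame (when two genotypes are present), `n_total`.
#' @export
summarize_fibres <- function(pop, reference = "WT") {
  stopifnot(all(c("csa_um2", "fibre_type", "muscle", "genotype") %in%
                  names(pop)))
  check_positive(csa_um2 = pop$csa_um2)
  by_cell <- stats::aggregate(csa_um2 ~ muscle + fibre_type + genotype,
                              data = pop,
                              FUN = function(x) c(n = length(x),
                                                  mean = mean(x)))
  by_cell <- data.frame(by_cell[, 1:3],
                        n = as.integer(by_cell$csa_um2[, "n"]),
                        mean_csa_um2 = by_cell$csa_um2[, "mean"])
  genos <- unique(pop$genotype)
  comparison <- NULL
  if (length(genos) == 2 && reference %in% genos) {
    test <- setdiff(genos, reference)
    cells <- unique(by_cell[, c("muscle", "fibre_type")])
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- by_cell$muscle == cells$muscle[i] &
        by_cell$fibre_type == cells$fibre_type[i]
      ref_row <- by_cell[sel & by_cell$genotype == reference, ]
      test_row <- by_cell[sel & by_cell$genotype == test, ]
      ref_mean <- if (nrow(ref_row)) ref_row$mean_csa_um2 else NA_real_
      test_mean <- if (nrow(test_row)) test_row$mean_csa_um2 else NA_real_
      if (is.na(ref_mean) || is.na(test_mean)) {
        warning(sprintf("empty cell for muscle %s type %s in one genotype",
                        cells$muscle[i], cells$fibre_type[i]))
      }
      data.frame(muscle = cells$muscle[i], fibre_type = cells$fibre_type[i],
                 mean_ref = ref_mean, mean_test = test_mean,
                 n_ref = if (nrow(ref_row)) ref_row$n else 0L,
                 n_test = if (nrow(test_row)) test_row$n else 0L,
                 pct_change = 100 * (test_mean / ref_mean - 1),
                 pct_reduction = 100 * (1 - test_mean / ref_mean))
    })
    comparison <- do.call(rbind, rows)
    # overall (type-pooled) comparison per muscle
    overall <- lapply(unique(pop$muscle), function(m) {
      ref_csa <- pop$csa_um2[pop$muscle == m & pop$genotype == reference]
      test_csa <- pop$csa_um2[pop$muscle == m & pop$genotype == test]
      data.frame(muscle = m, fibre_type = "all",
                 mean_ref = mean(ref_csa), mean_test = mean(test_csa),
                 n_ref = length(ref_csa), n_test = length(test_csa),
                 pct_change = 100 * (mean(test_csa) / mean(ref_csa) - 1),
                 pct_reduction = 100 * (1 - mean(test_csa) / mean(ref_csa)))
    })
    comparison <- rbind(comparison, do.call(rbind, overall))
  }
  out <- list(by_cell = by_cell, comparison = comparison,
              n_total = nrow(pop), reference = reference)
  class(out) <- "fibre_summary"
  out
}

#' @export
print.fibre_summary <- function(x, ...) {
  cat(sprintf("Fibre population summary: %d fibres\n", x$n_total))
  print(x$by_cell, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat(sprintf("Genotype comparison (vs %s):\n", x$reference))
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}

#' Myotube fusion index
#'
#' Percentage of all nuclei residing within myotubes containing at least
#' `min_nuclei` nuclei.
#'
#' @param nuclei_in_myotubes Count of nuclei inside qualifying myotubes, or
#'   (with `per_myotube = TRUE`) a vector of per-myotube nucleus counts from
#'   which qualifying nuclei are summed with the `min_nuclei` threshold.
#' @param nuclei_total Total nuclei counted (> 0).
#' @param per_myotube Interpret `nuclei_in_myotubes` as per-myotube counts.
#' @param min_nuclei Minimum nuclei for a myotube to qualify (default 3).
#' @return Fusion index, percent.
#' @examples
#' fusion_index(30, 100)
#' fusion_index(c(5, 2, 8, 1), 40, per_myotube = TRUE)
#' @export
fusion_index <- function(nuclei_in_myotubes, nuclei_total,
                         per_myotube = FALSE, min_nuclei = 3) {
  check_positive(nuclei_total = nuclei_total)
  fused <- if (per_myotube) {
    sum(nuclei_in_myotubes[nuclei_in_myotubes >= min_nuclei])
  } else {
    nuclei_in_myotubes
  }
  check_nonneg(fused, "nuclei_in_myotubes")
  if (fused > nuclei_total) {
    stop("fused nuclei exceed total nuclei", call. = FALSE)
  }
  100 * fused / nuclei_total
}

#' EdU proliferation fraction
#'
#' EdU-positive nuclei as a percentage of total (Hoechst-stained) nuclei.
#' Vectors are pooled across fields (equivalent to weighting per-field
#' fractions by field totals).
#'
#' @param edu_positive EdU-positive counts, one per field.
#' @param hoechst_total Total nuclei per field (sum > 0).
#' @return Pooled EdU fraction, percent.
#' @export
edu_fraction <- function(edu_positive, hoechst_total) {
  check_nonneg(edu_positive, "edu_positive")
  check_nonneg(hoechst_total, "hoechst_total")
  if (sum(hoechst_total) == 0) stop("zero total nuclei", call. = FALSE)
  if (sum(edu_positive) > sum(hoechst_total)) {
    stop("positive nuclei exceed total nuclei", call. = FALSE)
  }
  100 * sum(edu_positive) / sum(hoechst_total)
}

#' Myotube width comparison
#'
#' Means and SDs of two width samples plus the percent reduction of the test
#' sample relative to the reference: `100 * (1 - mean(test)/mean(ref))`.
#'
#' @param widths_ref Reference (e.g. WT) widths, um; non-empty, positive.
#' @param widths_test Test (e.g. knockout) widths, um.
#' @return List: `mean_ref`, `mean_test`, `sd_ref`, `sd_test`,
#'   `pct_reduction`.
#' @export
myotube_width_summary <- function(widths_ref, widths_test) {
  if (length(widths_ref) == 0 || length(widths_test) == 0) {
    stop("width samples must be non-empty", call. = FALSE)
  }
  check_positive(widths_ref = widths_ref, widths_test = widths_test)
  list(mean_ref = mean(widths_ref), mean_test = mean(widths_test),
       sd_ref = stats::sd(widths_ref), sd_test = stats::sd(widths_test),
       pct_reduction = 100 * (1 - mean(widths_test) / mean(widths_ref)))
}
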