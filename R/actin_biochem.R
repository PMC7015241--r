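#' Fit a single-site actin binding isotherm
#'
#' Least-squares fit of the one-site saturation model
#' \eqn{f([A]) = [A] / ([A] + K_d)} to co-sedimentation data (fraction of
#' ligand pelleting with F-actin vs actin concentration). Ligand depletion is
#' ignored by default (free actin is taken equal to total actin, appropriate
#' when the ligand is not in large excess of Kd); a depletion-corrected
#' quadratic model is available via `depletion = TRUE`, which solves the
#' equilibrium for the complex concentration given the fixed ligand
#' concentration.
#'
#' If the measured fractions never rise appreciably above zero the protein is
#' reported as non-binding (`kd = NA`, `no_binding = TRUE`) rather than
#' producing an unstable fit.
#'
#' @param actin_um Actin concentrations, uM, or a data frame with columns
#'   `actin_um` and `bound_frac`.
#' @param bound_frac Bound ligand fractions in \[0, 1\].
#' @param ligand_um Ligand concentration (uM); used only when
#'   `depletion = TRUE`.
#' @param depletion Use the depletion-corrected quadratic binding model.
#' @return An object of class `kd_fit` with elements `kd`, `kd_se`, `rss`,
#'   `fitted`, `residuals`, `no_binding`, `model`.
#' @examples
#' iso <- gen_binding_isotherm(kd = 7.6, seed = 1)
#' fit <- fit_binding_isotherm(iso)
#' coef(fit)
#' @export
fit_binding_isotherm <- function(actin_um, bound_frac = NULL, ligand_um = 10,
                                 depletion = FALSE) {
  if (is.data.frame(actin_um)) {
    bound_frac <- actin_um$bound_frac
    actin_um <- actin_um$actin_um
  }
  check_nonneg(actin_um, "actin_um")
  if (length(actin_um) < 4) {
    stop("need at least 4 concentrations", call. = FALSE)
  }
  pos <- actin_um[actin_um > 0]
  if (max(pos) / min(pos) < 5) {
    stop("concentrations must span at least a 5-fold range", call. = FALSE)
  }
  if (any(bound_frac < -0.2) || any(bound_frac > 1.2)) {
    stop("`bound_frac` values far outside [0, 1]", call. = FALSE)
  }
  if (max(bound_frac) < 0.05) {
    out <- list(kd = NA_real_, kd_se = NA_real_, rss = NA_real_,
                fitted = rep(0, length(actin_um)),
                residuals = bound_frac,
                actin_um = actin_um, bound_frac = bound_frac,
                no_binding = TRUE, model = "none")
    class(out) <- c("kd_fit", "fibr_fit")
    return(out)
  }
  # start: concentration where the data cross half-saturation
  i <- which.min(abs(bound_frac - 0.5))
  kd0 <- max(actin_um[i], min(pos))
  dat <- data.frame(a = actin_um, f = bound_frac)
  if (depletion) {
    form <- f ~ ((a + ligand_um + kd) -
                   sqrt((a + ligand_um + kd)^2 - 4 * a * ligand_um)) /
      (2 * ligand_um)
    model <- "quadratic (ligand depletion)"
  } else {
    form <- f ~ a / (a + kd)
    model <- "one-site saturation"
  }
  fit <- minpack.lm::nlsLM(form, data = dat, start = list(kd = kd0),
                           lower = 1e-6,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  sm <- summary(fit)
  out <- list(kd = unname(coef(fit)["kd"]),
              kd_se = unname(sm$coefficients["kd", "Std. Error"]),
              rss = sum(residuals(fit)^2),
              fitted = fitted(fit),
              residuals = as.numeric(residuals(fit)),
              actin_um = actin_um, bound_frac = bound_frac,
              ligand_um = ligand_um,
              no_binding = FALSE, model = model)
  class(out) <- c("kd_fit", "fibr_fit")
  out
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  a <- if (is.null(newdata)) object$actin_um else {
    if (is.data.frame(newdata)) newdata$actin_um else newdata
  }
  if (isTRUE(object$no_binding)) return(rep(0, length(a)))
  a / (a + object$kd)
}

#' @export
residuals.kd_fit <- function(object, ...) object$residuals

#' @export
print.kd_fit <- function(x, ...) {
  cat("Single-site binding isotherm fit\n")
  if (isTRUE(x$no_binding)) {
    cat("  no measurable binding (fractions ~ 0); Kd not determined\n")
  } else {
    cat(sprintf("  Kd = %.3g uM (SE %.2g), model: %s\n",
                x$kd, x$kd_se, x$model))
    cat(sprintf("  RSS = %.3g over %d concentrations\n",
                x$rss, length(x$actin_um)))
  }
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  plot(x$actin_um, x$bound_frac, xlab = "[actin] (uM)",
       ylab = "bound fraction", ylim = c(0, 1), pch = 19, ...)
  if (!isTRUE(x$no_binding)) {
    a <- seq(0, max(x$actin_um), length.out = 200)
    lines(a, predict(x, a))
    abline(v = x$kd, lty = 3)
  }
  invisible(x)
}

#' Partition actin between bundled, filamentous and soluble pools
#'
#' Differential-sedimentation bookkeeping: a low-speed spin pellets bundled
#' (crosslinked) F-actin, a subsequent high-speed spin pellets the remaining
#' filaments, and the final supernatant holds unpolymerized actin. Band
#' densities are converted to fractions of the total.
#'
#' @param low_pellet,high_pellet,supernatant Band densities (>= 0, not all 0).
#' @return List with `fractions` (named: bundled, filamentous, soluble) and
#'   the input densities.
#' @export
partition_bundling <- function(low_pellet, high_pellet, supernatant) {
  check_nonneg(c(low_pellet, high_pellet, supernatant), "densities")
  total <- low_pellet + high_pellet + supernatant
  if (total == 0) stop("all densities are zero", call. = FALSE)
  fr <- c(bundled = low_pellet, filamentous = high_pellet,
          soluble = supernatant) / total
  list(fractions = fr,
       densities = c(low_pellet = low_pellet, high_pellet = high_pellet,
                     supernatant = supernatant))
}

#' Normalize a polymerization trace
#'
#' Subtracts the baseline fluorescence and divides by the plateau amplitude:
#' baseline is the mean of the first `k` points, plateau the mean of the last
#' `k`. The trace must have reached steady state (flat tail); a drifting tail
#' triggers a warning since the plateau estimate is then biased.
#'
#' @param trace Data frame with columns `time_s`, `rfu` (or `f_norm` for an
#'   already-normalized trace, which passes through idempotently).
#' @param k Number of points averaged at each end.
#' @return Data frame with columns `time_s`, `f_norm` and attribute
#'   `normalized = "polymerization"`.
#' @export
normalize_polymerization <- function(trace, k = 5) {
  sig <- if ("f_norm" %in% names(trace)) trace$f_norm else trace$rfu
  n <- length(sig)
  if (n < 2 * k) stop("trace too short for end-point averaging", call. = FALSE)
  baseline <- mean(sig[seq_len(k)])
  plateau <- mean(sig[seq(n - k + 1, n)])
  if (plateau <= baseline) {
    stop("plateau does not exceed baseline; trace not normalizable",
         call. = FALSE)
  }
  tail_idx <- seq(max(1, floor(0.9 * n)), n)
  tail_slope <- ols_line(trace$time_s[tail_idx], sig[tail_idx])["slope"]
  rel_drift <- abs(tail_slope) * diff(range(trace$time_s)) /
    (plateau - baseline)
  if (rel_drift > 0.05) {
    warning("terminal 10% of trace still drifting; plateau estimate may be biased")
  }
  out <- data.frame(time_s = trace$time_s,
                    f_norm = (sig - baseline) / (plateau - baseline))
  attr(out, "normalized") <- "polymerization"
  out
}

#' Extract the polymerization rate from a normalized trace
#'
#' The overall polymerization rate is the slope of the linear region of the
#' normalized curve, operationalized as the maximum slope over sliding
#' windows restricted to the 10--60% normalized band (the region free of
#' both the lag phase and plateau saturation), converted from normalized
#' units/s to nM actin/s via the polymerizable actin pool
#' (total actin minus the critical concentration):
#' `rate_nM_s = slope * (total_actin_um - c_crit_um) * 1000`.
#'
#' @param trace_norm Normalized trace from [normalize_polymerization()].
#' @param total_actin_um Total actin, uM.
#' @param c_crit_um Critical concentration, uM (barbed-end textbook value
#'   0.1 uM by default; the polymerized mass at plateau is
#'   `total - c_crit`).
#' @param window_frac Sliding-window width as a fraction of the trace length.
#' @param band Normalized-fluorescence band defining the linear region.
#' @return List of class `rate_result`: `rate_nm_per_s`, `slope_per_s`,
#'   `window` (t_start, t_end).
#' @export
polymerization_rate <- function(trace_norm, total_actin_um, c_crit_um = 0.1,
                                window_frac = 0.1, band = c(0.1, 0.6)) {
  if (!identical(attr(trace_norm, "normalized"), "polymerization")) {
    stop("trace must first be normalized with normalize_polymerization()",
         call. = FALSE)
  }
  check_positive(total_actin_um = total_actin_um)
  f <- trace_norm$f_norm
  t <- trace_norm$time_s
  n <- length(f)
  w <- max(3L, round(window_frac * n))
  in_band <- f >= band[1] & f <= band[2]
  best <- -Inf
  best_win <- c(NA_real_, NA_real_)
  for (i in seq_len(n - w + 1)) {
    idx <- i:(i + w - 1)
    if (!all(in_band[idx])) next
    sl <- unname(ols_line(t[idx], f[idx])["slope"])
    if (sl > best) {
      best <- sl
      best_win <- c(t[i], t[i + w - 1])
    }
  }
  if (!is.finite(best)) {
    stop("no sliding window lies within the linear band; trace too coarse or saturated",
         call. = FALSE)
  }
  out <- list(rate_nm_per_s = unname(best * (total_actin_um - c_crit_um) * 1000),
              slope_per_s = unname(best),
              window = best_win,
              total_actin_um = total_actin_um, c_crit_um = c_crit_um)
  class(out) <- "rate_result"
  out
}

#' Normalize a depolymerization trace
#'
#' Applies the disassembly-assay convention: the final time-point intensity
#' of the Latrunculin-A-treated F-actin-alone run is mapped to 0 and the
#' maximum fluorescence of the data set to 1.
#'
#' @param trace Data frame with columns `time_s`, `rfu`.
#' @param lata_final Final fluorescence of the protein-free (F-actin +
#'   Latrunculin A) trace, defining the fully-disassembled level.
#' @return Data frame with columns `time_s`, `f_norm` and attribute
#'   `normalized = "depolymerization"`.
#' @export
normalize_depolymerization <- function(trace, lata_final) {
  mx <- max(trace$rfu)
  if (mx <= lata_final) {
    stop("trace maximum does not exceed `lata_final`; degenerate range",
         call. = FALSE)
  }
  out <- data.frame(time_s = trace$time_s,
                    f_norm = (trace$rfu - lata_final) / (mx - lata_final))
  attr(out, "normalized") <- "depolymerization"
  out
}

#' Quantify the depolymerization-rate decrease conferred by a ligand
#'
#' Initial disassembly rates are estimated on each normalized trace by an
#' ordinary linear fit over the first `window_s` seconds (default 60 s);
#' the protection is reported as
#' `percent_decrease = 100 * (1 - rate_plus / rate_free)`. An alternative
#' `method = "exponential"` fits a single-exponential decay to each full
#' trace and compares rate constants instead.
#'
#' @param protein_free,protein_plus Normalized traces
#'   (see [normalize_depolymerization()]).
#' @param window_s Initial-rate window, s.
#' @param method `"initial_slope"` (default) or `"exponential"`.
#' @return List of class `rate_result`: `rate_free`, `rate_plus` (1/s,
#'   positive = disassembly), `percent_decrease`, `window`, `method`.
#' @export
depolymerization_decrease <- function(protein_free, protein_plus,
                                      window_s = 60,
                                      method = c("initial_slope",
                                                 "exponential")) {
  method <- match.arg(method)
  for (tr in list(protein_free, protein_plus)) {
    if (!identical(attr(tr, "normalized"), "depolymerization")) {
      stop("traces must first be normalized with normalize_depolymerization()",
           call. = FALSE)
    }
  }
  rate_of <- function(tr) {
    if (method == "initial_slope") {
      idx <- tr$time_s <= min(tr$time_s) + window_s
      if (sum(idx) < 3) stop("initial window holds fewer than 3 points",
                             call. = FALSE)
      -ols_line(tr$time_s[idx], tr$f_norm[idx])["slope"]
    } else {
      dat <- data.frame(t = tr$time_s - min(tr$time_s), f = tr$f_norm)
      k0 <- -ols_line(dat$t[dat$f > 0.2], log(pmax(dat$f[dat$f > 0.2], 1e-12)))["slope"]
      fit <- minpack.lm::nlsLM(f ~ exp(-k * t), data = dat,
                               start = list(k = max(k0, 1e-6)), lower = 0)
      unname(coef(fit)["k"])
    }
  }
  rate_free <- unname(rate_of(protein_free))
  rate_plus <- unname(rate_of(protein_plus))
  if (rate_free <= 0) {
    stop("protein-free trace shows no net disassembly (non-positive rate)",
         call. = FALSE)
  }
  out <- list(rate_free = rate_free, rate_plus = rate_plus,
              percent_decrease = 100 * (1 - rate_plus / rate_free),
              window = c(0, window_s), method = method)
  class(out) <- "rate_result"
  out
}

#' @export
print.rate_result <- function(x, ...) {
  cat("Kinetic rate result\n")
  if (!is.null(x$rate_nm_per_s)) {
    cat(sprintf("  polymerization rate: %.4g nM/s (slope %.4g /s, window %g-%g s)\n",
                x$rate_nm_per_s, x$slope_per_s, x$window[1], x$window[2]))
  }
  if (!is.null(x$percent_decrease)) {
    cat(sprintf("  disassembly rates: free %.4g, plus %.4g (%s)\n",
                x$rate_free, x$rate_plus, x$method))
    cat(sprintf("  rate decrease: %.1f%%\n", x$percent_decrease))
  }
  invisible(x)
}
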