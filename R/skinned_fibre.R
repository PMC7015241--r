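#' Elliptical fibre cross-sectional area
#'
#' Single skinned fibres are modelled as elliptical in cross section:
#' \eqn{CSA = (\pi/4) d h} from the measured width and height.
#'
#' @param d Fibre width, um (> 0). Vectorized.
#' @param h Fibre height, um (> 0).
#' @return CSA in um^2.
#' @examples
#' elliptical_csa(d = 60, h = 40)
#' @export
elliptical_csa <- function(d, h) {
  check_positive(d = d, h = h)
  pi / 4 * d * h
}

#' Fit the T1 (end-of-step force vs step size) relation
#'
#' Length steps of a few nm per half-sarcomere are imposed on an
#' isometrically contracting fibre; the force attained at the end of each
#' step (T1), plotted against step size, is fitted by an ordinary
#' least-squares line. The slope is the half-sarcomere stiffness and the
#' absolute abscissa intercept is the half-sarcomere strain
#' \eqn{Y_0 = |{-intercept/slope}|}. A zero slope (all forces equal) yields
#' a flagged degenerate result instead of an error so batch processing can
#' continue.
#'
#' @param step_nm Step sizes, nm per half-sarcomere; must include negative
#'   and positive steps. Or a data frame with columns `step_nm_hs`,
#'   `t1_rel`.
#' @param t1_force End-of-step forces (relative to isometric).
#' @return Object of class `t1_fit`: `slope` (stiffness), `intercept`, `y0`
#'   (nm per half-sarcomere), `r_squared`, `degenerate`.
#' @examples
#' fit_t1(step_nm = c(-3, -1.5, 0, 1.5, 3),
#'        t1_force = 1 + 0.25 * c(-3, -1.5, 0, 1.5, 3))
#' @export
fit_t1 <- function(step_nm, t1_force = NULL) {
  if (is.data.frame(step_nm)) {
    t1_force <- step_nm$t1_rel
    step_nm <- step_nm$step_nm_hs
  }
  if (length(step_nm) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(step_nm) == 0) {
    stop("zero variance in step sizes", call. = FALSE)
  }
  if (min(step_nm) >= 0 || max(step_nm) <= 0) {
    warning("steps do not span negative and positive values; extrapolated Y0")
  }
  fit <- stats::lm(t1_force ~ step_nm)
  cf <- coef(fit)
  slope <- unname(cf[2])
  intercept <- unname(cf[1])
  degenerate <- isTRUE(all.equal(slope, 0)) || abs(slope) < 1e-12
  y0 <- if (degenerate) NA_real_ else abs(-intercept / slope)
  tss <- sum((t1_force - mean(t1_force))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(residuals(fit)^2) / tss
  out <- list(slope = slope, intercept = intercept, y0 = y0,
              r_squared = r2,
              lm = fit, step_nm = step_nm, t1_force = t1_force,
              degenerate = degenerate)
  class(out) <- c("t1_fit", "fibr_fit")
  out
}

#' @export
coef.t1_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, y0 = object$y0)
}

#' @export
print.t1_fit <- function(x, ...) {
  cat("T1 relation (end-of-step force vs step size)\n")
  if (x$degenerate) {
    cat("  DEGENERATE: zero slope; Y0 undefined\n")
  } else {
    cat(sprintf("  stiffness (slope) = %.4g /nm, Y0 = %.4g nm per hs (R^2 = %.4f)\n",
                x$slope, x$y0, x$r_squared))
  }
  invisible(x)
}

#' Regress half-sarcomere strain on isometric force
#'
#' Across calcium levels, the half-sarcomere strain Y0 is regressed linearly
#' on the isometric force T0; the slope Cf reflects half-sarcomere
#' compliance and the ordinate intercept s0 the force-independent strain
#' contribution.
#'
#' @param t0 Isometric forces at each pCa, or a data frame with columns
#'   `t0`, `y0`.
#' @param y0 Half-sarcomere strains, nm per half-sarcomere.
#' @return Object of class `strain_force_fit`: `cf` (slope), `s0`
#'   (intercept), `r_squared` and the underlying `lm`.
#' @export
regress_strain_force <- function(t0, y0 = NULL) {
  if (is.data.frame(t0)) {
    y0 <- t0$y0
    t0 <- t0$t0
  }
  if (length(t0) < 3) stop("need at least 3 (T0, Y0) pairs", call. = FALSE)
  fit <- stats::lm(y0 ~ t0)
  cf <- coef(fit)
  tss <- sum((y0 - mean(y0))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(residuals(fit)^2) / tss
  out <- list(cf = unname(cf[2]), s0 = unname(cf[1]),
              r_squared = r2, lm = fit,
              t0 = t0, y0 = y0)
  class(out) <- c("strain_force_fit", "fibr_fit")
  out
}

#' @export
coef.strain_force_fit <- function(object, ...) {
  c(cf = object$cf, s0 = object$s0)
}

#' @export
print.strain_force_fit <- function(x, ...) {
  cat(sprintf("Y0-T0 regression: Cf (slope) = %.4g, s0 (intercept) = %.4g (R^2 = %.4f)\n",
              x$cf, x$s0, x$r_squared))
  invisible(x)
}

#' Fit the force--pCa relation (Hill sigmoid)
#'
#' Isometric force at each calcium level, normalized to the force at
#' saturating calcium, is fitted with the sigmoid Hill equation
#' \deqn{T_{rel} = 1 / (1 + 10^{n_H (pCa - pK)})}
#' yielding the Hill coefficient nH (cooperativity of calcium activation)
#' and pK, the pCa of half-maximal force (calcium sensitivity). The base-10
#' form matches pCa = -log10\[Ca2+\]. By construction the fitted curve
#' passes through 0.5 at pCa = pK.
#'
#' @param pca pCa values, or a data frame with columns `pca`, `t_rel`.
#' @param t_rel Relative tensions in \[0, 1\].
#' @return Object of class `pca_fit`: coefficients `nh`, `pk`, plus `rss`,
#'   `fitted`, `residuals`, `vcov`, `converged`.
#' @examples
#' d <- gen_force_pca(nh = 2.5, pk = 5.9, seed = 1)
#' coef(fit_force_pca(d))
#' @export
fit_force_pca <- function(pca, t_rel = NULL) {
  if (is.data.frame(pca)) {
    t_rel <- pca$t_rel
    pca <- pca$pca
  }
  if (length(pca) < 4) stop("need at least 4 points", call. = FALSE)
  if (all(t_rel < 0.02) || all(t_rel > 0.98)) {
    stop("all tensions at one saturation level; nH and pK unidentifiable",
         call. = FALSE)
  }
  pk0 <- pca[which.min(abs(t_rel - 0.5))]
  starts <- list(list(nh = 2, pk = pk0))
  for (i in 1:10) {
    starts[[i + 1]] <- with_seed(i, list(nh = exp(rnorm(1, log(2), 0.5)),
                                         pk = pk0 + rnorm(1, sd = 0.3)))
  }
  dat <- data.frame(pca = pca, t_rel = t_rel)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(t_rel ~ 1 / (1 + 10^(nh * (pca - pk))), data = dat,
                        start = st, lower = c(1e-6, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- list(coefficients = c(nh = NA_real_, pk = NA_real_),
                rss = NA_real_, data = dat,
                fitted = rep(NA_real_, nrow(dat)),
                residuals = rep(NA_real_, nrow(dat)),
                vcov = NULL, converged = FALSE)
    class(out) <- c("pca_fit", "fibr_fit")
    return(out)
  }
  cf <- coef(fit)
  out <- list(coefficients = c(nh = unname(cf["nh"]), pk = unname(cf["pk"])),
              rss = sum(residuals(fit)^2), data = dat,
              fitted = fitted(fit),
              residuals = as.numeric(residuals(fit)),
              vcov = tryCatch(vcov(fit), error = function(e) NULL),
              converged = TRUE)
  class(out) <- c("pca_fit", "fibr_fit")
  out
}

#' @export
coef.pca_fit <- function(object, ...) object$coefficients

#' @export
predict.pca_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$pca else {
    if (is.data.frame(newdata)) newdata$pca else newdata
  }
  cf <- object$coefficients
  1 / (1 + 10^(cf["nh"] * (p - cf["pk"])))
}

#' @export
residuals.pca_fit <- function(object, ...) object$residuals

#' @export
print.pca_fit <- function(x, ...) {
  cat("Force-pCa Hill sigmoid fit\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE after seeded restarts\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  nH = %.4g, pK = %.4g; RSS = %.3g over %d points\n",
              cf["nh"], cf["pk"], x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.pca_fit <- function(object, ...) {
  print(object)
  if (object$converged && !is.null(object$vcov)) {
    se <- sqrt(diag(object$vcov))
    cat(sprintf("  SE: nH %.3g, pK %.3g\n", se[1], se[2]))
  }
  invisible(object)
}

#' @export
plot.pca_fit <- function(x, ...) {
  plot(x$data$pca, x$data$t_rel, xlim = rev(range(x$data$pca)),
       xlab = "pCa", ylab = "relative tension", pch = 19, ...)
  if (x$converged) {
    p <- seq(min(x$data$pca), max(x$data$pca), length.out = 200)
    lines(p, predict(x, p))
    abline(v = x$coefficients["pk"], h = 0.5, lty = 3)
  }
  invisible(x)
}

#' Passive Young's modulus at sarcomere length 3.0 um
#'
#' A low-order polynomial (default cubic) is fitted to the passive
#' stress--sarcomere-length curve recorded during incremental stretch, and
#' the Young's modulus is the tangent of that smooth curve evaluated at a
#' sarcomere length of 3.0 um. Only the local tangent is needed, so a
#' polynomial suffices over mechanistic (exponential) forms. The tangent is
#' reported both per um of sarcomere length and per unit sarcomere strain,
#' using strain = (sl - sl_slack)/sl_slack (the slack-referenced convention;
#' the slack length must be supplied because conventions differ).
#'
#' @param sl_um Sarcomere lengths, um, or a data frame with columns `sl_um`,
#'   `stress_kn_m2`.
#' @param stress_kn_m2 Passive stresses, kN/m^2.
#' @param sl_eval Evaluation point, um (default 3.0); must lie within the
#'   data range.
#' @param sl_slack Slack sarcomere length defining strain, um.
#' @param degree Polynomial degree (default 3).
#' @return Object of class `passive_fit`: `e_per_um` (kN/m^2 per um),
#'   `e_per_strain` (kN/m^2 per unit strain), `sl_eval`, `sl_slack`,
#'   `failure_sl` (last recorded sl), `lm`.
#' @export
passive_young_modulus <- function(sl_um, stress_kn_m2 = NULL, sl_eval = 3.0,
                                  sl_slack = 2.2, degree = 3) {
  if (is.data.frame(sl_um)) {
    stress_kn_m2 <- sl_um$stress_kn_m2
    sl_um <- sl_um$sl_um
  }
  if (length(sl_um) < 4) stop("need at least 4 points", call. = FALSE)
  if (sl_eval < min(sl_um) || sl_eval > max(sl_um)) {
    stop(sprintf("evaluation point %.2f um lies outside the data range",
                 sl_eval), call. = FALSE)
  }
  check_positive(sl_slack = sl_slack)
  degree <- min(degree, length(sl_um) - 1)
  fit <- stats::lm(stress_kn_m2 ~ stats::poly(sl_um, degree, raw = TRUE))
  cf <- coef(fit)
  # derivative of the raw polynomial at sl_eval
  tangent <- sum(cf[-1] * seq_len(degree) * sl_eval^(seq_len(degree) - 1))
  out <- list(e_per_um = tangent,
              e_per_strain = tangent * sl_slack,
              sl_eval = sl_eval, sl_slack = sl_slack,
              failure_sl = max(sl_um), degree = degree, lm = fit,
              sl_um = sl_um, stress_kn_m2 = stress_kn_m2)
  class(out) <- c("passive_fit", "fibr_fit")
  out
}

#' @export
print.passive_fit <- function(x, ...) {
  cat(sprintf("Passive modulus (degree-%d polynomial tangent at sl = %.2f um)\n",
              x$degree, x$sl_eval))
  cat(sprintf("  E = %.4g kN/m^2 per um sl = %.4g kN/m^2 per unit strain (slack %.2f um)\n",
              x$e_per_um, x$e_per_strain, x$sl_slack))
  cat(sprintf("  last recorded sl (failure) = %.2f um\n", x$failure_sl))
  invisible(x)
}
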