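#' Pennation-corrected whole-muscle cross-sectional area
#'
#' CSA is estimated from wet weight and optimal length as
#' \deqn{CSA = w \cos\theta / (L_f \delta)}
#' where \eqn{L_f} is the fibre length (muscle length times the
#' muscle-specific fibre-length ratio), \eqn{\theta} the pennation angle and
#' \eqn{\delta} the muscle density. Built-in profiles carry the standard
#' mouse constants: EDL \eqn{\theta = 8.3°}, \eqn{L_f/L_0 = 0.51}; soleus
#' \eqn{\theta = 8.7°}, \eqn{L_f/L_0 = 0.75}; density 1.056 g/cm^3.
#'
#' @param weight_g Muscle wet weight, g.
#' @param length_cm Muscle length at the force--length plateau (L0), cm.
#' @param muscle Built-in profile, `"edl"` or `"soleus"`; ignored when both
#'   `theta_deg` and `lf_factor` are supplied.
#' @param theta_deg Pennation angle, degrees in \[0, 90).
#' @param lf_factor Fibre-length/muscle-length ratio.
#' @param density Muscle density, g/cm^3.
#' @return An object of class `muscle_geometry`: `w`, `L0`, `theta_deg`,
#'   `lf_factor`, `density`, `Lf` (cm) and `csa_cm2`.
#' @examples
#' muscle_csa(weight_g = 0.010, length_cm = 1.0, muscle = "edl")
#' @export
muscle_csa <- function(weight_g, length_cm, muscle = c("edl", "soleus"),
                       theta_deg = NULL, lf_factor = NULL, density = 1.056) {
  check_positive(weight_g = weight_g, length_cm = length_cm,
                 density = density)
  profiles <- list(edl = list(theta_deg = 8.3, lf_factor = 0.51),
                   soleus = list(theta_deg = 8.7, lf_factor = 0.75))
  if (is.null(theta_deg) || is.null(lf_factor)) {
    muscle <- match.arg(muscle)
    prof <- profiles[[muscle]]
    if (is.null(theta_deg)) theta_deg <- prof$theta_deg
    if (is.null(lf_factor)) lf_factor <- prof$lf_factor
  } else {
    muscle <- "custom"
  }
  if (theta_deg < 0 || theta_deg >= 90) {
    stop("`theta_deg` must lie in [0, 90)", call. = FALSE)
  }
  check_positive(lf_factor = lf_factor)
  lf <- lf_factor * length_cm
  csa <- weight_g * cos(theta_deg * pi / 180) / (lf * density)
  out <- list(w = weight_g, L0 = length_cm, theta_deg = theta_deg,
              lf_factor = lf_factor, density = density, Lf = lf,
              muscle = muscle, csa_cm2 = csa)
  class(out) <- "muscle_geometry"
  out
}

#' @export
print.muscle_geometry <- function(x, ...) {
  cat(sprintf("Muscle geometry (%s): w = %g g, L0 = %g cm, theta = %g deg\n",
              x$muscle, x$w, x$L0, x$theta_deg))
  cat(sprintf("  Lf = %g cm (Lf/L0 = %g), density = %g g/cm^3\n",
              x$Lf, x$lf_factor, x$density))
  cat(sprintf("  CSA = %.5g cm^2\n", x$csa_cm2))
  invisible(x)
}

#' Fit the Hill hyperbolic force--velocity relation
#'
#' Ordinary least squares on velocity residuals for the Hill hyperbola
#' \eqn{(T + a)(V + b) = (V_0 + b)a}, with free positive regression
#' parameters a, b and V0. The curve is not constrained to pass through
#' (T0, 0); T0 is used only for initialization and for reporting the
#' curvature ratio a/T0. Fitting uses Levenberg--Marquardt with up to 10
#' seeded random restarts; persistent non-convergence yields a flagged
#' (`converged = FALSE`) result rather than an error.
#'
#' @param load Loads T in (0, T0\], force units, or a data frame with
#'   columns `load` and `velocity`.
#' @param velocity Shortening velocities (>= 0), velocity units.
#' @param t0 Isometric force, same units as `load`.
#' @return Object of class `fv_fit`: coefficients `a`, `b`, `v0`, plus
#'   `a_over_t0`, `rss`, `fitted`, `residuals`, `vcov`, `converged`.
#' @examples
#' fv <- gen_force_velocity(a = 0.25, b = 1, v0 = 4, t0 = 1, seed = 1)
#' fit <- fit_hill_fv(fv, t0 = 1)
#' coef(fit)
#' @export
fit_hill_fv <- function(load, velocity = NULL, t0) {
  if (is.data.frame(load)) {
    velocity <- load$velocity
    load <- load$load
  }
  check_positive(t0 = t0)
  check_nonneg(load, "load")
  if (length(load) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(velocity < -1e-8)) {
    stop("`velocity` must be non-negative", call. = FALSE)
  }
  dat <- data.frame(T = load, V = velocity)
  a0 <- 0.25 * t0
  v00 <- max(velocity)
  b0 <- a0 * v00 / t0
  starts <- list(list(a = a0, b = b0, v0 = v00))
  for (i in 1:10) {
    starts[[i + 1]] <- with_seed(i, list(a = a0 * exp(rnorm(1, sd = 0.5)),
                                         b = b0 * exp(rnorm(1, sd = 0.5)),
                                         v0 = v00 * exp(rnorm(1, sd = 0.3))))
  }
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(V ~ a * (v0 + b) / (T + a) - b, data = dat,
                        start = st, lower = rep(1e-9, 3),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- list(coefficients = c(a = NA_real_, b = NA_real_, v0 = NA_real_),
                t0 = t0, a_over_t0 = NA_real_, rss = NA_real_,
                data = dat, fitted = rep(NA_real_, nrow(dat)),
                residuals = rep(NA_real_, nrow(dat)), vcov = NULL,
                converged = FALSE)
    class(out) <- c("fv_fit", "fibr_fit")
    return(out)
  }
  cf <- coef(fit)
  out <- list(coefficients = c(a = unname(cf["a"]), b = unname(cf["b"]),
                               v0 = unname(cf["v0"])),
              t0 = t0, a_over_t0 = unname(cf["a"]) / t0,
              rss = sum(residuals(fit)^2),
              data = dat, fitted = fitted(fit),
              residuals = as.numeric(residuals(fit)),
              vcov = tryCatch(vcov(fit), error = function(e) NULL),
              converged = TRUE)
  class(out) <- c("fv_fit", "fibr_fit")
  out
}

#' @export
coef.fv_fit <- function(object, ...) object$coefficients

#' @export
predict.fv_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$T else {
    if (is.data.frame(newdata)) newdata$load else newdata
  }
  cf <- object$coefficients
  cf["a"] * (cf["v0"] + cf["b"]) / (T + cf["a"]) - cf["b"]
}

#' @export
residuals.fv_fit <- function(object, ...) object$residuals

#' @export
fitted.fv_fit <- function(object, ...) object$fitted

#' @export
print.fv_fit <- function(x, ...) {
  cat("Hill force-velocity fit: (T + a)(V + b) = (V0 + b) a\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE after seeded restarts\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  a = %.4g, b = %.4g, V0 = %.4g (a/T0 = %.3g)\n",
              cf["a"], cf["b"], cf["v0"], x$a_over_t0))
  cat(sprintf("  RSS = %.3g over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.fv_fit <- function(object, ...) {
  print(object)
  if (object$converged && !is.null(object$vcov)) {
    se <- sqrt(diag(object$vcov))
    cat(sprintf("  SE: a %.3g, b %.3g, V0 %.3g\n", se[1], se[2], se[3]))
  }
  invisible(object)
}

#' @export
plot.fv_fit <- function(x, ...) {
  plot(x$data$T, x$data$V, xlab = "load", ylab = "velocity", pch = 19, ...)
  if (x$converged) {
    tt <- seq(0, max(x$data$T), length.out = 200)
    lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' @export
simulate.fv_fit <- function(object, nsim = 1, seed = 1, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit",
                              call. = FALSE)
  cf <- object$coefficients
  sd_hat <- sqrt(object$rss / max(1, nrow(object$data) - 3))
  lapply(seq_len(nsim), function(i) {
    gen_force_velocity(a = cf["a"], b = cf["b"], v0 = cf["v0"],
                       t0 = object$t0, loads = object$data$T,
                       noise_sd = sd_hat, seed = seed + i - 1)
  })
}

#' Power curve and maximum power from a force--velocity fit
#'
#' Mechanical power is \eqn{W(T) = T \, V(T)} along the fitted hyperbola. It
#' vanishes at T = 0 and at the isometric intercept
#' \eqn{T_{max} = a V_0 / b}, and peaks at the closed-form optimum
#' \deqn{T^* = \sqrt{a (T_{max} + a)} - a,}
#' which for physiological curvature lies near one third of the isometric
#' force. The closed form is cross-checked against the grid argmax.
#'
#' @param fit A converged [fit_hill_fv()] result.
#' @param n_grid Number of load-grid points.
#' @return Object of class `power_curve`: `loads`, `power`, `wmax`,
#'   `t_at_wmax`, `t_at_wmax_rel` (relative to T0), `tmax`.
#' @export
power_from_fit <- function(fit, n_grid = 1000) {
  stopifnot(inherits(fit, "fv_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  cf <- fit$coefficients
  tmax <- cf[["a"]] * cf[["v0"]] / cf[["b"]]
  if (!is.finite(tmax) || tmax <= 0) {
    stop("degenerate fit: isometric intercept Tmax <= 0", call. = FALSE)
  }
  loads <- seq(0, tmax, length.out = n_grid)
  vel <- pmax(0, cf[["a"]] * (cf[["v0"]] + cf[["b"]]) / (loads + cf[["a"]]) -
                cf[["b"]])
  power <- loads * vel
  t_star <- sqrt(cf[["a"]] * (tmax + cf[["a"]])) - cf[["a"]]
  v_star <- cf[["a"]] * (cf[["v0"]] + cf[["b"]]) / (t_star + cf[["a"]]) -
    cf[["b"]]
  out <- list(loads = loads, power = power,
              wmax = t_star * v_star, t_at_wmax = t_star,
              t_at_wmax_rel = t_star / fit$t0, tmax = tmax,
              t_grid_argmax = loads[which.max(power)])
  class(out) <- "power_curve"
  out
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve: Wmax = %.4g at T = %.4g (%.3g x T0); Tmax = %.4g\n",
              x$wmax, x$t_at_wmax, x$t_at_wmax_rel, x$tmax))
  invisible(x)
}

#' @export
plot.power_curve <- function(x, ...) {
  plot(x$loads, x$power, type = "l", xlab = "load", ylab = "power", ...)
  abline(v = x$t_at_wmax, lty = 3)
  invisible(x)
}

#' Summarize an eccentric-contraction injury series
#'
#' Isometric force is measured before and after a series of eccentric
#' (active-stretch) contractions; the injury readout is the percent drop in
#' mean isometric force:
#' `percent_drop = 100 * (1 - mean(post) / mean(pre))`.
#'
#' @param pre_iso Pre-series isometric forces, mN (non-empty, positive).
#' @param ec_forces Peak force of each eccentric contraction, mN.
#' @param post_iso Post-series isometric forces, mN.
#' @return Object of class `eccentric_series`: the three series plus
#'   `percent_drop`.
#' @export
summarize_eccentric <- function(pre_iso, ec_forces, post_iso) {
  if (length(pre_iso) == 0 || length(post_iso) == 0) {
    stop("`pre_iso` and `post_iso` must be non-empty", call. = FALSE)
  }
  check_positive(pre_iso = pre_iso, post_iso = post_iso)
  if (mean(pre_iso) == 0) stop("zero mean pre-series force", call. = FALSE)
  out <- list(pre_iso = pre_iso, ec_forces = ec_forces, post_iso = post_iso,
              percent_drop = 100 * (1 - mean(post_iso) / mean(pre_iso)))
  class(out) <- "eccentric_series"
  out
}

#' @export
print.eccentric_series <- function(x, ...) {
  cat(sprintf("Eccentric series: %d contractions; force drop %.1f%% (pre %.4g -> post %.4g)\n",
              length(x$ec_forces), x$percent_drop,
              mean(x$pre_iso), mean(x$post_iso)))
  invisible(x)
}
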