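#' Synthetic load--velocity data from a Hill hyperbola
#'
#' Draws shortening velocities at given loads from the Hill hyperbolic
#' force--velocity relation \eqn{(T + a)(V + b) = (V_0 + b)a}, i.e.
#' \eqn{V(T) = a(V_0 + b)/(T + a) - b}, with additive Gaussian noise on the
#' velocity. Used to validate [fit_hill_fv()] by parameter recovery.
#'
#' @param a Curvature parameter, force units (> 0).
#' @param b Curvature parameter, velocity units (> 0).
#' @param v0 Unloaded shortening velocity, velocity units (> 0).
#' @param t0 Isometric force; only used to build the default load grid (> 0).
#' @param loads Load grid (force units). Default: 9 loads evenly spaced over
#'   \code{[0.1, 0.95] * t0}.
#' @param noise_sd Standard deviation of additive Gaussian velocity noise.
#' @param seed Integer seed; required, no global RNG default.
#' @return A data frame with columns `load` and `velocity`; the generating
#'   parameters are attached as attribute `"params"`.
#' @examples
#' fv <- gen_force_velocity(a = 0.25, b = 1, v0 = 4, t0 = 1, seed = 1)
#' fit_hill_fv(fv$load, fv$velocity, t0 = 1)
#' @export
gen_force_velocity <- function(a, b, v0, t0, loads = NULL, noise_sd = 0,
                               seed) {
  check_positive(a = a, b = b, v0 = v0, t0 = t0)
  check_nonneg(noise_sd, "noise_sd")
  if (is.null(loads)) loads <- seq(0.1, 0.95, length.out = 9) * t0
  check_nonneg(loads, "loads")
  v <- a * (v0 + b) / (loads + a) - b
  v <- with_seed(seed, v + rnorm(length(loads), sd = noise_sd))
  out <- data.frame(load = loads, velocity = v)
  attr(out, "params") <- list(a = a, b = b, v0 = v0, t0 = t0,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic force--pCa data from the Hill sigmoid
#'
#' Relative tension follows
#' \eqn{T_{rel}(pCa) = 1 / (1 + 10^{n_H (pCa - pK)})}: half-maximal at
#' \code{pca = pk}, saturating towards 1 at high calcium (low pCa). Gaussian
#' noise is added and the result clipped to \[0, 1\] (relative tension is
#' physically bounded).
#'
#' @param nh Hill coefficient (steepness / cooperativity), > 0.
#' @param pk pCa of half-maximal tension.
#' @param pca pCa grid; default spans the activating range 6.5--4.5.
#' @inheritParams gen_force_velocity
#' @return Data frame with columns `pca`, `t_rel`.
#' @export
gen_force_pca <- function(nh, pk, pca = seq(6.5, 4.5, by = -0.2),
                          noise_sd = 0, seed) {
  check_positive(nh = nh)
  check_nonneg(noise_sd, "noise_sd")
  if (length(pca) == 0) stop("`pca` grid is empty", call. = FALSE)
  t_rel <- 1 / (1 + 10^(nh * (pca - pk)))
  t_rel <- with_seed(seed, t_rel + rnorm(length(pca), sd = noise_sd))
  if (noise_sd > 0) t_rel <- clip01(t_rel)
  out <- data.frame(pca = pca, t_rel = t_rel)
  attr(out, "params") <- list(nh = nh, pk = pk, noise_sd = noise_sd,
                              seed = seed)
  out
}

#' Synthetic single-site binding isotherm
#'
#' Bound fraction at each actin concentration follows the one-site saturation
#' curve \eqn{f([A]) = [A] / ([A] + K_d)}, with Gaussian noise clipped to
#' \[0, 1\]. Emulates co-sedimentation assays in which a fixed ligand
#' concentration is incubated with 1--30 uM polymerized actin.
#'
#' @param kd Dissociation constant, uM (> 0).
#' @param actin_um Actin concentration grid, uM (non-negative).
#' @inheritParams gen_force_velocity
#' @return Data frame with columns `actin_um`, `bound_frac`.
#' @export
gen_binding_isotherm <- function(kd, actin_um = c(1, 2, 4, 7, 10, 14, 18, 24, 30),
                                 noise_sd = 0, seed) {
  check_positive(kd = kd)
  check_nonneg(actin_um, "actin_um")
  check_nonneg(noise_sd, "noise_sd")
  f <- actin_um / (actin_um + kd)
  f <- with_seed(seed, f + rnorm(length(actin_um), sd = noise_sd))
  if (noise_sd > 0) f <- clip01(f)
  out <- data.frame(actin_um = actin_um, bound_frac = f)
  attr(out, "params") <- list(kd = kd, noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic pyrene-actin polymerization trace
#'
#' Fluorescence rises from a baseline to a plateau as a single exponential
#' with an explicit lag phase:
#' \eqn{F(t) = base + (plat - base) \max(0, 1 - e^{-k_{obs}(t - lag)})}.
#' The analysis extracts only a linear-region slope, which this shape
#' exercises fully; no mechanistic nucleation--elongation model is attempted.
#'
#' @param k_obs Observed assembly rate constant, 1/s (> 0).
#' @param lag Lag time before fluorescence rise, s.
#' @param plateau_rfu Steady-state plateau fluorescence (> baseline).
#' @param baseline_rfu Baseline fluorescence.
#' @param times Strictly increasing time grid, s.
#' @inheritParams gen_force_velocity
#' @return Data frame with columns `time_s`, `rfu`.
#' @export
gen_polymerization_trace <- function(k_obs, lag = 0, plateau_rfu = 1000,
                                     baseline_rfu = 100,
                                     times = seq(0, 2000, by = 2),
                                     noise_sd = 0, seed) {
  check_positive(k_obs = k_obs)
  check_nonneg(lag, "lag")
  check_nonneg(noise_sd, "noise_sd")
  if (plateau_rfu <= baseline_rfu) {
    stop("`plateau_rfu` must exceed `baseline_rfu`", call. = FALSE)
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing grid", call. = FALSE)
  }
  f <- baseline_rfu + (plateau_rfu - baseline_rfu) *
    pmax(0, 1 - exp(-k_obs * (times - lag)))
  f <- with_seed(seed, f + rnorm(length(times), sd = noise_sd))
  out <- data.frame(time_s = times, rfu = f)
  attr(out, "params") <- list(k_obs = k_obs, lag = lag,
                              plateau_rfu = plateau_rfu,
                              baseline_rfu = baseline_rfu,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic Latrunculin-A depolymerization trace pair
#'
#' Generates matched protein-free and protein-plus disassembly traces. On the
#' normalized scale the decays are \eqn{e^{-k_0 t}} and
#' \eqn{e^{-k_0 (1 - p) t}} where \eqn{p} is the fractional protection
#' conferred by the actin-binding protein; both are mapped back to raw RFU
#' with the stated baseline and maximum. The default 600-s time base matches
#' standard fluorometer runs for this assay.
#'
#' @param k0 Disassembly rate constant of unprotected F-actin, 1/s (> 0).
#' @param protection Fractional rate reduction in \[0, 1).
#' @param baseline_rfu,max_rfu Raw fluorescence scale.
#' @param times Strictly increasing time grid, s.
#' @inheritParams gen_force_velocity
#' @return List with elements `free` and `plus`, each a data frame with
#'   columns `time_s`, `rfu`.
#' @export
gen_depolymerization_pair <- function(k0, protection, baseline_rfu = 100,
                                      max_rfu = 1000,
                                      times = seq(0, 600, by = 1),
                                      noise_sd = 0, seed) {
  check_positive(k0 = k0)
  if (!is.numeric(protection) || protection < 0 || protection >= 1) {
    stop("`protection` must lie in [0, 1)", call. = FALSE)
  }
  check_nonneg(noise_sd, "noise_sd")
  if (max_rfu <= baseline_rfu) {
    stop("`max_rfu` must exceed `baseline_rfu`", call. = FALSE)
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing grid", call. = FALSE)
  }
  amp <- max_rfu - baseline_rfu
  f_free <- baseline_rfu + amp * exp(-k0 * times)
  f_plus <- baseline_rfu + amp * exp(-k0 * (1 - protection) * times)
  noisy <- with_seed(seed, {
    list(free = f_free + rnorm(length(times), sd = noise_sd),
         plus = f_plus + rnorm(length(times), sd = noise_sd))
  })
  out <- list(free = data.frame(time_s = times, rfu = noisy$free),
              plus = data.frame(time_s = times, rfu = noisy$plus))
  attr(out, "params") <- list(k0 = k0, protection = protection,
                              baseline_rfu = baseline_rfu, max_rfu = max_rfu,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic Z-line density profile
#'
#' A flat background carrying a centred trapezoidal peak: plateau of width
#' \code{width_nm - 2 * shoulder} flanked by linear shoulders, where
#' \code{shoulder = shoulder_frac * width_nm} on each side, so the width at
#' the base of the peak is exactly `width_nm`. The trapezoid makes the
#' ground-truth base width unambiguous for validating [zline_width()].
#'
#' @param width_nm True width at base, nm (> 0).
#' @param peak_amp Peak amplitude above background, intensity units.
#' @param background Background intensity level.
#' @param shoulder_frac Length of each linear shoulder as a fraction of
#'   `width_nm`, in \[0, 0.5\].
#' @param positions Strictly increasing position grid, nm; must contain the
#'   peak with margin for background estimation.
#' @inheritParams gen_force_velocity
#' @return Data frame with columns `position_nm`, `intensity`.
#' @export
gen_zline_profile <- function(width_nm, peak_amp = 1, background = 0.1,
                              shoulder_frac = 0.1,
                              positions = seq(-150, 150, by = 0.5),
                              noise_sd = 0, seed) {
  check_positive(width_nm = width_nm, peak_amp = peak_amp)
  check_nonneg(background, "background")
  if (shoulder_frac < 0 || shoulder_frac > 0.5) {
    stop("`shoulder_frac` must lie in [0, 0.5]", call. = FALSE)
  }
  span <- diff(range(positions))
  if (width_nm >= span) {
    stop("`width_nm` exceeds the profile support", call. = FALSE)
  }
  half <- width_nm / 2
  sh <- shoulder_frac * width_nm
  x <- abs(positions)
  frac <- ifelse(x <= half - sh, 1,
                 ifelse(x < half,
                        if (sh > 0) (half - x) / sh else 0,
                        0))
  intensity <- background + peak_amp * frac
  intensity <- with_seed(seed,
                         intensity + rnorm(length(positions), sd = noise_sd))
  out <- data.frame(position_nm = positions, intensity = intensity)
  attr(out, "params") <- list(width_nm = width_nm, peak_amp = peak_amp,
                              background = background,
                              shoulder_frac = shoulder_frac,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic fibre cross-sectional-area population
#'
#' Per-fibre CSA values are drawn log-normally within each fibre type
#' (muscle fibre size distributions are right-skewed and well described as
#' log-normal); types are assigned by a multinomial draw with the given
#' proportions.
#'
#' @param mu_log Mean of log(CSA / um^2).
#' @param sigma_log SD of log(CSA); 0 gives all fibres CSA `exp(mu_log)`.
#' @param n_fibres Number of fibres (> 0).
#' @param type_props Named fibre-type proportions summing to 1.
#' @param muscle,genotype Labels carried into the output table.
#' @inheritParams gen_force_velocity
#' @return Data frame with columns `csa_um2`, `fibre_type`, `muscle`,
#'   `genotype`.
#' @export
gen_fibre_population <- function(mu_log, sigma_log, n_fibres,
                                 type_props = c(`2B` = 0.6, `2X` = 0.25,
                                                `2A` = 0.1, `1` = 0.05),
                                 muscle = "EDL", genotype = "WT", seed) {
  if (!is.numeric(n_fibres) || n_fibres <= 0 || n_fibres != round(n_fibres)) {
    stop("`n_fibres` must be a positive integer", call. = FALSE)
  }
  check_nonneg(sigma_log, "sigma_log")
  if (abs(sum(type_props) - 1) > 1e-9) {
    stop("`type_props` must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    types <- sample(names(type_props), n_fibres, replace = TRUE,
                    prob = type_props)
    csa <- exp(rnorm(n_fibres, mean = mu_log, sd = sigma_log))
    data.frame(csa_um2 = csa, fibre_type = types,
               muscle = muscle, genotype = genotype,
               stringsAsFactors = FALSE)
  })
}
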