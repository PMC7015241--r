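#' @keywords internal
#' @importFrom stats coef fitted residuals rnorm vcov simulate
#' @importFrom graphics abline lines
#' @importFrom grDevices dev.cur
"_PACKAGE"

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards. Every stochastic generator in the package goes through this, so
# there is no hidden global RNG dependence: identical (seed, parameters)
# always reproduce identical draws.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_positive <- function(..., .what = NULL) {
  vals <- list(...)
  nms <- if (is.null(.what)) names(vals) else .what
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be positive and finite", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", what), call. = FALSE)
  }
  invisible(TRUE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Closed-form simple linear regression, used internally where a full lm object
# is unnecessary. Returns c(intercept, slope).
ols_line <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("zero variance in predictor", call. = FALSE)
  slope <- sum((x - xb) * (y - yb)) / sxx
  c(intercept = yb - slope * xb, slope = slope)
}
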