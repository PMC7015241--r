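# Independent brute-force oracles used to cross-check the nonlinear fitters.
# Each is a plain grid search with iterative zoom, sharing no code with the
# fitting routines.

grid_refine <- function(sse_fun, lower, upper, n = 15, rounds = 4) {
  lo <- lower
  hi <- upper
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- Map(function(l, u) seq(l, u, length.out = n), lo, hi)
    pts <- do.call(expand.grid, grids)
    sse <- apply(pts, 1, function(p) sse_fun(as.numeric(p)))
    i <- which.min(sse)
    best <- as.numeric(pts[i, ])
    step <- mapply(function(l, u) (u - l) / (n - 1), lo, hi)
    lo <- pmax(lower, best - 2 * step)
    hi <- pmin(upper, best + 2 * step)
  }
  best
}

oracle_fv <- function(load, velocity, t0) {
  sse <- function(p) {
    v_hat <- p[1] * (p[3] + p[2]) / (load + p[1]) - p[2]
    sum((velocity - v_hat)^2)
  }
  p <- grid_refine(sse, lower = c(0.01 * t0, 0.01, 0.2 * max(velocity)),
                   upper = c(2 * t0, 10, 3 * max(velocity)),
                   n = 12, rounds = 7)
  c(a = p[1], b = p[2], v0 = p[3])
}

oracle_pca <- function(pca, t_rel) {
  sse <- function(p) {
    sum((t_rel - 1 / (1 + 10^(p[1] * (pca - p[2]))))^2)
  }
  p <- grid_refine(sse, lower = c(0.5, min(pca)), upper = c(8, max(pca)),
                   n = 25, rounds = 7)
  c(nh = p[1], pk = p[2])
}

oracle_kd <- function(actin_um, bound_frac) {
  sse <- function(p) sum((bound_frac - actin_um / (actin_um + p[1]))^2)
  grid_refine(sse, lower = 0.1, upper = 200, n = 400, rounds = 4)[1]
}

# Shared depolymerization pipeline: raw pair -> normalization on the
# final-LatA-point/max convention -> initial-rate percent decrease.
run_depoly_pipeline <- function(pair, window_s = 60) {
  lata_final <- pair$free$rfu[nrow(pair$free)]
  free_n <- normalize_depolymerization(pair$free, lata_final)
  plus_n <- normalize_depolymerization(pair$plus, lata_final)
  depolymerization_decrease(free_n, plus_n, window_s = window_s)
}
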