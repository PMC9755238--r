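# Independent brute-force oracles used to validate the vectorised
# implementations. Deliberately naive (triple loops, literal definitions).

# Chebyshev-ball dilation: every voxel within Chebyshev distance <= radius
# of a TRUE voxel
dilate_oracle <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    xs <- max(1, idx[v, 1] - radius):min(d[1], idx[v, 1] + radius)
    ys <- max(1, idx[v, 2] - radius):min(d[2], idx[v, 2] + radius)
    zs <- max(1, idx[v, 3] - radius):min(d[3], idx[v, 3] + radius)
    out[xs, ys, zs] <- TRUE
  }
  out
}

# 26-neighbourhood count by explicit loops, out-of-bounds = FALSE
count26_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] && mask[ii, jj, kk])
        cnt <- cnt + 1L
    }
    out[i, j, k] <- cnt
  }
  out
}

# Benjamini-Hochberg step-up by the literal definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# OLS by the normal equations
normal_eq_fit <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

# toy label volume: start from a filler label, then paint named regions
toy_volume <- function(dims, paint = list(), voxel_size = c(0.5, 0.5, 0.5),
                       base = "white_matter") {
  sch <- phantom_scheme()
  grid <- array(scheme_id(sch, base), dim = dims)
  for (nm in names(paint)) grid[paint[[nm]]] <- scheme_id(sch, nm)
  label_volume(grid, voxel_size = voxel_size, scheme = sch)
}

# random claustrum + insular-WM configuration for property tests
random_claustrum_volume <- function(dims = c(12L, 12L, 12L)) {
  sch <- phantom_scheme()
  grid <- array(scheme_id(sch, "white_matter"), dim = dims)
  blob <- function() {
    ctr <- sapply(dims, function(n) sample(4:(n - 3), 1))
    ext <- sample(1:2, 3, replace = TRUE)
    g <- claustrumdev:::index_grids(dims)
    abs(g$x - ctr[1]) <= ext[1] & abs(g$y - ctr[2]) <= ext[2] &
      abs(g$z - ctr[3]) <= ext[3]
  }
  cl <- blob(); cr <- blob() & !cl
  while (!any(cr)) cr <- blob() & !cl
  wml <- dilate_chebyshev(cl, 2) & !cl & !cr
  wmr <- dilate_chebyshev(cr, 2) & !cl & !cr & !wml
  grid[wml] <- scheme_id(sch, "insular_wm_left")
  grid[wmr] <- scheme_id(sch, "insular_wm_right")
  grid[cl] <- scheme_id(sch, "claustrum_left")
  grid[cr] <- scheme_id(sch, "claustrum_right")
  label_volume(grid, scheme = sch)
}

# minimal two-group table with inert covariates for recovery simulations
simulate_two_group <- function(n_term, n_preterm, mean_term, sd_term,
                               mean_preterm, sd_preterm) {
  eff <- effect_params(outcomes = list(
    y = outcome_def(mean_term, sd_term, mean_preterm, sd_preterm)))
  generate_cohort(cohort_spec(n_preterm = n_preterm, n_term = n_term),
                  effects = eff, seed = sample.int(2^31 - 1, 1))
}
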