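# Small, fast synthetic-embryo parameter sets used across tests.

small_truth <- function(seed = 11, noise_sd = 0, ...) {
  args <- list(grid_dim = c(12, 24, 24), voxel_size_um = c(9, 6, 6),
               embryo_radius_um = 55, n_nuclei = 25, nucleus_radius_um = 8,
               reporter_coverage = 0.6, noise_sd = noise_sd, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(embryo_truth, args)
}

# Random tiny channel_volume for oracle checks: 3 channels, values 0..maxv.
random_tiny_volume <- function(dim_zyx = c(5, 5, 5), maxv = 1000) {
  vox <- array(sample.int(maxv + 1L, 3L * prod(dim_zyx), replace = TRUE) - 1L,
               dim = c(3L, dim_zyx))
  channel_volume(vox, c("DAPI", "GFP", "EFFECTOR"), c(9, 6, 6), 16)
}

random_mask <- function(dim_zyx = c(5, 5, 5), p = 0.5, name = "DAPI") {
  region_mask(array(runif(prod(dim_zyx)) < p, dim = dim_zyx), name)
}

# Noiseless 3PL samples from known parameters.
logistic_points <- function(a, b, c, x) {
  tibble::tibble(x = x, y = c / (1 + exp(-a * (x - b))))
}

# Quantify one synthetic sample generated at a target reporter coverage.
quantify_coverage_fixture <- function(coverage, seed = 21) {
  et <- small_truth(seed = seed, noise_sd = 0, reporter_coverage = coverage,
                    n_nuclei = 30)
  s <- generate_volume(et, 0.5)
  quantify_sample(s$volume, config = quant_config())
}

# Independent brute-force Otsu oracle: minimize total within-class SS over
# all splits of the sorted sample.
otsu_oracle <- function(x) {
  ux <- sort(unique(x))
  best <- NULL
  best_ss <- Inf
  for (t in ux[-length(ux)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best <- t }
  }
  best
}

# Independent REML criterion for value ~ condition + (1 | replicate),
# computed from dense matrices; profiled over the variance ratio on a grid.
reml_grid_oracle <- function(df, ratio_grid = exp(seq(log(1e-4), log(1e4), length.out = 4001))) {
  X <- model.matrix(~condition, df)
  Z <- model.matrix(~replicate - 1, df)
  y <- df$value
  n <- length(y); p <- ncol(X)
  crit <- vapply(ratio_grid, function(r) {
    V <- diag(n) + r * tcrossprod(Z)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    e <- y - X %*% beta
    q <- drop(t(e) %*% Vi %*% e)
    s2 <- q / (n - p)
    (n - p) * log(s2) + determinant(V)$modulus + determinant(XtViX)$modulus + (n - p)
  }, numeric(1))
  r <- ratio_grid[which.min(crit)]
  V <- diag(n) + r * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  s2 <- drop(t(e) %*% Vi %*% e) / (n - p)
  c(residual = s2, replicate = r * s2)
}
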