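# Shared oracles: brute-force tensor composition, quadrature CDFs for
# distributional checks, and autocorrelation-robust standard errors.

# Element-by-element nested-loop evaluation of the CP sum (independent of
# parafac_compose's vectorized path).
brute_force_compose <- function(margins) {
  dims <- margins$dims
  B <- array(0, dim = dims$p)
  idx_grid <- as.matrix(expand.grid(lapply(dims$p, seq_len)))
  for (row in seq_len(nrow(idx_grid))) {
    ii <- idx_grid[row, ]
    val <- 0
    for (r in seq_len(margins$R)) {
      prod_r <- 1
      for (j in seq_len(dims$D)) prod_r <- prod_r * margins$beta[[r]][[j]][ii[j]]
      val <- val + prod_r
    }
    B[matrix(ii, 1)] <- val
  }
  B
}

random_margins <- function(p, R, seed = 1) {
  set.seed(seed)
  tensor_margins(replicate(R, lapply(p, function(pj) rnorm(pj)), simplify = FALSE),
                 tensor_dims(p))
}

# numeric CDF from an unnormalized log-kernel on (0, Inf)
quad_cdf <- function(log_kernel, upper_hint = 50) {
  probe <- seq(1e-8, upper_hint, length.out = 4000)
  M <- max(log_kernel(probe), na.rm = TRUE)
  Z <- stats::integrate(function(t) exp(log_kernel(t) - M), 0, Inf,
                        rel.tol = 1e-10)$value
  function(q) vapply(q, function(u) {
    stats::integrate(function(t) exp(log_kernel(t) - M), 0, u,
                     rel.tol = 1e-9)$value / Z
  }, numeric(1))
}

# Geyer initial-positive-sequence standard error for a correlated chain
ips_se <- function(x) {
  n <- length(x)
  g <- as.vector(stats::acf(x, lag.max = min(n - 2, 4000), type = "covariance",
                            plot = FALSE, demean = TRUE)$acf)
  v <- g[1]
  k <- 2
  while (k + 1 <= length(g)) {
    pair <- g[k] + g[k + 1]
    if (pair <= 0) break
    v <- v + 2 * pair
    k <- k + 2
  }
  sqrt(max(v, g[1] * 1e-12) / n)
}

# small prepared-data helper for sampler unit tests
tiny_data <- function(n = 15, p_dims = c(2, 2), q = 2, p_demo = 1, seed = 1,
                      hyper = btr_hyper()) {
  set.seed(seed)
  Z <- if (p_demo > 0) matrix(rnorm(n * p_demo), n, p_demo) else NULL
  Z1 <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
  X <- array(rnorm(n * prod(p_dims)), dim = c(n, p_dims))
  btreg:::prepare_data(rnorm(n), X, Z, Z1, hyper)
}
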