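# Unit checks of the individual full-conditional updates against light
# oracles; the deeper 1e5-draw suite lives in test-acceptance.R.

test_that("update_s reduces to its prior-ish gamma at zero margins", {
  dims <- tensor_dims(c(6, 4))
  m0 <- tensor_margins(list(lapply(dims$p, numeric)), dims)
  set.seed(1)
  draws <- replicate(2e4, update_s(m0, tau_r = 1, a_lambda = 2.4, b_lambda = 1.1)[1, 1])
  expect_equal(mean(draws), (2.4 + 6) / 1.1, tolerance = 0.01)
  # doubling the L1 norm increases the rate accordingly
  m1 <- tensor_margins(list(list(rep(0.5, 6), rep(0.2, 4))), dims)
  m2 <- tensor_margins(list(list(rep(1.0, 6), rep(0.4, 4))), dims)
  set.seed(2)
  d1 <- replicate(2e4, update_s(m1, 1, 2.4, 1.1)[1, 1])
  set.seed(2)
  d2 <- replicate(2e4, update_s(m2, 1, 2.4, 1.1)[1, 1])
  expect_equal(mean(d1), (2.4 + 6) / (1.1 + 3), tolerance = 0.02)
  expect_equal(mean(d2), (2.4 + 6) / (1.1 + 6), tolerance = 0.02)
})

test_that("update_w single-site law matches gamma reduction and quadrature", {
  dims <- tensor_dims(c(1, 1))
  set.seed(3)
  # beta = 0: w ~ Ga(1/2, s^2/2)
  m0 <- tensor_margins(list(list(0, 0)), dims)
  w0 <- replicate(2e4, update_w(m0, tau_r = 1, s = matrix(2, 2, 1))[[1]][[1]])
  expect_gt(stats::ks.test(w0, stats::pgamma, shape = 0.5, rate = 2)$p.value, 0.01)
  # nonzero beta: giG(1/2, s^2, beta^2/tau) vs quadrature CDF
  mb <- tensor_margins(list(list(0.9, 0.4)), dims)
  wb <- replicate(2e4, update_w(mb, tau_r = 1.5, s = matrix(2, 2, 1))[[1]][[1]])
  cdf <- quad_cdf(function(t) -0.5 * log(t) - (4 * t + (0.81 / 1.5) / t) / 2)
  expect_gt(stats::ks.test(wb, cdf)$p.value, 0.01)
})

test_that("margin conditional matches the scalar conjugate closed form", {
  # one-voxel image: scalar Bayesian regression with prior N(0, tau w)
  set.seed(4)
  n <- 50
  H <- matrix(rnorm(n), n, 1)
  ytilde <- rnorm(n)
  tau <- 1.4; w <- 0.6; s2 <- 0.8
  cond <- btreg:::margin_conditional(H, ytilde, w, tau, s2)
  post_var <- 1 / (sum(H^2) / s2 + 1 / (tau * w))
  post_mean <- post_var * sum(H * ytilde) / s2
  expect_equal(cond$mu, post_mean, tolerance = 1e-10)
  expect_equal(1 / cond$chol_prec[1, 1]^2, post_var, tolerance = 1e-10)
})

test_that("margin conditional approaches the prior as sigma^2 grows", {
  set.seed(5)
  H <- matrix(rnorm(20), 20, 2)
  cond <- btreg:::margin_conditional(H, rnorm(20), c(0.5, 1.5), 2, 1e12)
  expect_equal(cond$mu, c(0, 0), tolerance = 1e-4)
  Sig <- chol2inv(cond$chol_prec)
  expect_equal(Sig, diag(2 * c(0.5, 1.5)), tolerance = 1e-4)
})

test_that("gamma/sigma2 joint draw matches the conjugate NIG closed form", {
  # null model: B = 0, eta absent, Z = intercept only
  set.seed(6)
  n <- 40
  hyper <- btr_hyper(nu = 6, gamma_prior_scale = 2)
  X <- array(0, dim = c(n, 2, 2))
  data <- btreg:::prepare_data(rnorm(n, 1, 0.7), X, NULL, NULL, hyper)
  grids <- hyper_grids(2, 1)
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$margins$beta[[1]] <- list(c(0, 0), c(0, 0)); st$contrib[] <- 0
  S <- 4e4
  out <- matrix(NA_real_, S, 2)
  for (i in seq_len(S)) {
    st <- update_gamma_sigma(st, data, hyper)
    out[i, ] <- c(st$gamma[1], st$sigma2)
  }
  y <- data$y
  kap <- 1 / hyper$gamma_prior_scale
  post_prec <- n + kap
  mu_n <- sum(y) / post_prec
  a_n <- (n + hyper$nu) / 2
  b_n <- (hyper$nu * hyper$s0sq + sum(y^2) - sum(y)^2 / post_prec) / 2
  expect_equal(mean(out[, 2]), b_n / (a_n - 1), tolerance = 0.02)
  expect_equal(mean(out[, 1]), mu_n, tolerance = 0.02)
  expect_equal(stats::var(out[, 1]), (b_n / (a_n - 1)) / post_prec, tolerance = 0.05)
})

test_that("gamma posterior mean approaches OLS under a flat prior", {
  set.seed(7)
  n <- 60
  hyper <- btr_hyper(gamma_prior_scale = 1e8)
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- array(0, dim = c(n, 2, 2))
  y <- 1 + Z %*% c(2, -1) + rnorm(n, 0, 0.3)
  data <- btreg:::prepare_data(drop(y), X, Z, NULL, hyper)
  grids <- hyper_grids(2, 1)
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$margins$beta[[1]] <- list(c(0, 0), c(0, 0)); st$contrib[] <- 0
  set.seed(8)
  G <- colMeans(t(replicate(5000, update_gamma_sigma(st, data, hyper)$gamma)))
  ols <- drop(solve(crossprod(data$Z), crossprod(data$Z, data$y)))
  expect_equal(G, ols, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("eta update matches the Bayesian ridge closed form", {
  set.seed(9)
  n <- 30; q <- 3
  hyper <- btr_hyper()
  Z1 <- matrix(rnorm(n * q), n, q)
  X <- array(0, dim = c(n, 2, 2))
  y <- drop(Z1 %*% c(1, -1, 0.5)) + rnorm(n, 0, 0.5)
  data <- btreg:::prepare_data(y, X, NULL, Z1, hyper)
  grids <- hyper_grids(2, 1)
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$margins$beta[[1]] <- list(c(0, 0), c(0, 0)); st$contrib[] <- 0
  st$gamma <- 0; st$sigma2 <- 0.25
  st$lam_diag <- rep(1e-8, q); st$lam_off <- matrix(0, q, q)  # Lambda ~ I
  st$m <- 2.5
  set.seed(10)
  E <- t(replicate(3e4, update_eta(st, data)$eta))
  ridge_prec <- crossprod(Z1) + 2.5 * assemble_laplacian(st$lam_diag, st$lam_off)
  mu <- drop(solve(ridge_prec, crossprod(Z1, y)))
  expect_equal(colMeans(E), mu, tolerance = 0.02)
  expect_equal(stats::cov(E), 0.25 * solve(ridge_prec), tolerance = 0.05)
  # m -> infinity shrinks eta to zero
  st$m <- 1e8
  set.seed(11)
  E2 <- t(replicate(500, update_eta(st, data)$eta))
  expect_lt(max(abs(E2)), 0.02)
})

test_that("lambda element conditionals match grid quadrature", {
  set.seed(12)
  q <- 2
  hyper <- btr_hyper(a_gl = 1.4, b_gl = 1.1)
  data <- tiny_data(n = 10, q = q, hyper = hyper)
  grids <- hyper_grids(2, 1)
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$eta <- c(0.8, -0.4); st$sigma2 <- 0.6; st$m <- 1.7
  S <- 3e4
  ld <- numeric(S); lo <- numeric(S)
  for (i in seq_len(S)) {
    st <- update_lambda(st, data)
    ld[i] <- st$lam_diag[1]; lo[i] <- st$lam_off[1, 2]
  }
  a <- 1.4; b <- 1.1; m <- 1.7; s2 <- 0.6; eta <- c(0.8, -0.4)
  cdf_d <- quad_cdf(function(t) -1.5 * log(t) - a^2 / (2 * t) - m * eta[1]^2 * t / (2 * s2))
  expect_gt(stats::ks.test(ld, cdf_d)$p.value, 0.01)
  # signed off-diagonal: two-sided CDF by quadrature
  lk <- function(t) ifelse(t == 0, -Inf,
    -1.5 * log(abs(t)) - b^2 / (2 * abs(t)) -
      m * ((eta[1]^2 + eta[2]^2) * abs(t) + 2 * eta[1] * eta[2] * t) / (2 * s2))
  M <- max(lk(seq(-10, 10, length.out = 2001)), na.rm = TRUE)
  Z <- stats::integrate(function(t) exp(lk(t) - M), -Inf, 0)$value +
    stats::integrate(function(t) exp(lk(t) - M), 0, Inf)$value
  cdf_o <- function(qv) vapply(qv, function(u) {
    if (u <= 0) stats::integrate(function(t) exp(lk(t) - M), -Inf, u)$value / Z
    else (stats::integrate(function(t) exp(lk(t) - M), -Inf, 0)$value +
            stats::integrate(function(t) exp(lk(t) - M), 0, u)$value) / Z
  }, numeric(1))
  expect_gt(stats::ks.test(lo, cdf_o)$p.value, 0.01)
})

test_that("m, a, b conditionals match their stated laws", {
  set.seed(13)
  q <- 3
  hyper <- btr_hyper(h_m = 0.7, g_a = 0.3, g_b = 0.2)
  data <- tiny_data(n = 12, q = q, hyper = hyper)
  grids <- hyper_grids(2, 1)
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$eta <- c(0.5, -0.2, 0.3); st$sigma2 <- 0.9
  st$lam_diag <- c(0.8, 1.2, 0.5)
  st$lam_off <- matrix(0, q, q)
  st$lam_off[upper.tri(st$lam_off)] <- c(0.4, -0.3, 0.6)
  st$lam_off <- st$lam_off + t(st$lam_off) - diag(diag(st$lam_off))
  diag(st$lam_off) <- 0
  L <- assemble_laplacian(st$lam_diag, st$lam_off)
  quad <- drop(st$eta %*% L %*% st$eta)
  S <- 3e4
  out <- matrix(NA_real_, S, 3)
  for (i in seq_len(S)) {
    st2 <- update_m_a_b(st, data, hyper, update_ab = TRUE)
    out[i, ] <- c(st2$m, st2$a_gl, st2$b_gl)
  }
  # m | eta ~ Ga(h_m + q/2, h_m + quad/(2 sigma^2))
  sh <- 0.7 + q / 2; rt <- 0.7 + quad / (2 * 0.9)
  expect_gt(suppressWarnings(
    stats::ks.test(out[, 1], stats::pgamma, shape = sh, rate = rt)$p.value), 0.01)
  # a | lambda: positive-truncated normal driven by sum 1/lambda_ii
  Sa <- sum(1 / st$lam_diag)
  cdf_a <- quad_cdf(function(t) -0.3 * t - t^2 / 2 * Sa, upper_hint = 5)
  expect_gt(suppressWarnings(stats::ks.test(out[, 2], cdf_a)$p.value), 0.01)
  Sb <- sum(1 / abs(st$lam_off[upper.tri(st$lam_off)]))
  cdf_b <- quad_cdf(function(t) -0.2 * t - t^2 / 2 * Sb, upper_hint = 5)
  expect_gt(suppressWarnings(stats::ks.test(out[, 3], cdf_b)$p.value), 0.01)
})

test_that("component-scale update matches quadrature and keeps Phi on the simplex", {
  set.seed(14)
  data <- tiny_data(n = 8, p_dims = c(2, 2), q = 0, p_demo = 0)
  grids <- hyper_grids(2, 1)
  hyper <- btr_hyper()
  st <- btreg:::gibbs_init(data, 1, grids, hyper)
  st$margins$beta[[1]] <- list(c(0.6, -0.3), c(0.2, 0.5))
  st$w <- list(list(c(0.8, 1.2), c(0.5, 1.5)))
  C <- sum(c(0.6, -0.3)^2 / c(0.8, 1.2)) + sum(c(0.2, 0.5)^2 / c(0.5, 1.5))
  S <- 3e4
  taus <- numeric(S); phi_dev <- 0
  for (i in seq_len(S)) {
    st2 <- update_alpha_phi_tau(st, grids, data$dims)
    taus[i] <- st2$tau
    phi_dev <- max(phi_dev, abs(sum(st2$phi) - 1))
  }
  expect_lt(phi_dev, 1e-12)
  # R = 1: alpha is pinned at 1, b_tau = 1; tau ~ giG(1 - 2, 2, C)
  cdf <- quad_cdf(function(t) (1 - 2 - 1) * log(t) - (2 * t + C / t) / 2)
  expect_gt(stats::ks.test(taus, cdf)$p.value, 0.01)
})

test_that("near-zero margins drive the component scales toward zero", {
  set.seed(15)
  data <- tiny_data(n = 8, p_dims = c(2, 2), q = 0, p_demo = 0)
  grids <- hyper_grids(2, 2)
  st <- btreg:::gibbs_init(data, 2, grids, btr_hyper())
  st$margins$beta <- replicate(2, list(list(c(1e-6, -1e-6), c(1e-6, 1e-6)))[[1]],
                               simplify = FALSE)
  st$w <- replicate(2, list(list(rep(1, 2), rep(1, 2)))[[1]], simplify = FALSE)
  taus <- replicate(2000, update_alpha_phi_tau(st, grids, data$dims)$tau)
  expect_lt(stats::median(taus), 1e-3)
})
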