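test_that("assemble_laplacian follows the stated structure and is SPD", {
  expect_equal(assemble_laplacian(c(1, 1), matrix(0, 2, 2)), diag(2, 2))
  off <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  expect_equal(assemble_laplacian(c(0.5, 0.5), off),
               matrix(c(2, -0.5, -0.5, 2), 2, 2))
  expect_error(assemble_laplacian(c(0, 1), matrix(0, 2, 2)), "positive")
  set.seed(1)
  for (i in 1:200) {
    q <- 10
    ld <- rexp(q) + 1e-3
    off <- matrix(0, q, q)
    off[upper.tri(off)] <- rnorm(q * (q - 1) / 2)
    off <- off + t(off)
    L <- assemble_laplacian(ld, off)
    expect_true(isSymmetric(L))
    expect_gt(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("gl_log_prior_eta is a correctly normalized Gaussian", {
  L <- assemble_laplacian(c(0.7, 1.3), matrix(c(0, -0.4, -0.4, 0), 2, 2))
  m <- 1.7; s2 <- 0.8
  # mode value
  expect_equal(gl_log_prior_eta(c(0, 0), s2, L, m),
               -log(2 * pi) + 0.5 * determinant(m * L / s2, TRUE)$modulus[1])
  # integrates to one over a grid (q = 2)
  g <- seq(-12, 12, length.out = 401)
  h <- g[2] - g[1]
  dens <- outer(g, g, Vectorize(function(a, b) exp(gl_log_prior_eta(c(a, b), s2, L, m))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 0.02)
  # doubling m: closed-form change in the log density
  e <- c(0.3, -0.5)
  delta <- gl_log_prior_eta(e, s2, L, 2 * m) - gl_log_prior_eta(e, s2, L, m)
  expect_equal(delta, (2 / 2) * log(2) - (m / (2 * s2)) * drop(e %*% L %*% e),
               tolerance = 1e-10)
  # q = 1 reduces to a scalar normal
  expect_equal(gl_log_prior_eta(0.4, s2, matrix(2.5), m),
               stats::dnorm(0.4, 0, sqrt(s2 / (m * 2.5)), log = TRUE))
  expect_error(gl_log_prior_eta(c(0, 0), s2, L, 0), "m must be")
})

test_that("gl_log_prior_lambda matches term-by-term hand evaluation", {
  a <- 1.3; b <- 0.9
  ld <- c(1, 1); off <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  L <- assemble_laplacian(ld, off)
  hand <- -0.5 * log(det(L)) - 2 * (1.5 * log(1) + a^2 / 2) +
    (-1.5 * log(0.5) - b^2 / (2 * 0.5))
  expect_equal(as.numeric(gl_log_prior_lambda(ld, off, a, b)), hand, tolerance = 1e-12)
  # permutation symmetry
  set.seed(2)
  q <- 4
  ld4 <- rexp(q) + 0.1
  off4 <- matrix(0, q, q); off4[upper.tri(off4)] <- rnorm(6); off4 <- off4 + t(off4)
  perm <- c(3, 1, 4, 2)
  expect_equal(as.numeric(gl_log_prior_lambda(ld4, off4, a, b)),
               as.numeric(gl_log_prior_lambda(ld4[perm], off4[perm, perm], a, b)),
               tolerance = 1e-10)
  # quadratic penalty scaling in a
  d1 <- gl_log_prior_lambda(ld4, off4, a, b)
  d2 <- gl_log_prior_lambda(ld4, off4, 2 * a, b)
  expect_equal(as.numeric(d1 - d2), (4 * a^2 - a^2) / 2 * sum(1 / ld4), tolerance = 1e-10)
  # zero off-diagonal sits outside the (continuous) support
  expect_equal(as.numeric(gl_log_prior_lambda(c(1, 1), matrix(0, 2, 2), a, b)), -Inf)
  expect_error(gl_log_prior_lambda(c(-1, 1), off, a, b), "positive|> 0")
})

test_that("calibrate_s0 hits the stated tail probability", {
  s0 <- calibrate_s0(nu = 2, prob = 0.95, threshold = 1)
  expect_equal(s0, -log(0.95), tolerance = 1e-10)
  # round trip at other settings
  for (nu in c(2, 5, 11)) {
    s0 <- calibrate_s0(nu, 0.9, 2.5)
    expect_equal(btreg:::pinvgamma_sigma2(2.5, nu, s0), 0.9, tolerance = 1e-10)
  }
  # monotone decreasing in prob; prob -> 1 gives s0 -> 0
  s <- sapply(c(0.5, 0.8, 0.95, 0.999), function(p) calibrate_s0(2, p, 1))
  expect_true(all(diff(s) < 0))
  expect_lt(s[4], 2e-3)
})

test_that("hyper_grids spans the documented intervals with 10 points", {
  g <- hyper_grids(D = 2, R = 2)
  expect_length(g$alpha, 10)
  expect_length(g$a_lambda, 10)
  expect_equal(g$alpha[1], 0.25)
  expect_equal(g$alpha[10], 2^(-0.1))
  expect_equal(diff(g$alpha), rep((2^(-0.1) - 0.25) / 9, 9))
  expect_equal(range(g$a_lambda), c(2, 3))
  expect_equal(hyper_grids(2, 1)$alpha, rep(1, 10))
  expect_equal(g$b_lambda(2), 2^(1 / 4))
})

test_that("mdgdp prior draws have the double-exponential margin law", {
  dims <- tensor_dims(c(40, 40))
  set.seed(3)
  pr <- mdgdp_sample_prior(dims, R = 2, alpha = 0.7, a_lambda = 2.5, b_lambda = 1.2)
  expect_equal(sum(pr$state$phi), 1, tolerance = 1e-12)
  # conditional variance identity var(beta | phi, tau, W) = phi_r tau w
  set.seed(4)
  tau_r <- 1.3; w <- 0.8; s <- 2
  bb <- rnorm(2e5, 0, sqrt(tau_r * w))
  expect_equal(stats::var(bb), tau_r * w, tolerance = 0.02)
  # marginal over w: double exponential with rate s / sqrt(phi_r tau)
  set.seed(5)
  ws <- rexp(2e5, rate = s^2 / 2)
  beta <- rnorm(2e5, 0, sqrt(tau_r * ws))
  laplace_cdf <- function(q) ifelse(q < 0, 0.5 * exp(q * s / sqrt(tau_r)),
                                    1 - 0.5 * exp(-q * s / sqrt(tau_r)))
  expect_gt(stats::ks.test(beta, laplace_cdf)$p.value, 0.01)
  # seeded reproducibility
  set.seed(9); p1 <- mdgdp_sample_prior(dims, 2, 0.7, 2.5, 1.2)
  set.seed(9); p2 <- mdgdp_sample_prior(dims, 2, 0.7, 2.5, 1.2)
  expect_identical(p1, p2)
})
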