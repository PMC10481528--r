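make_fake_draws <- function(gamma, sigma2, y, eta = NULL, B = NULL, loglik = NULL) {
  S <- length(sigma2)
  if (is.null(loglik)) {
    loglik <- vapply(seq_len(S), function(s)
      sum(stats::dnorm(y, gamma[s, 1], sqrt(sigma2[s]), log = TRUE)), numeric(1))
  }
  structure(list(
    draws = list(gamma = gamma, eta = eta %||% matrix(NA_real_, S, 0),
                 sigma2 = sigma2, tau = rep(1, S),
                 phi = matrix(1, S, 1), alpha = rep(1, S),
                 a_lambda = rep(2, S), m = rep(1, S),
                 a_gl = rep(1, S), b_gl = rep(1, S),
                 B = B, loglik = loglik),
    dims = tensor_dims(c(2, 2)), rank = 1, mask = array(TRUE, c(2, 2)),
    n = length(y), p = 0, q = ncol(eta %||% matrix(0, 1, 0)),
    config = btr_config(n_iter = 2, burn_in = 1), hyper = btr_hyper(), y = y),
    class = "btr_draws")
}
`%||%` <- btreg:::`%||%`

test_that("rrmse matches its defining examples and invariances", {
  expect_equal(rrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  obs <- c(4, 7, 1, 3)
  expect_equal(rrmse(rep(mean(obs), 4), obs), 1)
  expect_equal(rrmse(c(1, 2, 6), c(1, 2, 3)), sqrt(4.5), tolerance = 1e-12)
  set.seed(1)
  th <- rnorm(50); hat <- th + rnorm(50, 0, 0.3)
  expect_equal(rrmse(3 * hat - 2, 3 * th - 2), rrmse(hat, th), tolerance = 1e-12)
  expect_error(rrmse(c(1, 2), c(5, 5)), "constant")
})

test_that("DIC is the plug-in deviance for a degenerate chain", {
  set.seed(2)
  y <- rnorm(20, 1, 0.5)
  S <- 50
  gm <- matrix(1, S, 1); colnames(gm) <- "(Intercept)"
  fd <- make_fake_draws(gm, rep(0.25, S), y)
  dic <- compute_dic(fd, y, array(0, c(20, 2, 2)))
  expect_equal(dic$p_d, 0, tolerance = 1e-10)
  expect_equal(dic$dic, -2 * sum(stats::dnorm(y, 1, 0.5, log = TRUE)), tolerance = 1e-10)
})

test_that("DIC effective parameter count matches the conjugate normal-mean oracle", {
  # known-variance normal mean with near-flat prior: p_D ~ 1
  set.seed(3)
  n <- 50; sig <- 0.8
  y <- rnorm(n, 2, sig)
  post_var <- sig^2 / n
  S <- 20000
  theta <- rnorm(S, mean(y), sqrt(post_var))
  gm <- matrix(theta, S, 1); colnames(gm) <- "(Intercept)"
  fd <- make_fake_draws(gm, rep(sig^2, S), y)
  dic <- compute_dic(fd, y, array(0, c(n, 2, 2)))
  expect_equal(dic$p_d, 1, tolerance = 0.05)
  expect_error(compute_dic(make_fake_draws(gm[1:5, , drop = FALSE],
                                           rep(sig^2, 5), y), y,
                           array(0, c(n, 2, 2))), "10 stored")
})

test_that("select_rank returns the grid argmin and full trace", {
  sc <- sim_scenario(n = 40, p_dims = c(4, 4), rank = 1, q = 0, seed = 4)
  d <- simulate_dataset(sc)
  sel <- select_rank(d$y, d$X, d$Z, NULL, rank_grid = 1,
                     config = btr_config(n_iter = 200, burn_in = 80, seed = 5))
  expect_equal(sel$best_rank, 1)
  expect_equal(nrow(sel$dic_table), 1)
})

test_that("credible-interval flags and cross-model aggregation behave", {
  S <- 500
  eta <- cbind(geneA = rnorm(S, 2, 0.1), geneB = rnorm(S, 0, 1))
  fd <- make_fake_draws(matrix(0, S, 1, dimnames = list(NULL, "(Intercept)")),
                        rep(1, S), rnorm(5), eta = eta)
  fl <- flag_significant(fd, level = 0.95)
  expect_true(fl$flagged[fl$gene == "geneA"])
  expect_false(fl$flagged[fl$gene == "geneB"])
  # all-positive draws are flagged at any level
  eta_pos <- cbind(geneA = rexp(S) + 0.01, geneB = rnorm(S))
  fd2 <- make_fake_draws(matrix(0, S, 1, dimnames = list(NULL, "(Intercept)")),
                         rep(1, S), rnorm(5), eta = eta_pos)
  expect_true(flag_significant(fd2, 0.999)$flagged[1])
  # 20 flags out of 30 models -> 66.67 percent
  flags <- lapply(1:30, function(i)
    tibble::tibble(gene = "ARL5B", flagged = i <= 20))
  tab <- significance_table(flags)
  expect_equal(tab$frequency, 20)
  expect_equal(tab$percentage, 100 * 20 / 30, tolerance = 1e-10)
})

test_that("adf screening separates stationary from random-walk chains", {
  set.seed(61)
  wn <- rnorm(600)
  rw <- cumsum(rnorm(600))
  expect_lt(adf_test(wn)$p_value, 0.05)
  expect_gt(adf_test(rw)$p_value, 0.1)
  S <- 300
  gm <- cbind(`(Intercept)` = rnorm(S), demo1 = cumsum(rnorm(S)))
  fd <- make_fake_draws(gm, abs(rnorm(S)) + 0.5, rnorm(5))
  rep_tab <- check_convergence(fd)
  expect_true(all(c("(Intercept)", "demo1", "sigma2", "tau") %in% rep_tab$parameter))
  expect_true(rep_tab$stationary[rep_tab$parameter == "(Intercept)"])
  expect_false(rep_tab$stationary[rep_tab$parameter == "demo1"])
})

test_that("prediction is the plug-in posterior-mean linear rule", {
  sc <- sim_scenario(n = 40, p_dims = c(4, 4), rank = 1, q = 3, seed = 7)
  d <- simulate_dataset(sc)
  fit <- btr(d$y, d$X, d$Z, d$Z1, rank = 1,
             config = btr_config(n_iter = 300, burn_in = 100, seed = 8))
  n_new <- 4
  X0 <- array(0, dim = c(n_new, 4, 4))
  Z0 <- matrix(0, n_new, ncol(d$Z)); Z10 <- matrix(0, n_new, 3)
  expect_equal(predict(fit, X0, Z0, Z10), rep(fit$intercept, n_new))
  # linearity in the image block
  Xa <- array(rnorm(n_new * 16), dim = c(n_new, 4, 4))
  p1 <- predict(fit, Xa, Z0, Z10)
  p2 <- predict(fit, 2 * Xa, Z0, Z10)
  expect_equal(p2 - p1, drop(btreg:::stack_matrix(Xa) %*% as.vector(fit$B)),
               tolerance = 1e-10)
  expect_error(predict(fit, array(0, c(2, 5, 5)), Z0, Z10), "grid")
})

test_that("tidy and glance summarize a fit", {
  sc <- sim_scenario(n = 30, p_dims = c(3, 3), rank = 1, q = 2, seed = 9)
  d <- simulate_dataset(sc)
  fit <- btr(d$y, d$X, d$Z, d$Z1, rank = 1,
             config = btr_config(n_iter = 150, burn_in = 50, seed = 10))
  td <- tidy(fit)
  expect_setequal(unique(td$type), c("intercept", "demographic", "gene"))
  expect_true(all(td$lower <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_equal(gl$rank, 1)
  expect_true(is.finite(gl$dic))
})
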