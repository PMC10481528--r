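#' Relative root mean squared error
#'
#' `RRMSE = sqrt(mean((pred - obs)^2)) / sqrt(mean((obs - mean(obs))^2))`:
#' prediction RMSE normalized by the standard deviation of the observed
#' values, so a mean-only null predictor scores exactly 1 and values above 1
#' indicate performance worse than the null model.
#'
#' @param pred Predicted values.
#' @param obs Observed values (length >= 2, not constant).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' rrmse(c(1, 2, 6), c(1, 2, 3))   # sqrt(4.5)
rrmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  denom <- sqrt(mean((obs - mean(obs))^2))
  if (denom == 0) stop("rrmse undefined for a constant observed vector", call. = FALSE)
  sqrt(mean((pred - obs)^2)) / denom
}

#' Deviance information criterion of a fitted chain
#'
#' `DIC = Dbar + p_D` with `Dbar` the posterior mean deviance (`-2 log lik`)
#' and `p_D = Dbar - D(posterior means)` (the Spiegelhalter effective
#' parameter count). The plug-in deviance is evaluated at the posterior means
#' of the intercept, `gamma`, `eta`, the composed tensor and `sigma^2`.
#'
#' @param object A `"btr_draws"` object from [run_mcmc()] (with stored `B`),
#'   or a `"btr_fit"`.
#' @param y,X,Z,Z1 The training data (defaulting to what the fit stored,
#'   where available).
#' @return List with `dic`, `p_d`, `mean_deviance`.
#' @export
compute_dic <- function(object, y, X, Z = NULL, Z1 = NULL) {
  draws <- if (inherits(object, "btr_fit")) object$samples$draws else object$draws
  if (length(draws$loglik) < 10) stop("need at least 10 stored draws for DIC", call. = FALSE)
  dbar <- mean(-2 * draws$loglik)
  n <- length(y)
  Zi <- cbind(1, if (is.null(Z)) matrix(0, n, 0) else as.matrix(Z))
  fitted <- drop(Zi %*% colMeans(draws$gamma))
  if (ncol(draws$eta) > 0)
    fitted <- fitted + drop(as.matrix(Z1) %*% colMeans(draws$eta))
  if (!is.null(draws$B)) {
    Bbar <- colMeans(draws$B)
    fitted <- fitted + drop(stack_matrix(X) %*% Bbar)
  }
  s2bar <- mean(draws$sigma2)
  dhat <- -2 * sum(stats::dnorm(y, fitted, sqrt(s2bar), log = TRUE))
  p_d <- dbar - dhat
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

#' Select the tensor rank by DIC
#'
#' Fits the model at each rank in `rank_grid` and returns the DIC-minimizing
#' rank together with the full DIC trace.
#'
#' @inheritParams run_mcmc
#' @param rank_grid Nonempty integer vector of candidate ranks.
#' @return List with `best_rank` and a tibble `dic_table` (columns `rank`,
#'   `dic`, `p_d`).
#' @export
select_rank <- function(y, X, Z = NULL, Z1 = NULL, rank_grid = 1:3,
                        config = btr_config(), hyper = btr_hyper()) {
  stopifnot(length(rank_grid) >= 1)
  rows <- purrr::map(rank_grid, function(r) {
    res <- tryCatch({
      cfg <- config
      if (!is.null(config$seed)) cfg$seed <- config$seed + r
      d <- run_mcmc(y, X, Z = Z, Z1 = Z1, rank = r, config = cfg, hyper = hyper)
      dic_res <- compute_dic(d, y, X, Z, Z1)
      tibble::tibble(rank = r, dic = dic_res$dic, p_d = dic_res$p_d)
    }, error = function(e) {
      warning("rank ", r, " failed: ", conditionMessage(e), call. = FALSE)
      tibble::tibble(rank = r, dic = NA_real_, p_d = NA_real_)
    })
    res
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(!is.na(tab$dic))
  if (length(ok) == 0) stop("every candidate rank failed", call. = FALSE)
  list(best_rank = tab$rank[ok[which.min(tab$dic[ok])]], dic_table = tab)
}

#' Flag genes whose credible interval excludes zero
#'
#' A gene is flagged when its equal-tailed posterior credible interval at
#' `level` excludes 0. Given several fits (e.g. across image slices and
#' visits), [significance_table()] aggregates flags into frequencies and
#' percentages.
#'
#' @param object A `"btr_draws"` or `"btr_fit"` with gene draws.
#' @param level Credible level in (0, 1), default 0.95.
#' @return Tibble with columns `gene`, `estimate`, `lower`, `upper`, `flagged`.
#' @export
flag_significant <- function(object, level = 0.95) {
  stopifnot(level > 0, level < 1)
  draws <- if (inherits(object, "btr_fit")) object$samples$draws else object$draws
  eta <- draws$eta
  if (ncol(eta) == 0) return(tibble::tibble(gene = character(0), estimate = numeric(0),
                                            lower = numeric(0), upper = numeric(0),
                                            flagged = logical(0)))
  al <- (1 - level) / 2
  qs <- apply(eta, 2, stats::quantile, probs = c(al, 1 - al))
  tibble::tibble(gene = colnames(eta) %||% paste0("gene", seq_len(ncol(eta))),
                 estimate = colMeans(eta),
                 lower = qs[1, ], upper = qs[2, ],
                 flagged = qs[1, ] > 0 | qs[2, ] < 0)
}

#' Aggregate significance flags across models
#'
#' @param flag_list List of tibbles from [flag_significant()], one per fitted
#'   model (same genes in each).
#' @return Tibble `gene`, `frequency`, `model_count`, `percentage`
#'   (= `100 * frequency / model_count`), sorted by decreasing frequency.
#' @export
significance_table <- function(flag_list) {
  stopifnot(length(flag_list) >= 1)
  dplyr::bind_rows(flag_list) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(frequency = sum(.data$flagged),
                     model_count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percentage = 100 * .data$frequency / .data$model_count) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' Stationarity screening of the stored chains
#'
#' Applies the augmented Dickey-Fuller unit-root test to every monitored
#' scalar chain (demographic coefficients, gene coefficients, `sigma^2`,
#' `tau`, and a subsample of tensor voxels); a chain passes when the unit
#' root is rejected at `alpha`.
#'
#' @param object A `"btr_draws"` or `"btr_fit"`.
#' @param alpha Test level (default 0.05).
#' @param max_voxels Number of (highest-variance) tensor-voxel chains tested.
#' @return Tibble `parameter`, `statistic`, `p_value`, `stationary`.
#' @export
check_convergence <- function(object, alpha = 0.05, max_voxels = 10) {
  draws <- if (inherits(object, "btr_fit")) object$samples$draws else object$draws
  if (length(draws$sigma2) < 100)
    stop("need at least 100 stored draws for stationarity screening", call. = FALSE)
  chains <- list()
  for (k in seq_len(ncol(draws$gamma)))
    chains[[colnames(draws$gamma)[k] %||% paste0("gamma", k)]] <- draws$gamma[, k]
  if (ncol(draws$eta) > 0)
    for (k in seq_len(ncol(draws$eta)))
      chains[[colnames(draws$eta)[k]]] <- draws$eta[, k]
  chains$sigma2 <- draws$sigma2
  chains$tau <- draws$tau
  if (!is.null(draws$B)) {
    v <- apply(draws$B, 2, stats::var)
    top <- order(v, decreasing = TRUE)[seq_len(min(max_voxels, length(v)))]
    for (k in top) chains[[paste0("B_voxel", k)]] <- draws$B[, k]
  }
  purrr::imap(chains, function(x, nm) {
    if (stats::var(x) == 0) {
      tibble::tibble(parameter = nm, statistic = NA_real_, p_value = NA_real_,
                     stationary = NA)
    } else {
      a <- adf_test(x)
      tibble::tibble(parameter = nm, statistic = a$statistic, p_value = a$p_value,
                     stationary = a$p_value < alpha)
    }
  }) |> dplyr::bind_rows()
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the differenced series on its lagged level, a constant, and
#' `lags` lagged differences; the t-statistic on the lagged level is compared
#' to the Dickey-Fuller tau_mu distribution (constant, no trend) by two-way
#' interpolation of the published finite-sample table. P-values are clamped
#' to [0.01, 0.99].
#'
#' @param x Numeric series (length >= 20).
#' @param lags Number of lagged differences; default `trunc((n - 1)^(1/3))`.
#' @return List with `statistic`, `p_value`, `lags`.
#' @export
adf_test <- function(x, lags = trunc((length(x) - 1)^(1 / 3))) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 20, lags >= 0)
  dx <- diff(x)
  k <- lags + 1L
  nobs <- length(dx) - lags
  yt <- dx[k:length(dx)]
  xlag <- x[k:(length(dx))]
  X <- cbind(1, xlag)
  if (lags > 0) {
    lagged <- sapply(seq_len(lags), function(l) dx[(k - l):(length(dx) - l)])
    X <- cbind(X, lagged)
  }
  fit <- stats::lm.fit(X, yt)
  res <- fit$residuals
  s2 <- sum(res^2) / (nobs - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
  # Dickey-Fuller tau_mu table (constant, no trend): rows by sample size
  tbl_n <- c(25, 50, 100, 250, 500, 1e5)
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  tbl <- rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))
  crit <- sapply(seq_along(probs), function(j)
    stats::approx(tbl_n, tbl[, j], xout = min(max(nobs, 25), 1e5), rule = 2)$y)
  p <- stats::approx(crit, probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = min(max(p, 0.01), 0.99), lags = lags)
}
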