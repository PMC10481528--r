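#' Fit the integrative Bayesian tensor regression model
#'
#' The model is
#' `y_i = alpha + z_i' gamma + z1_i' eta + <X_i, B> + eps_i`,
#' `eps_i ~ N(0, sigma^2)`, with a rank-`R` PARAFAC coefficient tensor `B`
#' under the multiway Dirichlet generalized double Pareto shrinkage prior and
#' a graph-Laplacian prior on the gene coefficients `eta`. The response is
#' centred and scaled internally (matching the noise-variance calibration,
#' which assumes a standardized response); all reported draws are
#' back-transformed to the original scale.
#'
#' @param y Length-`n` response vector.
#' @param X `n x p_1 x ... x p_D` image stack; voxels that are zero in every
#'   subject are screened out of estimation and reported as exact zeros.
#' @param Z Optional demographic matrix / data frame (`n x p`).
#' @param Z1 Optional gene-expression matrix / data frame (`n x q`).
#' @param rank PARAFAC rank.
#' @param config A [btr_config()].
#' @param hyper A [btr_hyper()].
#' @param scale_y Centre and scale the response internally (default `TRUE`).
#' @return An object of class `"btr_fit"` with posterior means
#'   (`intercept`, `gamma`, `eta`, `B`), `ci` tibbles, the raw `samples`
#'   (a `"btr_draws"` on the original response scale), `dic`, and call info.
#' @export
#' @examples
#' sc <- sim_scenario(n = 40, p_dims = c(6, 6), rank = 1, q = 4, seed = 1)
#' d <- simulate_dataset(sc)
#' fit <- btr(d$y, d$X, d$Z, d$Z1, rank = 1,
#'            config = btr_config(n_iter = 200, burn_in = 100, seed = 1))
#' glance(fit)
btr <- function(y, X, Z = NULL, Z1 = NULL, rank = 1,
                config = btr_config(), hyper = btr_hyper(), scale_y = TRUE) {
  y <- as.numeric(y)
  mu_y <- if (scale_y) mean(y) else 0
  sd_y <- if (scale_y) stats::sd(y) else 1
  if (scale_y && sd_y == 0) stop("response is constant; cannot scale", call. = FALSE)
  ys <- (y - mu_y) / sd_y
  Zm <- if (is.null(Z)) NULL else as.matrix(Z)
  Z1m <- if (is.null(Z1)) NULL else as.matrix(Z1)
  samples <- run_mcmc(ys, X, Zm, Z1m, rank = rank, config = config, hyper = hyper)
  # back-transform draws to the original response scale
  d <- samples$draws
  d$gamma <- d$gamma * sd_y
  d$gamma[, 1] <- d$gamma[, 1] + mu_y
  if (ncol(d$eta) > 0) d$eta <- d$eta * sd_y
  if (!is.null(d$B)) d$B <- d$B * sd_y
  d$sigma2 <- d$sigma2 * sd_y^2
  # refresh log-likelihood on the original scale (shift/scale of a normal)
  d$loglik <- d$loglik - length(y) * log(sd_y)
  samples$draws <- d
  samples$y <- y
  Bbar <- if (!is.null(d$B)) array(colMeans(d$B), dim = samples$dims$p) else NULL
  qfun <- function(mat) {
    qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975))
    tibble::tibble(term = colnames(mat) %||% paste0("V", seq_len(ncol(mat))),
                   estimate = colMeans(mat), lower = qs[1, ], upper = qs[2, ])
  }
  fit <- structure(list(
    intercept = mean(d$gamma[, 1]),
    gamma = if (ncol(d$gamma) > 1) colMeans(d$gamma[, -1, drop = FALSE]) else numeric(0),
    eta = if (ncol(d$eta) > 0) colMeans(d$eta) else numeric(0),
    B = Bbar,
    ci_gamma = qfun(d$gamma),
    ci_eta = if (ncol(d$eta) > 0) qfun(d$eta) else NULL,
    samples = samples, rank = rank, dims = samples$dims,
    mask = samples$mask, scale = list(mu_y = mu_y, sd_y = sd_y),
    n = samples$n), class = "btr_fit")
  fit$dic <- compute_dic(fit, y, X, Zm, Z1m)$dic
  fit
}

#' @export
print.btr_fit <- function(x, ...) {
  cat(sprintf("Integrative Bayesian tensor regression fit\n"))
  cat(sprintf("  image grid: %s   rank: %d   n = %d\n",
              paste(x$dims$p, collapse = " x "), x$rank, x$n))
  cat(sprintf("  demographics: %d   genes: %d\n", length(x$gamma), length(x$eta)))
  cat(sprintf("  DIC: %.2f   stored draws: %d\n", x$dic,
              length(x$samples$draws$sigma2)))
  invisible(x)
}

#' Predict from a fitted tensor regression
#'
#' Plug-in posterior-mean prediction
#' `yhat = alpha + Z gamma + Z1 eta + <X, B>`.
#'
#' @param object A `"btr_fit"`.
#' @param X New image stack (same grid as training).
#' @param Z,Z1 New covariate matrices (same columns as training).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.btr_fit <- function(object, X, Z = NULL, Z1 = NULL, ...) {
  d <- dim(X)
  if (length(d) != object$dims$D + 1L ||
      !identical(as.integer(d[-1L]), object$dims$p))
    stop("new image stack does not match the training grid", call. = FALSE)
  n <- d[1L]
  yhat <- rep(object$intercept, n)
  if (length(object$gamma) > 0) {
    Zm <- as.matrix(Z)
    if (is.null(Z) || ncol(Zm) != length(object$gamma))
      stop("Z must have the training demographic columns", call. = FALSE)
    yhat <- yhat + drop(Zm %*% object$gamma)
  }
  if (length(object$eta) > 0) {
    Z1m <- as.matrix(Z1)
    if (is.null(Z1) || ncol(Z1m) != length(object$eta))
      stop("Z1 must have the training gene columns", call. = FALSE)
    yhat <- yhat + drop(Z1m %*% object$eta)
  }
  if (!is.null(object$B)) yhat <- yhat + drop(stack_matrix(X) %*% as.vector(object$B))
  yhat
}

#' Tidy the posterior summaries of a tensor regression fit
#'
#' One row per scalar coefficient (intercept, demographics, genes) with the
#' posterior mean and equal-tailed 95% credible bounds; tensor voxels are
#' summarized separately through the fitted `B` array.
#'
#' @param x A `"btr_fit"`.
#' @param ... Unused.
#' @return A tibble `term`, `type`, `estimate`, `lower`, `upper`, `flagged`.
#' @exportS3Method generics::tidy
tidy.btr_fit <- function(x, ...) {
  g <- dplyr::mutate(x$ci_gamma,
                     type = ifelse(.data$term == "(Intercept)", "intercept", "demographic"))
  out <- g
  if (!is.null(x$ci_eta))
    out <- dplyr::bind_rows(out, dplyr::mutate(x$ci_eta, type = "gene"))
  dplyr::mutate(out, flagged = .data$lower > 0 | .data$upper < 0) |>
    dplyr::select("term", "type", "estimate", "lower", "upper", "flagged")
}

#' One-row model summary
#'
#' @param x A `"btr_fit"`.
#' @param ... Unused.
#' @return Tibble with `rank`, `n`, `n_gene`, `n_demo`, `dic`, `sigma2`,
#'   `n_draws`, `train_rrmse`.
#' @exportS3Method generics::glance
glance.btr_fit <- function(x, ...) {
  tibble::tibble(rank = x$rank, n = x$n, n_gene = length(x$eta),
                 n_demo = length(x$gamma), dic = x$dic,
                 sigma2 = mean(x$samples$draws$sigma2),
                 n_draws = length(x$samples$draws$sigma2))
}

#' Posterior draws as a wide per-draw table
#'
#' One row per stored draw, one column per monitored scalar (demographic and
#' gene coefficients, `sigma2`, `tau`, `alpha`, `a_lambda`, `m`, log
#' likelihood); the format the command-line `fit` run persists to disk.
#'
#' @param object A `"btr_fit"` or `"btr_draws"`.
#' @return A tibble with a leading `draw` column.
#' @export
draws_table <- function(object) {
  d <- if (inherits(object, "btr_fit")) object$samples$draws else object$draws
  out <- tibble::as_tibble(d$gamma)
  if (ncol(d$eta) > 0) out <- dplyr::bind_cols(out, tibble::as_tibble(d$eta))
  dplyr::bind_cols(tibble::tibble(draw = seq_along(d$sigma2)), out,
                   tibble::tibble(sigma2 = d$sigma2, tau = d$tau,
                                  alpha = d$alpha, a_lambda = d$a_lambda,
                                  m = d$m, loglik = d$loglik))
}

#' Posterior draws as a tidy tibble
#'
#' @param object A `"btr_fit"` or `"btr_draws"`.
#' @param params Which blocks to include.
#' @return Long tibble `draw`, `parameter`, `value`.
#' @export
tidy_draws <- function(object, params = c("gamma", "eta", "sigma2", "tau")) {
  d <- if (inherits(object, "btr_fit")) object$samples$draws else object$draws
  out <- list()
  S <- length(d$sigma2)
  if ("gamma" %in% params)
    out$gamma <- tibble::as_tibble(d$gamma) |>
      dplyr::mutate(draw = seq_len(S)) |>
      tidyr::pivot_longer(-"draw", names_to = "parameter")
  if ("eta" %in% params && ncol(d$eta) > 0)
    out$eta <- tibble::as_tibble(d$eta) |>
      dplyr::mutate(draw = seq_len(S)) |>
      tidyr::pivot_longer(-"draw", names_to = "parameter")
  if ("sigma2" %in% params)
    out$sigma2 <- tibble::tibble(draw = seq_len(S), parameter = "sigma2",
                                 value = d$sigma2)
  if ("tau" %in% params)
    out$tau <- tibble::tibble(draw = seq_len(S), parameter = "tau", value = d$tau)
  dplyr::bind_rows(out)
}
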