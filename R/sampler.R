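#' Chain configuration
#'
#' @param n_iter Total Gibbs sweeps (default 10000).
#' @param burn_in Discarded initial sweeps (default 3000; must be < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed set at the start of the run.
#' @param update_ab Update the graph-Laplacian penalties `a`, `b`. Default
#'   `FALSE`: the joint update of the element penalties with the Laplacian
#'   elements concentrates on a degenerate boundary (the implied joint over
#'   `(a, lambda)` is improper), so by default `a` and `b` stay at their
#'   [btr_hyper()] values and the Laplacian still adapts through `lambda`
#'   and `m`.
#' @param store_B Store the composed coefficient tensor at every kept draw.
#' @param verbose Print progress every 1000 sweeps.
#' @return A list of class `"btr_config"`.
#' @export
btr_config <- function(n_iter = 10000, burn_in = 3000, thin = 1, seed = NULL,
                       update_ab = FALSE, store_B = TRUE, verbose = FALSE) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, update_ab = update_ab,
                 store_B = store_B, verbose = verbose),
            class = "btr_config")
}

# ---- numerically safe log Bessel K ------------------------------------------

log_besselK <- function(x, nu) {
  nu <- abs(nu)
  v <- besselK(x, nu, expon.scaled = TRUE)
  out <- log(v) - x
  bad <- !is.finite(out)
  if (any(bad)) {
    # small-argument asymptote K_nu(x) ~ Gamma(nu)/2 * (2/x)^nu, nu > 0
    out[bad] <- log(0.5) + lgamma(nu) + nu * (log(2) - log(x[bad]))
  }
  out
}

# positive-truncated normal draw, stable in the deep tail
rtruncnorm_pos <- function(mu, sd) {
  alpha <- -mu / sd
  if (alpha < 6) {
    p0 <- stats::pnorm(alpha)
    u <- stats::runif(1, p0, 1)
    z <- stats::qnorm(u)
    if (is.finite(z) && z > alpha) return(mu + sd * z)
  }
  repeat {   # Robert (1995) exponential rejection for the far tail
    z <- alpha + stats::rexp(1, rate = alpha)
    if (stats::runif(1) <= exp(-(z - alpha)^2 / 2)) return(mu + sd * z)
  }
}

# ---- individual full-conditional updates ------------------------------------
# Each update_* function takes the current sampler state and returns the
# refreshed component(s).  `state` is a plain list; see gibbs_init() for the
# fields.  All updates are exact draws from their full conditionals (the
# lambda, a, b and m conditionals are closed-form here because the
# |Lambda|^{1/2} factor from the eta likelihood cancels the |Lambda|^{-1/2}
# in the element-level prior).

#' Update the generalized-double-Pareto rates s_jr
#'
#' `s_jr ~ Ga(a_lambda + p_j, b_lambda + ||beta_j^(r)||_1 / sqrt(phi_r tau))`,
#' the conditional with the local scales `w` integrated out.
#'
#' @param margins Current [tensor_margins()].
#' @param tau_r Component scales `phi_r * tau` (length `R`).
#' @param a_lambda,b_lambda GDP shape and rate.
#' @return `D x R` matrix of new rates.
#' @export
update_s <- function(margins, tau_r, a_lambda, b_lambda) {
  D <- margins$dims$D; R <- margins$R
  s <- matrix(0, D, R)
  for (r in seq_len(R)) for (j in seq_len(D)) {
    l1 <- sum(abs(margins$beta[[r]][[j]]))
    s[j, r] <- stats::rgamma(1, shape = a_lambda + margins$dims$p[j],
                             rate = b_lambda + l1 / sqrt(tau_r[r]))
  }
  s
}

#' Update the local scales w_jrk
#'
#' `w_jrk ~ giG(1/2, s_jr^2, beta_jk^(r)^2 / (phi_r tau))`, elementwise.
#'
#' @inheritParams update_s
#' @param s `D x R` matrix of current GDP rates.
#' @return Nested list `w[[r]][[j]]` of positive vectors.
#' @export
update_w <- function(margins, tau_r, s) {
  D <- margins$dims$D; R <- margins$R
  w <- vector("list", R)
  for (r in seq_len(R)) {
    w[[r]] <- vector("list", D)
    for (j in seq_len(D)) {
      b <- margins$beta[[r]][[j]]^2 / tau_r[r]
      w[[r]][[j]] <- rgig(length(b), 0.5, s[j, r]^2, b)
    }
  }
  w
}

# Gaussian full conditional of one margin vector: mean and covariance.
# ytilde must exclude every model term except component r's own contribution.
margin_conditional <- function(H, ytilde, w_jr, tau_r_val, sigma2) {
  prec <- crossprod(H) / sigma2
  diag(prec) <- diag(prec) + 1 / (tau_r_val * w_jr)
  ch <- tryCatch(chol(prec), error = function(e) {
    chol(prec + diag(1e-8 * max(diag(prec)), nrow(prec)))
  })
  mu <- backsolve(ch, backsolve(ch, crossprod(H, ytilde) / sigma2, transpose = TRUE))
  list(mu = drop(mu), chol_prec = ch)
}

draw_mvn_from_cond <- function(cond) {
  cond$mu + backsolve(cond$chol_prec, stats::rnorm(length(cond$mu)))
}

#' One back-fitting sweep over all tensor margins
#'
#' For each component `r` and mode `j` (in order), refreshes `s_jr`, `w_jr`
#' and then draws `beta_j^(r) ~ N(mu_jr, Sigma_jr)` with
#' `Sigma_jr = (H'H/sigma^2 + W_jr^{-1}/(phi_r tau))^{-1}` against the
#' residual that removes the contribution of every *other* component
#' (back-fitting), so each margin sees `y - Z gamma - Z1 eta - sum_{r' != r} <X, B_r'>`.
#'
#' @param state Sampler state list.
#' @param data Prepared data list (see [run_mcmc()]).
#' @return The state with `margins`, `contrib`, `s`, `w` refreshed.
#' @export
update_margins_block <- function(state, data) {
  R <- state$margins$R; D <- state$margins$dims$D
  base_resid <- data$y - drop(data$Z %*% state$gamma) -
    (if (data$q > 0) drop(data$Z1 %*% state$eta) else 0)
  for (r in seq_len(R)) {
    for (j in seq_len(D)) {
      l1 <- sum(abs(state$margins$beta[[r]][[j]]))
      state$s[j, r] <- stats::rgamma(1, shape = state$a_lambda + data$dims$p[j],
                                     rate = state$b_lambda + l1 / sqrt(state$tau_r[r]))
      bsq <- state$margins$beta[[r]][[j]]^2 / state$tau_r[r]
      state$w[[r]][[j]] <- rgig(length(bsq), 0.5, state$s[j, r]^2, bsq)
      H <- margin_design(data$X, state$margins, j, r)
      other <- if (R > 1) rowSums(state$contrib[, -r, drop = FALSE]) else 0
      ytilde <- base_resid - other
      cond <- margin_conditional(H, ytilde, state$w[[r]][[j]],
                                 state$tau_r[r], state$sigma2)
      beta_new <- draw_mvn_from_cond(cond)
      state$margins$beta[[r]][[j]] <- beta_new
      state$contrib[, r] <- drop(H %*% beta_new)
    }
  }
  state
}

#' Joint update of the demographic coefficients and noise variance
#'
#' Draws `sigma^2` from its conditional with `gamma` collapsed out, then
#' `gamma | sigma^2`. Because both the `gamma` prior and the graph-Laplacian
#' prior on `eta` scale with `sigma^2`, the inverse-gamma shape is
#' `(n + q + nu)/2` and the rate picks up `m eta' Lambda eta / 2` in addition
#' to the usual residual terms.
#'
#' @param state,data As in [update_margins_block()].
#' @param hyper A [btr_hyper()] list.
#' @return State with `gamma` and `sigma2` refreshed.
#' @export
update_gamma_sigma <- function(state, data, hyper) {
  ystar <- data$y - (if (data$q > 0) drop(data$Z1 %*% state$eta) else 0) -
    rowSums(state$contrib)
  prec <- crossprod(data$Z) + data$Sigma0_gamma_inv
  ch <- chol(prec)
  mu <- backsolve(ch, backsolve(ch, crossprod(data$Z, ystar), transpose = TRUE))
  quad_eta <- if (data$q > 0) {
    L <- assemble_laplacian(state$lam_diag, state$lam_off)
    state$m * drop(crossprod(state$eta, L %*% state$eta))
  } else 0
  a_sig <- (data$n + data$q + hyper$nu) / 2
  b_sig <- (hyper$nu * hyper$s0sq + sum(ystar^2) - sum(ystar * (data$Z %*% mu)) +
              quad_eta) / 2
  if (b_sig <= 0) stop("non-positive inverse-gamma rate in sigma^2 update", call. = FALSE)
  state$sigma2 <- 1 / stats::rgamma(1, shape = a_sig, rate = b_sig)
  state$gamma <- drop(mu + sqrt(state$sigma2) * backsolve(ch, stats::rnorm(ncol(data$Z))))
  state
}

#' Update the gene coefficients under the graph-Laplacian prior
#'
#' `eta ~ N(mu_eta, Sigma_eta)` with
#' `mu_eta = (Z1'Z1 + m Lambda)^{-1} Z1' y**` and
#' `Sigma_eta = sigma^2 (Z1'Z1 + m Lambda)^{-1}`, where `y**` removes the
#' demographic and image terms.
#'
#' @param state,data As in [update_margins_block()].
#' @return State with `eta` refreshed.
#' @export
update_eta <- function(state, data) {
  if (data$q == 0) return(state)
  ystar2 <- data$y - drop(data$Z %*% state$gamma) - rowSums(state$contrib)
  L <- assemble_laplacian(state$lam_diag, state$lam_off)
  prec <- crossprod(data$Z1) + state$m * L
  ch <- chol(prec)
  mu <- backsolve(ch, backsolve(ch, crossprod(data$Z1, ystar2), transpose = TRUE))
  state$eta <- drop(mu + sqrt(state$sigma2) * backsolve(ch, stats::rnorm(data$q)))
  state
}

#' Exact elementwise update of the Laplacian elements
#'
#' The determinant factors cancel between the `eta` likelihood and the
#' element-level prior, so every `lambda` element has a closed-form full
#' conditional: `lambda_ii ~ giG(-1/2, m eta_i^2 / sigma^2, a^2)` and each
#' off-diagonal is a two-sided mixture whose positive branch is
#' `giG(-1/2, m (eta_i + eta_j)^2 / sigma^2, b^2)` and negative branch
#' `giG(-1/2, m (eta_i - eta_j)^2 / sigma^2, b^2)`, with mixture weights
#' proportional to `exp(-b |eta_i +/- eta_j| sqrt(m) / sigma)`.
#'
#' @param state,data As in [update_margins_block()].
#' @return State with `lam_diag` and `lam_off` refreshed.
#' @export
update_lambda <- function(state, data) {
  q <- data$q
  if (q == 0) return(state)
  eta <- state$eta; s2 <- state$sigma2; m <- state$m
  a <- state$a_gl; b <- state$b_gl
  state$lam_diag <- rgig(q, -0.5, m * eta^2 / s2, a^2)
  if (q > 1) {
    iu <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
    cp <- m * (eta[iu[, 1]] + eta[iu[, 2]])^2 / s2
    cm <- m * (eta[iu[, 1]] - eta[iu[, 2]])^2 / s2
    # P(lambda_ij > 0) from the two branch normalizing constants
    lp <- -b * sqrt(cp); lm <- -b * sqrt(cm)
    ppos <- 1 / (1 + exp(lm - lp))
    pos <- stats::runif(nrow(iu)) < ppos
    mag <- rgig(nrow(iu), -0.5, ifelse(pos, cp, cm), b^2)
    off <- matrix(0, q, q)
    off[upper.tri(off)] <- ifelse(pos, mag, -mag)
    state$lam_off <- off + t(off)
  }
  state
}

#' Update the graph-Laplacian hyperparameters m, a, b
#'
#' All three have closed-form conditionals once the `C_{a,b}` constants are
#' cancelled between the element-level prior and its hyperprior:
#' `m ~ Ga(h_m + q/2, h_m + eta' Lambda eta / (2 sigma^2))`, and `a`, `b`
#' are positive-truncated normals driven by `sum 1/lambda_ii` and
#' `sum_{j<i} 1/|lambda_ij|`.
#'
#' @param state,data As in [update_margins_block()].
#' @param hyper A [btr_hyper()] list.
#' @param update_ab Refresh `a` and `b` (set `FALSE` to hold them fixed).
#' @return State with `m` (and optionally `a_gl`, `b_gl`) refreshed.
#' @export
update_m_a_b <- function(state, data, hyper, update_ab = TRUE) {
  q <- data$q
  if (q == 0) {
    state$m <- stats::rgamma(1, shape = hyper$h_m, rate = hyper$h_m)
    return(state)
  }
  L <- assemble_laplacian(state$lam_diag, state$lam_off)
  quad <- drop(crossprod(state$eta, L %*% state$eta))
  state$m <- stats::rgamma(1, shape = hyper$h_m + q / 2,
                           rate = hyper$h_m + quad / (2 * state$sigma2))
  if (update_ab) {
    Sa <- sum(1 / state$lam_diag)
    if (is.finite(Sa) && Sa > 0)
      state$a_gl <- rtruncnorm_pos(-hyper$g_a / Sa, 1 / sqrt(Sa))
    if (q > 1) {
      Sb <- sum(1 / abs(state$lam_off[upper.tri(state$lam_off)]))
      if (is.finite(Sb) && Sb > 0)
        state$b_gl <- rtruncnorm_pos(-hyper$g_b / Sb, 1 / sqrt(Sb))
    }
  }
  state
}

#' Compositional update of the Dirichlet concentration and component scales
#'
#' First draws the concentration `alpha` by griddy Gibbs over its 10-point
#' grid, using the marginal likelihood of the margins with `(Phi, tau)`
#' integrated out (a product of Bessel-K integrals); then draws each
#' component scale `tau_r = phi_r tau` from its giG full conditional
#' `giG(alpha - sum_j p_j / 2, 2 b_tau, C_r)` with
#' `C_r = sum_j beta_j^(r)' W_jr^{-1} beta_j^(r)`, and sets
#' `tau = sum_r tau_r`, `phi_r = tau_r / tau` (the Dirichlet-gamma
#' augmentation, exact for `a_tau = R alpha`).
#'
#' @param state Sampler state.
#' @param grids Output of [hyper_grids()].
#' @param dims A [tensor_dims()] object.
#' @return State with `alpha`, `b_tau`, `tau_r`, `tau`, `phi` refreshed.
#' @export
update_alpha_phi_tau <- function(state, grids, dims) {
  R <- state$margins$R
  P <- sum(dims$p)
  C_r <- vapply(seq_len(R), function(r) {
    sum(vapply(seq_len(dims$D), function(j) {
      sum(state$margins$beta[[r]][[j]]^2 / state$w[[r]][[j]])
    }, numeric(1)))
  }, numeric(1))
  C_r <- pmax(C_r, 1e-300)
  lw <- vapply(grids$alpha, function(al) {
    btau <- al * R^(1 / dims$D)
    nu <- al - P / 2
    sum(al * log(btau) - lgamma(al) + log(2) +
          (nu / 2) * (log(C_r) - log(2 * btau)) +
          log_besselK(sqrt(2 * btau * C_r), nu))
  }, numeric(1))
  lw <- lw - max(lw)
  state$alpha <- grids$alpha[sample.int(length(grids$alpha), 1, prob = exp(lw))]
  state$b_tau <- state$alpha * R^(1 / dims$D)
  state$tau_r <- rgig(R, state$alpha - P / 2, 2 * state$b_tau, C_r)
  state$tau <- sum(state$tau_r)
  state$phi <- state$tau_r / state$tau
  state
}

# griddy Gibbs for the GDP shape a_lambda given the current rates s
update_a_lambda <- function(state, grids, dims) {
  svec <- as.vector(state$s)
  lw <- vapply(grids$a_lambda, function(a) {
    bl <- grids$b_lambda(a)
    sum(a * log(bl) - lgamma(a) + (a - 1) * log(svec) - bl * svec)
  }, numeric(1))
  lw <- lw - max(lw)
  state$a_lambda <- grids$a_lambda[sample.int(length(grids$a_lambda), 1, prob = exp(lw))]
  state$b_lambda <- grids$b_lambda(state$a_lambda)
  state
}

# ---- orchestration ----------------------------------------------------------

# Initialize the sampler state.  from_prior = TRUE draws every parameter
# from its prior (used by the joint-distribution validation); otherwise a
# diffuse deterministic-ish start is used.
gibbs_init <- function(data, rank, grids, hyper, from_prior = FALSE,
                       a_gl = hyper$a_gl, b_gl = hyper$b_gl) {
  dims <- data$dims
  if (from_prior) {
    alpha <- sample(grids$alpha, 1)
    a_lambda <- sample(grids$a_lambda, 1)
    b_lambda <- grids$b_lambda(a_lambda)
    pr <- mdgdp_sample_prior(dims, rank, alpha, a_lambda, b_lambda)
    st <- pr$state
    margins <- pr$margins
    sigma2 <- 1 / stats::rgamma(1, shape = hyper$nu / 2, rate = hyper$nu * hyper$s0sq / 2)
    gamma <- stats::rnorm(ncol(data$Z), 0, sqrt(sigma2 * hyper$gamma_prior_scale))
    m <- stats::rgamma(1, shape = hyper$h_m, rate = hyper$h_m)
    if (data$q > 0) {
      lam <- r_lambda_prior(data$q, a_gl, b_gl)
      L <- assemble_laplacian(lam$lam_diag, lam$lam_off)
      ch <- chol((m / sigma2) * L)
      eta <- drop(backsolve(ch, stats::rnorm(data$q)))
    } else {
      lam <- list(lam_diag = numeric(0), lam_off = matrix(0, 0, 0))
      eta <- numeric(0)
    }
    state <- list(margins = margins, tau_r = st$tau_r, tau = st$tau, phi = st$phi,
                  alpha = alpha, a_lambda = a_lambda, b_lambda = b_lambda,
                  b_tau = st$b_tau, s = st$s, w = st$w,
                  gamma = gamma, sigma2 = sigma2, eta = eta,
                  lam_diag = lam$lam_diag, lam_off = lam$lam_off,
                  m = m, a_gl = a_gl, b_gl = b_gl)
  } else {
    beta <- replicate(rank, lapply(dims$p, function(pj) stats::rnorm(pj, 0, 0.1)),
                      simplify = FALSE)
    margins <- tensor_margins(beta, dims)
    alpha <- grids$alpha[5]
    a_lambda <- grids$a_lambda[5]
    state <- list(margins = margins,
                  tau_r = rep(1, rank), tau = rank, phi = rep(1 / rank, rank),
                  alpha = alpha, a_lambda = a_lambda,
                  b_lambda = grids$b_lambda(a_lambda),
                  b_tau = alpha * rank^(1 / dims$D),
                  s = matrix(a_lambda, dims$D, rank),
                  w = replicate(rank, lapply(dims$p, function(pj) rep(1, pj)),
                                simplify = FALSE),
                  gamma = rep(0, ncol(data$Z)), sigma2 = stats::var(data$y),
                  eta = rep(0, data$q),
                  lam_diag = rep(1, data$q),
                  lam_off = matrix(0, data$q, data$q),
                  m = 1, a_gl = a_gl, b_gl = b_gl)
  }
  state$contrib <- contrib_matrix(data$X, state$margins)
  state
}

# n x R matrix of per-component inner products <X_i, B_r>
contrib_matrix <- function(X_stack, margins) {
  n <- dim(X_stack)[1L]
  out <- matrix(0, n, margins$R)
  Xm <- stack_matrix(X_stack)
  for (r in seq_len(margins$R)) {
    Br <- Reduce(`%o%`, margins$beta[[r]])
    out[, r] <- drop(Xm %*% as.vector(Br))
  }
  out
}

# One full Gibbs sweep; shared by run_mcmc() and the Geweke validation.
gibbs_sweep <- function(state, data, grids, hyper, update_ab = TRUE) {
  state <- update_alpha_phi_tau(state, grids, data$dims)
  state <- update_margins_block(state, data)
  state <- update_a_lambda(state, grids, data$dims)
  state <- update_gamma_sigma(state, data, hyper)
  state <- update_eta(state, data)
  state <- update_lambda(state, data)
  state <- update_m_a_b(state, data, hyper, update_ab = update_ab)
  state
}

# Assemble the internal data list from user inputs.  Z gains an intercept
# column; the all-zero-voxel mask is applied (screened voxels contribute
# nothing to the likelihood and are zeroed in reported tensors).
prepare_data <- function(y, X, Z = NULL, Z1 = NULL, hyper = btr_hyper(),
                         mask = NULL) {
  n <- length(y)
  d <- dim(X)
  if (is.null(d) || length(d) < 3L)
    stop("X must be an n x p_1 x ... x p_D array with D >= 2", call. = FALSE)
  if (d[1L] != n) stop("nrow of image stack must match length(y)", call. = FALSE)
  dims <- tensor_dims(d[-1L])
  Z <- if (is.null(Z)) matrix(0, n, 0) else as.matrix(Z)
  Z1 <- if (is.null(Z1)) matrix(0, n, 0) else as.matrix(Z1)
  stopifnot(nrow(Z) == n, nrow(Z1) == n)
  Zi <- cbind(`(Intercept)` = 1, Z)
  if (is.null(mask)) mask <- apply(X != 0, seq_along(dims$p) + 1L, any)
  list(y = as.numeric(y), X = X, Z = Zi, Z1 = Z1, dims = dims,
       n = n, p = ncol(Z), q = ncol(Z1), mask = mask,
       Sigma0_gamma_inv = diag(1 / hyper$gamma_prior_scale, ncol(Zi)))
}

#' Run the Gibbs sampler
#'
#' Executes the full sweep sequence — `(alpha, Phi, tau)`, back-fitting over
#' `(s, w, beta)`, `(gamma, sigma^2)`, `eta`, `lambda`, `(m, a, b)` — for
#' `n_iter` sweeps and stores post-burn-in thinned draws of every monitored
#' quantity along with the per-draw log-likelihood used by [compute_dic()].
#' Runs are bit-reproducible under `config$seed`.
#'
#' @param y Length-`n` response.
#' @param X `n x p_1 x ... x p_D` image stack.
#' @param Z Optional `n x p` demographic matrix (intercept added internally).
#' @param Z1 Optional `n x q` gene-expression matrix.
#' @param rank Tensor rank `R >= 1`.
#' @param config A [btr_config()].
#' @param hyper A [btr_hyper()].
#' @return An object of class `"btr_draws"`: a list with draw matrices
#'   (`B`, `gamma`, `eta`, `sigma2`, `tau`, `phi`, `alpha`, `a_lambda`, `m`,
#'   `a_gl`, `b_gl`, `loglik`), the mask, dims and the configuration.
#' @export
run_mcmc <- function(y, X, Z = NULL, Z1 = NULL, rank = 1,
                     config = btr_config(), hyper = btr_hyper()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  data <- prepare_data(y, X, Z, Z1, hyper)
  grids <- hyper_grids(data$dims$D, rank)
  state <- gibbs_init(data, rank, grids, hyper)
  keep <- seq.int(config$burn_in + 1L, config$n_iter, by = config$thin)
  S <- length(keep)
  P <- prod(data$dims$p)
  draws <- list(
    B = if (config$store_B) matrix(NA_real_, S, P) else NULL,
    gamma = matrix(NA_real_, S, ncol(data$Z)),
    eta = matrix(NA_real_, S, data$q),
    sigma2 = numeric(S), tau = numeric(S),
    phi = matrix(NA_real_, S, rank),
    alpha = numeric(S), a_lambda = numeric(S),
    m = numeric(S), a_gl = numeric(S), b_gl = numeric(S),
    loglik = numeric(S))
  colnames(draws$gamma) <- colnames(data$Z)
  if (data$q > 0)
    colnames(draws$eta) <- colnames(data$Z1) %||% paste0("gene", seq_len(data$q))
  mask_vec <- as.numeric(data$mask)
  si <- 0L
  for (it in seq_len(config$n_iter)) {
    state <- gibbs_sweep(state, data, grids, hyper, update_ab = config$update_ab)
    if (it %% 200L == 0L &&
        (!is.finite(state$sigma2) || !all(is.finite(state$gamma)) ||
         !all(is.finite(unlist(state$margins$beta)))))
      stop("non-finite sampler state at sweep ", it, call. = FALSE)
    if (it > config$burn_in && (it - config$burn_in - 1L) %% config$thin == 0L) {
      si <- si + 1L
      fitted <- drop(data$Z %*% state$gamma) +
        (if (data$q > 0) drop(data$Z1 %*% state$eta) else 0) +
        rowSums(state$contrib)
      if (config$store_B)
        draws$B[si, ] <- as.vector(parafac_compose(state$margins)) * mask_vec
      draws$gamma[si, ] <- state$gamma
      if (data$q > 0) draws$eta[si, ] <- state$eta
      draws$sigma2[si] <- state$sigma2
      draws$tau[si] <- state$tau
      draws$phi[si, ] <- state$phi
      draws$alpha[si] <- state$alpha
      draws$a_lambda[si] <- state$a_lambda
      draws$m[si] <- state$m
      draws$a_gl[si] <- state$a_gl
      draws$b_gl[si] <- state$b_gl
      draws$loglik[si] <- sum(stats::dnorm(data$y, fitted, sqrt(state$sigma2),
                                           log = TRUE))
    }
    if (config$verbose && it %% 1000L == 0L)
      message("sweep ", it, " / ", config$n_iter)
  }
  structure(list(draws = draws, dims = data$dims, rank = rank,
                 mask = data$mask, n = data$n, p = data$p, q = data$q,
                 config = config, hyper = hyper,
                 y = data$y),
            class = "btr_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
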