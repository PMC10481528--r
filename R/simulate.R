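#' Define a simulation scenario
#'
#' Describes a synthetic imaging-transcriptomics dataset with known ground
#' truth: a low-rank image coefficient with a shared zero-mask (mimicking
#' cortical-thickness slices, which are zero outside the cortex in every
#' subject), gene features drawn from a graph-structured Gaussian (chain
#' plus hub edges with nontrivial partial correlations), sparse gene
#' effects, demographic effects and Gaussian noise at a stated
#' signal-to-noise ratio.
#'
#' @param n Number of subjects.
#' @param p_dims Image grid extents, e.g. `c(16, 16)`.
#' @param rank True CP rank of the image coefficient.
#' @param sparsity Fraction of voxels zero across all subjects (in `[0, 1)`);
#'   realized as a one-voxel border (rank-preserving) topped up with random
#'   scatter away from the signal support.
#' @param q Number of gene features.
#' @param n_hub Number of hub edges added to the chain gene graph.
#' @param prop_eta_nonzero Fraction of genes with a nonzero effect.
#' @param eta_size Magnitude of nonzero gene effects.
#' @param p_demo Number of demographic covariates.
#' @param gamma True demographic coefficients (recycled to `p_demo`).
#' @param intercept True intercept.
#' @param snr Signal-to-noise ratio `sd(linear predictor) / sigma`; ignored
#'   when `noise_sd` is given.
#' @param noise_sd Optional fixed residual standard deviation.
#' @param signal_shape `"blocks"` or `"smooth"` (see [make_low_rank_signal()]).
#' @param signal_scale Multiplier on the image coefficient.
#' @param image_noise_sd Subject-level voxel jitter around the shared pattern.
#' @param seed Integer seed.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n = 150, p_dims = c(16, 16), rank = 2, sparsity = 0.3,
                         q = 20, n_hub = 3, prop_eta_nonzero = 0.25,
                         eta_size = 0.5, p_demo = 2, gamma = c(0.5, -0.3),
                         intercept = 1, snr = 3, noise_sd = NULL,
                         signal_shape = c("blocks", "smooth"),
                         signal_scale = 0.5, image_noise_sd = 1, seed = 1L) {
  signal_shape <- match.arg(signal_shape)
  stopifnot(sparsity >= 0, sparsity < 1, n >= 3, q >= 0, p_demo >= 0)
  structure(list(n = n, p_dims = as.integer(p_dims), rank = rank,
                 sparsity = sparsity, q = q, n_hub = n_hub,
                 prop_eta_nonzero = prop_eta_nonzero, eta_size = eta_size,
                 p_demo = p_demo, gamma = rep_len(gamma, p_demo),
                 intercept = intercept, snr = snr, noise_sd = noise_sd,
                 signal_shape = signal_shape, signal_scale = signal_scale,
                 image_noise_sd = image_noise_sd, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Low-rank test signal
#'
#' Builds a `D`-way tensor of exactly the requested CP rank: `"blocks"` sums
#' `rank` outer products of disjoint-interval indicator vectors (rectangles),
#' `"smooth"` sums outer products of Gaussian bumps at distinct centres.
#' Indicators on disjoint row-intervals are linearly independent, so the 2-D
#' numerical (SVD) rank equals the CP rank.
#'
#' @param dims A [tensor_dims()] object (or integer vector of extents).
#' @param rank Requested rank, `<= min(p_j)/2` for `"blocks"`.
#' @param shape `"blocks"` or `"smooth"`.
#' @param interior Margin (in voxels) kept clear at every mode's boundary so
#'   the signal survives a border mask.
#' @param seed Integer seed.
#' @return A dense array of shape `p_1 x ... x p_D`.
#' @export
make_low_rank_signal <- function(dims, rank = 2, shape = c("blocks", "smooth"),
                                 interior = 1L, seed = 1L) {
  if (!inherits(dims, "tensor_dims")) dims <- tensor_dims(dims)
  shape <- match.arg(shape)
  set.seed(seed)
  beta <- vector("list", rank)
  for (r in seq_len(rank)) {
    beta[[r]] <- lapply(seq_len(dims$D), function(j) {
      pj <- dims$p[j]
      lo <- interior + 1L; hi <- pj - interior
      if (hi < lo) stop("grid too small for the requested interior margin", call. = FALSE)
      v <- numeric(pj)
      if (shape == "blocks") {
        # disjoint interval per component along each mode
        width <- max(1L, (hi - lo + 1L) %/% rank)
        a <- lo + (r - 1L) * width
        b <- if (r == rank) hi else min(hi, a + width - 1L)
        if (a > hi) a <- hi
        v[a:b] <- stats::runif(1, 0.8, 1.2)
      } else {
        centre <- stats::runif(1, lo, hi)
        sdv <- (hi - lo + 1) / (2 * rank + 2)
        v <- exp(-((seq_len(pj) - centre)^2) / (2 * sdv^2))
        v[seq_len(pj) < lo | seq_len(pj) > hi] <- 0
      }
      v
    })
  }
  parafac_compose(tensor_margins(beta, dims))
}

# Chain-plus-hubs precision matrix for the gene block; partial correlations
# of linked pairs land in roughly [0.3, 0.6].  Returns the precision, its
# implied covariance/correlation and the edge list.
gene_graph_precision <- function(q, n_hub = 3, rho_range = c(0.3, 0.6)) {
  if (q == 0) return(list(Omega = matrix(0, 0, 0), Sigma = matrix(0, 0, 0),
                          edges = tibble::tibble()))
  edges <- if (q > 1) tibble::tibble(i = seq_len(q - 1), j = seq.int(2, q)) else
    tibble::tibble(i = integer(0), j = integer(0))
  if (q > 4 && n_hub > 0) {
    hub <- tibble::tibble(i = 1L,
                          j = as.integer(seq(3, q, length.out = min(n_hub, q - 2))))
    edges <- dplyr::bind_rows(edges, hub) |> dplyr::distinct()
  }
  Omega <- diag(q)
  if (nrow(edges) > 0) {
    w <- stats::runif(nrow(edges), rho_range[1], rho_range[2])
    for (k in seq_len(nrow(edges))) {
      Omega[edges$i[k], edges$j[k]] <- Omega[edges$j[k], edges$i[k]] <- -w[k]
    }
    # rescale diagonal for strict dominance -> positive definite
    diag(Omega) <- 1 + rowSums(abs(Omega)) - 1
  }
  Sigma <- solve(Omega)
  list(Omega = Omega, Sigma = Sigma, edges = edges)
}

#' Simulate a dataset from a scenario
#'
#' Draws gene features from `N(0, Sigma)` with `Sigma` the inverse of the
#' chain-plus-hubs precision; builds images as a shared smooth pattern plus
#' subject-level voxel jitter, multiplied by a deterministic zero-mask shared
#' by all subjects; composes the response from the true model and returns
#' the complete ground-truth record needed for recovery scoring. The mask is
#' also applied to the true coefficient tensor (masked voxels are
#' inestimable and are reported as zeros by the fitter).
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `"btr_dataset"` with `y`, `Z`, `Z1`, `X`, `mask`,
#'   `subjects` and a `truth` list (`B`, `B_unmasked`, `margins_shape`,
#'   `gamma`, `intercept`, `eta`, `noise_sd`, `Sigma_gene`, `Omega_gene`,
#'   `edges`, `scenario`).
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n
  dims <- tensor_dims(scenario$p_dims)
  P <- prod(dims$p)

  B0 <- scenario$signal_scale *
    make_low_rank_signal(dims, scenario$rank, scenario$signal_shape,
                         interior = 1L, seed = scenario$seed + 1L)
  mask <- make_zero_mask(dims, scenario$sparsity, avoid = B0 != 0)
  B_true <- B0 * mask

  # images: shared bump pattern + subject jitter, zeroed off-mask
  grid <- lapply(dims$p, function(pj) (seq_len(pj) - (pj + 1) / 2) / pj)
  base <- Reduce(`%o%`, lapply(grid, function(g) exp(-4 * g^2)))
  X <- array(stats::rnorm(n * P, 0, scenario$image_noise_sd), dim = c(n, dims$p))
  X <- X + rep(1, n) %o% base
  X <- X * (rep(1, n) %o% (mask * 1))

  Z <- if (scenario$p_demo > 0) {
    Zm <- cbind(stats::rnorm(n), matrix(stats::rbinom(n * (scenario$p_demo - 1), 1, 0.5),
                                        n, max(0, scenario$p_demo - 1)))
    colnames(Zm) <- paste0("demo", seq_len(scenario$p_demo))
    Zm[, seq_len(scenario$p_demo), drop = FALSE]
  } else matrix(0, n, 0)

  gg <- gene_graph_precision(scenario$q, scenario$n_hub)
  Z1 <- if (scenario$q > 0) {
    Zr <- matrix(stats::rnorm(n * scenario$q), n, scenario$q) %*% chol(gg$Sigma)
    colnames(Zr) <- paste0("gene", seq_len(scenario$q))
    Zr
  } else matrix(0, n, 0)

  eta <- numeric(scenario$q)
  n_nz <- round(scenario$q * scenario$prop_eta_nonzero)
  if (n_nz > 0) {
    nz <- seq_len(n_nz)   # first genes carry signal; recorded in truth
    eta[nz] <- scenario$eta_size * rep_len(c(1, -1), n_nz)
  }

  lp <- scenario$intercept +
    (if (scenario$p_demo > 0) drop(Z %*% scenario$gamma) else 0) +
    (if (scenario$q > 0) drop(Z1 %*% eta) else 0) +
    drop(stack_matrix(X) %*% as.vector(B_true))
  noise_sd <- scenario$noise_sd %||%
    (if (stats::sd(lp) > 0) stats::sd(lp) / scenario$snr else 1)
  y <- lp + stats::rnorm(n, 0, noise_sd)

  structure(list(
    y = y, Z = Z, Z1 = Z1, X = X, mask = mask,
    subjects = sprintf("subj%03d", seq_len(n)),
    truth = list(B = B_true, B_unmasked = B0, gamma = scenario$gamma,
                 intercept = scenario$intercept, eta = eta,
                 nonzero_eta = which(eta != 0), noise_sd = noise_sd,
                 linear_predictor = lp, Sigma_gene = gg$Sigma,
                 Omega_gene = gg$Omega, edges = gg$edges,
                 scenario = scenario)), class = "btr_dataset")
}

# Deterministic border mask (rank-1: outer product of indicator vectors)
# plus random scatter off the protected voxels, hitting the target fraction
# to within one voxel.  `avoid` marks voxels that must stay unmasked.
make_zero_mask <- function(dims, sparsity, avoid = NULL) {
  P <- prod(dims$p)
  target <- round(sparsity * P)
  mask <- array(TRUE, dim = dims$p)
  if (target == 0) return(mask)
  border <- lapply(dims$p, function(pj) {
    v <- rep(TRUE, pj); v[c(1L, pj)] <- FALSE; v
  })
  border_mask <- Reduce(`%o%`, border) > 0
  n_border <- sum(!border_mask)
  if (n_border <= target) {
    mask <- border_mask
    deficit <- target - n_border
    if (deficit > 0) {
      candidates <- which(mask & !(if (is.null(avoid)) array(FALSE, dims$p) else avoid))
      drop_idx <- sample(candidates, min(deficit, length(candidates)))
      mask[drop_idx] <- FALSE
    }
  } else {
    # border alone overshoots: scatter only
    candidates <- which(!(if (is.null(avoid)) array(FALSE, dims$p) else avoid))
    mask[sample(candidates, min(target, length(candidates)))] <- FALSE
  }
  mask
}

#' @export
print.btr_dataset <- function(x, ...) {
  cat(sprintf("<btr_dataset> n = %d, image %s (%.0f%% masked), %d genes, %d demographics\n",
              length(x$y), paste(dim(x$X)[-1], collapse = " x "),
              100 * mean(!x$mask), ncol(x$Z1), ncol(x$Z)))
  invisible(x)
}
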