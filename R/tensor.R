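#' Tensor dimension descriptor
#'
#' Records the number of modes `D` and the per-mode extents `p = (p_1, ..., p_D)`
#' of the image grid. All tensor indices are 1-based at the user interface
#' (matching the usual mathematical notation); internal array storage is R's
#' native column-major layout, so mode 1 varies fastest.
#'
#' @param p Integer vector of per-mode extents, length `D >= 2`, all `>= 1`.
#' @return An object of class `"tensor_dims"` with fields `D` and `p`.
#' @export
#' @examples
#' tensor_dims(c(16, 16))
tensor_dims <- function(p) {
  p <- as.integer(p)
  if (length(p) < 2L) stop("a tensor predictor needs at least D = 2 modes", call. = FALSE)
  if (any(p < 1L) || anyNA(p)) stop("all mode extents p_j must be positive integers", call. = FALSE)
  structure(list(D = length(p), p = p), class = "tensor_dims")
}

#' @export
print.tensor_dims <- function(x, ...) {
  cat(sprintf("<tensor_dims> D = %d, p = (%s)\n", x$D, paste(x$p, collapse = ", ")))
  invisible(x)
}

#' PARAFAC (CP) tensor margins
#'
#' A rank-`R` set of margin vectors `beta_j^(r)` (one length-`p_j` vector per
#' mode `j = 1..D` and component `r = 1..R`) representing the coefficient
#' tensor `B = sum_r beta_1^(r) o ... o beta_D^(r)`. Margins are deliberately
#' not identifiability-constrained (no scaling or sign convention): only the
#' composed tensor is identifiable, and that is all downstream code compares.
#'
#' @param beta A list of length `R`; each element a list of `D` numeric
#'   vectors, the j-th of length `p_j`.
#' @param dims A [tensor_dims()] object; inferred from `beta` when `NULL`.
#' @return An object of class `"tensor_margins"` with fields `R`, `dims`, `beta`.
#' @export
tensor_margins <- function(beta, dims = NULL) {
  stopifnot(is.list(beta), length(beta) >= 1L)
  lens <- vapply(beta[[1L]], length, integer(1))
  if (is.null(dims)) dims <- tensor_dims(lens)
  for (r in seq_along(beta)) {
    b <- beta[[r]]
    if (length(b) != dims$D) stop("margin set ", r, " does not have D vectors", call. = FALSE)
    for (j in seq_len(dims$D)) {
      if (length(b[[j]]) != dims$p[j])
        stop(sprintf("margin beta_%d^(%d) has length %d, expected p_%d = %d",
                     j, r, length(b[[j]]), j, dims$p[j]), call. = FALSE)
      if (!all(is.finite(b[[j]])))
        stop("margin vectors must be finite", call. = FALSE)
    }
  }
  structure(list(R = length(beta), dims = dims, beta = beta), class = "tensor_margins")
}

#' Compose the coefficient tensor from its PARAFAC margins
#'
#' Evaluates `(B)_{i_1..i_D} = sum_{r=1}^R prod_{j=1}^D beta_{j, i_j}^(r)`,
#' i.e. the sum of `R` outer products of the margin vectors.
#'
#' @param margins A [tensor_margins()] object.
#' @return A dense `D`-way array of shape `p_1 x ... x p_D`.
#' @export
#' @examples
#' m <- tensor_margins(list(list(c(1, 2), c(3, 4))))
#' parafac_compose(m)   # rank-1 outer product
parafac_compose <- function(margins) {
  stopifnot(inherits(margins, "tensor_margins"))
  p <- margins$dims$p
  B <- array(0, dim = p)
  for (r in seq_len(margins$R)) {
    B <- B + Reduce(`%o%`, margins$beta[[r]])
  }
  B
}

#' Model-parameter counts with and without the PARAFAC decomposition
#'
#' The unstructured coefficient tensor has `prod(p_j)` free elements, so the
#' full model carries `p + q + 2 + prod(p_j)` parameters (demographics,
#' genes, intercept and noise variance included); the rank-`R` PARAFAC
#' factorization reduces the tensor block to `R * sum(p_j)`.
#'
#' @param dims A [tensor_dims()] object.
#' @param R Tensor rank.
#' @param n_demo Number of demographic covariates (`p` in the regression).
#' @param n_gene Number of gene covariates (`q`).
#' @return Named numeric vector `c(full = ..., parafac = ...)`.
#' @export
count_parameters <- function(dims, R, n_demo = 0L, n_gene = 0L) {
  stopifnot(inherits(dims, "tensor_dims"), R >= 1)
  c(full    = n_demo + n_gene + 2 + prod(dims$p),
    parafac = n_demo + n_gene + 2 + R * sum(dims$p))
}

#' Tensor inner product
#'
#' Elementwise-product sum `<X, B> = sum_i X_i * B_i` of two equal-shaped
#' dense arrays.
#'
#' @param X,B Numeric arrays of identical shape.
#' @return A scalar.
#' @export
tensor_inner_product <- function(X, B) {
  if (!identical(dim(X), dim(B)))
    stop("tensor_inner_product: shape mismatch", call. = FALSE)
  sum(X * B)
}

# Flatten an n x p_1 x ... x p_D image stack to an n x prod(p) matrix whose
# column order matches as.vector() of a single image (column-major).
stack_matrix <- function(X_stack) {
  d <- dim(X_stack)
  matrix(X_stack, nrow = d[1L], ncol = prod(d[-1L]))
}

# Subject-subset of an image stack, preserving the array shape.
subset_stack <- function(X_stack, idx) {
  d <- dim(X_stack)
  out <- stack_matrix(X_stack)[idx, , drop = FALSE]
  array(out, dim = c(length(idx), d[-1L]))
}

# Per-subject inner products <X_i, B> for a whole stack.
stack_inner_product <- function(X_stack, B) {
  d <- dim(X_stack)
  if (!identical(as.integer(d[-1L]), as.integer(dim(B))))
    stop("image stack and coefficient tensor shapes differ", call. = FALSE)
  drop(stack_matrix(X_stack) %*% as.vector(B))
}

#' Per-margin design matrix for the back-fitting update
#'
#' For mode `j` and component `r`, row `i`, column `k` holds
#' `h_{i,j,k}^(r) = sum_{d : d_j = k} x_{i, d} * prod_{l != j} beta_{l, d_l}^(r)`,
#' i.e. the image contracted against every off-mode margin of component `r`.
#' It satisfies the identity
#' `H_{i,j}^(r) . beta_j^(r) = <X_i, beta_1^(r) o ... o beta_D^(r)>` for every
#' subject and mode, which is what the Gibbs sampler's margin update relies on.
#'
#' @param X_stack `n x p_1 x ... x p_D` array of images.
#' @param margins A [tensor_margins()] object.
#' @param j Mode index in `1..D`.
#' @param r Component index in `1..R`.
#' @return An `n x p_j` matrix.
#' @export
margin_design <- function(X_stack, margins, j, r) {
  stopifnot(inherits(margins, "tensor_margins"))
  dims <- margins$dims
  if (j < 1L || j > dims$D) stop("mode index j out of range", call. = FALSE)
  if (r < 1L || r > margins$R) stop("component index r out of range", call. = FALSE)
  d <- dim(X_stack)
  if (length(d) != dims$D + 1L || !identical(as.integer(d[-1L]), dims$p))
    stop("image stack shape does not match tensor dims", call. = FALSE)
  n <- d[1L]
  others <- setdiff(seq_len(dims$D), j)
  # off-mode weight vector, column-major over the remaining modes
  g <- if (length(others) == 1L) margins$beta[[r]][[others]] else
    as.vector(Reduce(`%o%`, margins$beta[[r]][others]))
  # reorder voxels so mode j is slowest, then contract each of the p_j blocks
  Xp <- aperm(X_stack, c(1L, 1L + others, 1L + j))
  Q <- prod(dims$p[others])
  dim(Xp) <- c(n * Q, dims$p[j])
  H <- matrix(0, n, dims$p[j])
  for (k in seq_len(dims$p[j])) {
    H[, k] <- matrix(Xp[, k], n, Q) %*% g
  }
  H
}
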