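#' Compare prediction methods over replicate train/test splits
#'
#' Runs, on identical splits, (i) the full integrative tensor model
#' (image + genes + demographics), (ii) an image-only Bayesian tensor
#' regression, (iii) an elastic net on the vectorized image voxels plus
#' genes and demographics, and (iv) a gene-only elastic net, and reports the
#' out-of-sample relative RMSE of each. Elastic-net fits use mixing
#' parameter 0.5 with the penalty chosen by 5-fold cross-validation on the
#' training split; demographics are included, unpenalized, in every method.
#'
#' @param dataset A `"btr_dataset"` (from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param splits Tibble from [split_train_test()]; default 10 splits at 80:20.
#' @param rank Tensor rank for the Bayesian fits.
#' @param config A [btr_config()] for the Bayesian fits.
#' @param hyper A [btr_hyper()].
#' @param methods Subset of `c("ibtr", "btr", "enet", "gene_enet")`.
#' @param seed Seed for the default splits and the elastic-net folds.
#' @return Tibble `split`, `method`, `rrmse`, `n_train`, `n_test`.
#' @export
evaluate_methods <- function(dataset, splits = NULL, rank = 2,
                             config = btr_config(n_iter = 2000, burn_in = 700),
                             hyper = btr_hyper(),
                             methods = c("ibtr", "btr", "enet", "gene_enet"),
                             seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(splits)) splits <- split_train_test(length(dataset$y), seed = seed)
  n_gene <- ncol(dataset$Z1); n_demo <- ncol(dataset$Z)
  Xm <- stack_matrix(dataset$X)
  rows <- list()
  for (s in seq_len(nrow(splits))) {
    tr <- splits$train[[s]]; te <- splits$test[[s]]
    ytr <- dataset$y[tr]; yte <- dataset$y[te]
    Ztr <- dataset$Z[tr, , drop = FALSE]; Zte <- dataset$Z[te, , drop = FALSE]
    Z1tr <- dataset$Z1[tr, , drop = FALSE]; Z1te <- dataset$Z1[te, , drop = FALSE]
    Xtr <- subset_stack(dataset$X, tr)
    Xte <- subset_stack(dataset$X, te)
    for (m in methods) {
      cfg <- config
      cfg$seed <- (config$seed %||% seed) + 1000L * s
      pred <- switch(
        m,
        ibtr = {
          fit <- btr(ytr, Xtr, Ztr, if (n_gene > 0) Z1tr else NULL,
                     rank = rank, config = cfg, hyper = hyper)
          predict(fit, Xte, Zte, if (n_gene > 0) Z1te else NULL)
        },
        btr = {
          fit <- btr(ytr, Xtr, Ztr, NULL, rank = rank, config = cfg, hyper = hyper)
          predict(fit, Xte, Zte, NULL)
        },
        enet = enet_predict(cbind(Ztr, Z1tr, Xm[tr, , drop = FALSE]),
                            ytr, cbind(Zte, Z1te, Xm[te, , drop = FALSE]),
                            n_unpenalized = n_demo, seed = cfg$seed),
        gene_enet = enet_predict(cbind(Ztr, Z1tr), ytr, cbind(Zte, Z1te),
                                 n_unpenalized = n_demo, seed = cfg$seed))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(split = s, method = m, rrmse = rrmse(pred, yte),
                       n_train = length(tr), n_test = length(te))
    }
  }
  dplyr::bind_rows(rows)
}

# elastic net (alpha = 0.5) with 5-fold CV on the training split; the first
# n_unpenalized columns (demographics) carry zero penalty
enet_predict <- function(xtr, ytr, xte, n_unpenalized = 0, seed = 1L) {
  set.seed(seed)
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  keep <- apply(xtr, 2, stats::sd) > 0
  if (!any(keep)) return(rep(mean(ytr), nrow(xte)))
  pf <- rep(1, ncol(xtr))
  pf[seq_len(min(n_unpenalized, ncol(xtr)))] <- 0
  cv <- glmnet::cv.glmnet(xtr[, keep, drop = FALSE], ytr, alpha = 0.5,
                          nfolds = 5, penalty.factor = pf[keep])
  drop(stats::predict(cv, newx = xte[, keep, drop = FALSE], s = "lambda.min"))
}
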