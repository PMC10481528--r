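#' Write / read a dense image stack
#'
#' The stack is stored as a plain-text container: a sidecar header file
#' (`<path>.hdr`, `dim: n p_1 ... p_D` plus a format line) and the values in
#' flat column-major order, one per line, full `%.17g` precision so that the
#' round trip is bit-exact for doubles.
#'
#' @param X `n x p_1 x ... x p_D` numeric array.
#' @param path Data file path; the header goes to `paste0(path, ".hdr")`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` the array.
#' @export
write_stack <- function(X, path) {
  d <- dim(X)
  stopifnot(length(d) >= 3L)
  writeLines(c(paste("dim:", paste(d, collapse = " ")),
               "format: flat column-major, one value per line, C %.17g"),
             paste0(path, ".hdr"))
  writeLines(sprintf("%.17g", as.vector(X)), path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  d <- as.integer(strsplit(sub("^dim:\\s*", "", hdr[1]), "\\s+")[[1]])
  vals <- as.numeric(readLines(path))
  if (length(vals) != prod(d)) stop("stack file length does not match header", call. = FALSE)
  array(vals, dim = d)
}

#' Write / read a covariate table
#'
#' Comma-separated, header row, '.' decimal, UTF-8; subject identifiers in
#' the first column. Values at full precision so the round trip is exact.
#'
#' @param x A data frame / tibble whose first column identifies subjects.
#' @param path File path.
#' @return `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  tibble::as_tibble(out)
}

#' Write a simulated dataset to a directory
#'
#' Emits `images.dat`(+`.hdr`), `genes.csv`, `demographics.csv`,
#' `response.csv` in the formats the pipeline consumes.
#'
#' @param dataset A `"btr_dataset"` (or a compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(dataset$X, file.path(dir, "images.dat"))
  ids <- dataset$subjects %||% sprintf("subj%03d", seq_along(dataset$y))
  write_table_csv(data.frame(subject = ids, dataset$Z1, check.names = FALSE),
                  file.path(dir, "genes.csv"))
  write_table_csv(data.frame(subject = ids, dataset$Z, check.names = FALSE),
                  file.path(dir, "demographics.csv"))
  write_table_csv(data.frame(subject = ids, y = dataset$y),
                  file.path(dir, "response.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  X <- read_stack(file.path(dir, "images.dat"))
  genes <- read_table_csv(file.path(dir, "genes.csv"))
  demo <- read_table_csv(file.path(dir, "demographics.csv"))
  resp <- read_table_csv(file.path(dir, "response.csv"))
  stopifnot(identical(genes[[1]], resp[[1]]), identical(demo[[1]], resp[[1]]))
  sc <- screen_voxels(X)
  structure(list(y = resp$y, Z = as.matrix(demo[, -1, drop = FALSE]),
                 Z1 = as.matrix(genes[, -1, drop = FALSE]),
                 X = sc$X, mask = sc$mask, subjects = resp[[1]]),
            class = "btr_dataset")
}

#' Screen voxels that are zero in every subject
#'
#' @param X_stack `n x p_1 x ... x p_D` array.
#' @return List with the (unchanged-shape) stack and the logical `mask`
#'   (`TRUE` = retained, i.e. nonzero for at least one subject).
#' @export
screen_voxels <- function(X_stack) {
  d <- dim(X_stack)
  mask <- apply(X_stack != 0, seq_along(d)[-1L], any)
  list(X = X_stack, mask = mask)
}

#' Retain slices with enough nonzero voxels
#'
#' A slice (one member of `slice_list`, each an `n x p_1 x ... x p_D` stack)
#' is retained when the fraction of voxels that are nonzero in at least one
#' subject is at least `threshold`.
#'
#' @param slice_list List of image stacks.
#' @param threshold Minimum nonzero-voxel fraction, in `(0, 1]` (default 0.5).
#' @return Integer vector of retained slice indices.
#' @export
filter_slices <- function(slice_list, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- vapply(slice_list, function(X) mean(screen_voxels(X)$mask), numeric(1))
  which(frac >= threshold)
}

#' Screen genes by correlation with the outcome at every visit
#'
#' A gene is retained when the Pearson correlation test against the outcome
#' has p-value below `level` at every visit (intersection rule). Constant
#' gene columns are excluded with a warning. The decision is invariant to
#' affine rescaling of expression columns.
#'
#' @param expression_list List of `n_v x q` matrices/data frames, one per
#'   visit, with identical gene columns.
#' @param outcome_list List of length-`n_v` outcome vectors, one per visit.
#' @param level Test level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Character vector of retained gene identifiers.
#' @export
screen_genes <- function(expression_list, outcome_list, level = 0.05,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(expression_list) == length(outcome_list))
  genes <- colnames(as.matrix(expression_list[[1]]))
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(as.matrix(expression_list[[1]]))))
  keep <- rep(TRUE, length(genes))
  for (v in seq_along(expression_list)) {
    E <- as.matrix(expression_list[[v]])
    yv <- outcome_list[[v]]
    stopifnot(ncol(E) == length(genes), nrow(E) == length(yv))
    pv <- vapply(seq_len(ncol(E)), function(k) {
      if (stats::sd(E[, k]) == 0) {
        warning("constant gene column ", genes[k], " excluded", call. = FALSE)
        return(1)
      }
      stats::cor.test(E[, k], yv, method = method, exact = FALSE)$p.value
    }, numeric(1))
    keep <- keep & (pv < level)
  }
  genes[keep]
}

#' Longitudinal change dataset
#'
#' Differences the response and the image stack between two visits
#' (`t2 - t1`) while carrying the cross-sectional gene and demographic
#' tables over unchanged.
#'
#' @param dataset_t2,dataset_t1 `"btr_dataset"` lists with matching subjects.
#' @return A `"btr_dataset"` with `y = y_t2 - y_t1`, `X = X_t2 - X_t1`.
#' @export
longitudinal_change <- function(dataset_t2, dataset_t1) {
  s2 <- dataset_t2$subjects; s1 <- dataset_t1$subjects
  if (!identical(s2, s1)) {
    bad <- union(setdiff(s2, s1), setdiff(s1, s2))
    stop("subject mismatch between visits: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  out <- dataset_t1
  out$y <- dataset_t2$y - dataset_t1$y
  out$X <- dataset_t2$X - dataset_t1$X
  out$mask <- screen_voxels(out$X)$mask
  out$truth <- NULL
  out
}

#' Seeded train/test splits
#'
#' Draws `n_splits` independent random 80:20 (by default) partitions of the
#' subject index.
#'
#' @param n Number of subjects (or a `"btr_dataset"`).
#' @param ratio Training fraction.
#' @param n_splits Number of replicate splits.
#' @param seed Integer seed.
#' @return Tibble `split`, `train` (list of index vectors), `test`.
#' @export
split_train_test <- function(n, ratio = 0.8, n_splits = 10, seed = 1L) {
  if (inherits(n, "btr_dataset")) n <- length(n$y)
  stopifnot(n >= 5, ratio > 0, ratio < 1)
  n_train <- round(ratio * n)
  if (n_train >= n || n_train < 1) stop("ratio leaves an empty train or test set", call. = FALSE)
  set.seed(seed)
  purrr::map(seq_len(n_splits), function(s) {
    tr <- sort(sample.int(n, n_train))
    tibble::tibble(split = s, train = list(tr), test = list(setdiff(seq_len(n), tr)))
  }) |> dplyr::bind_rows()
}
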