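## Loadings: correlations of measured variables with a composite score,
## z-standardized within tissue, plus set tests against random-draw nulls.

#' Loadings of measured features on a composite score
#'
#' The loading of a feature is its Pearson correlation with the score
#' (bounded by 1 in absolute value); `z_loading` standardizes loadings to
#' mean 0, sd 1 within each tissue (or globally if no tissue annotation),
#' supporting selection rules such as "loadings beyond 2.5 standard
#' deviations". Constant features get loading 0 and are flagged.
#'
#' @param features an [omics_matrix()] (e.g. the tissue-concatenated
#'   transcriptome, or the trait matrix).
#' @param score numeric vector aligned with the rows of `features` (a column
#'   of `hdma_fit$scores`).
#' @return an object of class `loading_vector`: data frame with columns
#'   `feature_id`, `tissue`, `loading`, `z_loading`, `constant_flag`.
#' @export
variable_loadings <- function(features, score) {
  stopifnot(inherits(features, "omics_matrix"))
  X <- features$values
  stopifnot(length(score) == nrow(X))
  if (!is.null(names(score)) && !is.null(rownames(X))) {
    stopifnot(identical(names(score), rownames(X)))
  }
  sds <- apply(X, 2L, stats::sd)
  const <- !is.finite(sds) | sds < 1e-12
  loading <- rep(0, ncol(X))
  if (any(!const)) {
    loading[!const] <- drop(cor(X[, !const, drop = FALSE], score))
  }
  ann <- features$feature_annotations
  tissue <- if (!is.null(ann) && "tissue" %in% names(ann)) {
    as.character(ann$tissue)
  } else rep(NA_character_, ncol(X))
  res <- data.frame(feature_id = colnames(X), tissue = tissue,
                    loading = loading, z_loading = NA_real_,
                    constant_flag = const, stringsAsFactors = FALSE)
  for (tis in unique(tissue)) {
    idx <- if (is.na(tis)) is.na(res$tissue) else !is.na(res$tissue) &
      res$tissue == tis
    l <- res$loading[idx]
    res$z_loading[idx] <- if (length(l) > 1L && stats::sd(l) > 1e-300) {
      (l - mean(l)) / stats::sd(l)
    } else 0
  }
  class(res) <- c("loading_vector", "data.frame")
  res
}

#' Proportion of trait variance captured by a composite score
#'
#' Mean, over traits, of the squared Pearson correlation between each trait
#' and the score. Constant traits are excluded with a warning.
#'
#' @param score numeric vector aligned with the trait matrix rows.
#' @param traits an [omics_matrix()] of traits.
#' @return a single number in `[0, 1]`.
#' @export
variance_explained <- function(score, traits) {
  stopifnot(inherits(traits, "omics_matrix"))
  X <- traits$values
  stopifnot(length(score) == nrow(X))
  sds <- apply(X, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " constant trait(s) excluded", call. = FALSE)
  }
  if (!any(keep)) stop("no non-constant traits")
  r <- drop(cor(X[, keep, drop = FALSE], score))
  mean(r^2)
}

#' Test the mean loading of a feature set against random same-size draws
#'
#' Observed statistic: mean loading over `set_ids` (e.g. marker genes of one
#' cell type). Null: `n_perm` means of random feature sets of the same size
#' drawn without replacement from all features. The two-sided empirical
#' p-value is `(1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param loadings a [variable_loadings()] result.
#' @param set_ids character vector of feature ids, a non-empty subset of
#'   `loadings$feature_id`.
#' @param n_perm number of random draws (at least 99).
#' @param seed integer seed for the draws.
#' @return list with `mean_loading`, `p_value`, `null_means`, `set_size`.
#' @export
marker_set_test <- function(loadings, set_ids, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(loadings, "loading_vector"))
  if (length(set_ids) == 0L) stop("empty feature set")
  if (!all(set_ids %in% loadings$feature_id)) {
    stop("set contains ids absent from the loadings")
  }
  if (n_perm < 99L) stop("n_perm must be at least 99")
  l <- loadings$loading
  obs <- mean(l[loadings$feature_id %in% set_ids])
  k <- sum(loadings$feature_id %in% set_ids)
  null_means <- vapply(seq_len(n_perm), function(i) {
    set.seed(derive_seed(seed, i))
    mean(l[sample.int(length(l), k)])
  }, numeric(1L))
  p <- (1 + sum(abs(null_means) >= abs(obs))) / (n_perm + 1)
  list(mean_loading = obs, p_value = p, null_means = null_means,
       set_size = k)
}

#' Write loadings as TSV
#'
#' @param loadings a [variable_loadings()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(loadings, path) {
  write.table(as.data.frame(loadings), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(path, n_features = nrow(loadings), modality = "loadings")
  invisible(path)
}
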