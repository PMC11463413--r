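## Permutation null for the mediated path coefficient: individual labels on
## the transcriptome are shuffled (genome-phenome pairing intact), the
## transcriptome kernel is rebuilt, and the full HDMA fit is recomputed.

#' One-sided empirical p-value with the add-one rule
#'
#' `(1 + #{null >= observed}) / (length(null) + 1)`, bounded away from zero.
#'
#' @param observed observed statistic (finite scalar).
#' @param null_values non-empty numeric vector of null statistics.
#' @return the empirical p-value.
#' @export
empirical_pvalue <- function(observed, null_values) {
  if (length(null_values) == 0L) stop("null_values is empty")
  if (!is.finite(observed) || any(!is.finite(null_values))) {
    stop("non-finite values in empirical p-value computation")
  }
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}

#' Permutation null distribution of the path coefficient
#'
#' Permutes the individual labels of the transcriptome matrix `n_perm`
#' times. Because feature-wise standardization commutes with row
#' permutation, the kernel of the permuted matrix is exactly the
#' row-and-column permuted kernel of the original matrix, and its
#' eigenvectors are the row-permuted eigenvectors; the implementation uses
#' this identity to rebuild the transcriptome kernel exactly without
#' recomputing its eigendecomposition, then refits HDMA with identical
#' settings for every permutation. Each permutation draws from its own seed
#' stream (`derive_seed(seed, i)`), so results do not depend on execution
#' order.
#'
#' @param K_G,K_P genome and phenome [kernel_matrix()] objects.
#' @param transcriptome the normalized transcriptome [omics_matrix()] (or a
#'   precomputed transcriptome [kernel_matrix()]).
#' @param n_perm number of permutations (at least 99).
#' @param seed master seed.
#' @param rank,tol,max_iter fit settings passed to the HDMA fit (see
#'   [fit_hdma()]).
#' @return object of class `permutation_result`: list with `observed`
#'   (unpermuted path coefficient), `null_values` (length `n_perm`),
#'   `p_value`, `seed`, `n_perm`, and `fit` (the unpermuted `hdma_fit`).
#' @export
permutation_null_path <- function(K_G, transcriptome, K_P, n_perm = 999L,
                                  seed = 1L, rank = NULL, tol = 1e-8,
                                  max_iter = 500L) {
  if (n_perm < 99L) stop("n_perm must be at least 99 (p-value resolution)")
  stopifnot(inherits(K_G, "kernel_matrix"), inherits(K_P, "kernel_matrix"))
  K_T <- if (inherits(transcriptome, "kernel_matrix")) {
    transcriptome
  } else {
    linear_kernel(transcriptome, modality = "transcriptome")
  }
  ids <- K_G$individual_ids
  if (!identical(ids, K_T$individual_ids) ||
      !identical(ids, K_P$individual_ids)) {
    stop("inputs must share the same individuals in the same order")
  }
  n <- length(ids)
  rank_g <- rank %||% choose_rank(K_G)
  rank_t <- rank %||% choose_rank(K_T)
  rank_p <- rank %||% choose_rank(K_P)
  fg <- .kernel_factors(K_G, rank_g)
  ft <- .kernel_factors(K_T, rank_t)
  fp <- .kernel_factors(K_P, rank_p)
  fit0 <- .finalize_hdma_fit(
    .fit_hdma_factors(fg, ft, fp, tol = tol, max_iter = max_iter),
    ids = ids,
    settings = list(rank = c(genome = ncol(fg$U),
                             transcriptome = ncol(ft$U),
                             phenome = ncol(fp$U)),
                    tol = tol, max_iter = max_iter, seed = seed))
  null_values <- vapply(seq_len(n_perm), function(i) {
    set.seed(derive_seed(seed, i))
    perm <- sample.int(n)
    ft_perm <- list(U = ft$U[perm, , drop = FALSE], d = ft$d, n = ft$n)
    f <- .fit_hdma_factors(fg, ft_perm, fp, tol = tol, max_iter = max_iter)
    .path_constrained(f)
  }, numeric(1L))
  structure(list(observed = fit0$path_coefficient,
                 null_values = null_values,
                 p_value = empirical_pvalue(fit0$path_coefficient,
                                            null_values),
                 seed = seed, n_perm = n_perm, fit = fit0),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result>\n")
  cat(sprintf("  observed path coefficient: %.4f\n", x$observed))
  cat(sprintf("  null: n = %d, median %.4f, max %.4f\n", x$n_perm,
              stats::median(x$null_values), max(x$null_values)))
  cat(sprintf("  empirical p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' Write a permutation result (JSON summary + TSV null values)
#'
#' @param x a `permutation_result`.
#' @param json_path output JSON path (observed, p_value, n_perm, seed).
#' @param null_path output TSV path for the null path coefficients.
#' @return invisibly, the two paths.
#' @export
write_permutation_result <- function(x, json_path, null_path) {
  stopifnot(inherits(x, "permutation_result"))
  jsonlite::write_json(list(observed = x$observed, p_value = x$p_value,
                            n_perm = x$n_perm, seed = x$seed),
                       json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write.table(data.frame(null_path_coefficient = x$null_values), null_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(json = json_path, nulls = null_path))
}
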