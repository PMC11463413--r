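## Per-feature normalization and covariate adjustment applied to expression
## and phenotype matrices before kernel construction.

#' Rank-based inverse normal transform
#'
#' Maps a numeric vector to normal quantiles of its mid-ranks,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. The result is
#' invariant under any strictly monotone transform of the input and has mean
#' (numerically) zero. A constant input is degenerate: every value gets the
#' median rank, so the output is all zeros, with a warning.
#'
#' @param x numeric vector, length at least 2.
#' @return numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (anyNA(x)) stop("missing values not allowed; resolve missingness first")
  if (stats::sd(x) < 1e-300) {
    warning("constant input: rank-inverse-normal output is all zeros",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

#' Apply the rank-inverse-normal transform to every feature of a matrix
#'
#' @param x an [omics_matrix()].
#' @return an [omics_matrix()] with each column transformed independently.
#' @export
normalize_features <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  x$values <- apply(x$values, 2L, rank_inverse_normal)
  x
}

#' Residualize features on covariates
#'
#' Replaces every column of `x` by its least-squares residual on an
#' intercept plus the covariate columns. Residual columns are orthogonal to
#' each covariate and mean-centered.
#'
#' @param x an [omics_matrix()].
#' @param covariates a [covariate_table()] covering the same individuals
#'   (order is matched by id).
#' @return an [omics_matrix()] of residuals.
#' @export
adjust_covariates <- function(x, covariates) {
  stopifnot(inherits(x, "omics_matrix"), inherits(covariates, "covariate_table"))
  ids <- rownames(x$values)
  if (!all(ids %in% covariates$individual_ids)) {
    stop("covariate table does not cover all individuals in the matrix")
  }
  C <- covariates$covariates[match(ids, covariates$individual_ids), ,
                             drop = FALSE]
  X <- cbind(1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("covariate design is rank deficient after alignment")
  }
  feat <- colnames(x$values)
  x$values <- qr.resid(qrX, x$values)
  dimnames(x$values) <- list(ids, feat)
  x
}
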