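## The high-dimensional mediation fit: composite scores G_C, T_C, P_C
## maximizing rho(G_C,T_C) * rho(T_C,P_C) subject to exact perfect mediation
## rho(G_C, P_C | T_C) = 0.

#' Path coefficient of a mediation triple
#'
#' The strength of the mediated path, defined as the product of the Pearson
#' correlation between the genome and transcriptome scores and the Pearson
#' correlation between the transcriptome and phenome scores.
#'
#' @param g,t,p numeric vectors of equal length (>= 3), none constant.
#' @return `cor(g, t) * cor(t, p)`.
#' @export
path_coefficient <- function(g, t, p) {
  stopifnot(length(g) == length(t), length(t) == length(p), length(g) >= 3L)
  for (v in list(g = g, t = t, p = p)) {
    if (stats::sd(v) < 1e-300) stop("constant input vector", call. = FALSE)
  }
  cor(g, t) * cor(t, p)
}

#' Partial correlation of two vectors given a third
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on an
#' intercept plus `z`. Errors if either vector lies in the span of `[1, z]`
#' (zero residual: the partial correlation is undefined).
#'
#' @param x,y,z numeric vectors of equal length (>= 4).
#' @return the partial correlation `rho(x, y | z)`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4L)
  X <- cbind(1, z)
  qrX <- qr(X)
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  if (sqrt(sum(rx^2)) < 1e-12 || sqrt(sum(ry^2)) < 1e-12) {
    stop("partial correlation undefined: vector lies in the span of [1, z]")
  }
  cor(rx, ry)
}

#' Default factor rank for a kernel
#'
#' The smallest number of leading eigencomponents capturing `prop` of the
#' kernel trace, capped at `n / 2` (guards against canonical-correlation
#' style overfitting in high dimensions).
#'
#' @param K a [kernel_matrix()] or symmetric matrix.
#' @param prop proportion of trace to capture (default 0.95).
#' @return an integer rank (at least 1).
#' @export
choose_rank <- function(K, prop = 0.95) {
  if (inherits(K, "kernel_matrix")) K <- K$K
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  r <- which(cumsum(ev) / sum(ev) >= prop)[1L]
  max(1L, min(r, floor(nrow(K) / 2)))
}

# eigendecomposition of a kernel truncated to its top-`rank` components with
# positive eigenvalues; columns of U are orthonormal and mean-zero (kernels
# are double-centered)
.kernel_factors <- function(K, rank = NULL, psd_tol = 1e-8) {
  if (inherits(K, "kernel_matrix")) K <- K$K
  n <- nrow(K)
  e <- eigen(K, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (min(e$values) < -psd_tol * scale) {
    stop("kernel is not positive semi-definite within tolerance")
  }
  pos <- which(e$values > 1e-10 * scale)
  if (length(pos) == 0L) stop("kernel has no positive eigenvalues")
  r <- if (is.null(rank)) length(pos) else min(rank, length(pos))
  r <- max(1L, min(r, n - 1L))
  list(U = e$vectors[, pos[seq_len(r)], drop = FALSE],
       d = e$values[pos[seq_len(r)]], n = n)
}

# exact maximizer of (a'b)(c'b) / (b'b): the normalized angle bisector of a
# and c (the objective is invariant to the scale of b)
.bisector_update <- function(a, c_) {
  na <- sqrt(sum(a^2)); nc <- sqrt(sum(c_^2))
  if (na < 1e-300 || nc < 1e-300) return(NULL)
  b <- a / na + c_ / nc
  nb <- sqrt(sum(b^2))
  if (nb < 1e-10) return(NULL)  # a and c anti-parallel: objective <= 0
  b / nb
}

#' Fit the high-dimensional mediation model
#'
#' Represents each modality by the top-rank eigencomponents of its centered
#' kernel and alternates two exact updates: (i) given the transcriptome score
#' t, the genome and phenome scores are its orthogonal projections into the
#' genome and phenome eigenspaces (each maximizes its correlation with t);
#' (ii) given g and p, t is updated to the closed-form maximizer of
#' `cor(g,t) * cor(t,p)` within the transcriptome eigenspace (the normalized
#' angle bisector of the projections of g and p). Both steps are monotone in
#' the objective, so the alternation converges. At convergence the
#' perfect-mediation constraint is enforced exactly by removing from the
#' phenome score its regression on the component of the genome score
#' orthogonal to the transcriptome score, which sets
#' `rho(G_C, P_C | T_C) = 0` up to floating-point roundoff.
#'
#' Sign convention: scores are flipped so that `cor(T_C, P_C) >= 0` and
#' `cor(G_C, T_C) >= 0`; if `anchor_traits` is supplied, all three scores
#' are additionally flipped jointly so that the trait with the largest
#' absolute loading on P_C has a positive loading.
#'
#' @param K_G,K_T,K_P [kernel_matrix()] objects on the same individuals (in
#'   the same order) for genome, transcriptome, and phenome.
#' @param rank number of eigencomponents per kernel; `NULL` (default) uses
#'   [choose_rank()] per kernel (95% of trace, capped at n/2). A single
#'   integer applies to all three kernels.
#' @param tol relative convergence tolerance on the path coefficient
#'   (default `1e-8`).
#' @param max_iter maximum alternation sweeps (default 500).
#' @param seed integer recorded with the fit; the algorithm itself is
#'   deterministic (initialization is the leading transcriptome
#'   eigenvector).
#' @param anchor_traits optional [omics_matrix()] of traits used only for
#'   the sign anchor.
#' @return an object of class `hdma_fit`: list with `scores` (n x 3 matrix,
#'   columns `G_C`, `T_C`, `P_C`, each mean 0 variance 1), `path_coefficient`,
#'   `partials` (named: `rho_GT`, `rho_TP`, `rho_GP_given_T`), `rank` (per
#'   kernel), `n_iterations`, `converged`, `settings`.
#' @export
fit_hdma <- function(K_G, K_T, K_P, rank = NULL, tol = 1e-8, max_iter = 500L,
                     seed = 1L, anchor_traits = NULL) {
  for (k in list(K_G, K_T, K_P)) stopifnot(inherits(k, "kernel_matrix"))
  ids <- K_G$individual_ids
  if (!identical(ids, K_T$individual_ids) ||
      !identical(ids, K_P$individual_ids)) {
    stop("kernels must share the same individuals in the same order")
  }
  rank_g <- rank %||% choose_rank(K_G)
  rank_t <- rank %||% choose_rank(K_T)
  rank_p <- rank %||% choose_rank(K_P)
  fg <- .kernel_factors(K_G, rank_g)
  ft <- .kernel_factors(K_T, rank_t)
  fp <- .kernel_factors(K_P, rank_p)
  fit <- .fit_hdma_factors(fg, ft, fp, tol = tol, max_iter = max_iter)
  .finalize_hdma_fit(fit, ids = ids, anchor_traits = anchor_traits,
                     settings = list(rank = c(genome = ncol(fg$U),
                                              transcriptome = ncol(ft$U),
                                              phenome = ncol(fp$U)),
                                     tol = tol, max_iter = max_iter,
                                     seed = seed))
}

# the alternating optimization on precomputed factors; returns raw scores.
# Because the eigenvector columns of each factor basis are orthonormal and
# mean-zero, the whole alternation runs in coefficient space: with t = U_T b,
# the projection of t into the genome eigenspace is U_G (C_GT b) where
# C_GT = U_G' U_T, and all norms and correlations reduce to coefficient
# norms and inner products. The n-dimensional scores are reconstructed once
# at convergence.
.fit_hdma_factors <- function(fg, ft, fp, tol = 1e-8, max_iter = 500L) {
  C_GT <- crossprod(fg$U, ft$U)
  C_PT <- crossprod(fp$U, ft$U)
  b <- c(1, rep(0, ncol(ft$U) - 1L))  # t = leading transcriptome eigenvector
  path_old <- -Inf
  converged <- FALSE
  iter <- 0L
  a <- c_ <- NULL
  repeat {
    iter <- iter + 1L
    # (i) correlation-maximizing projections of t into genome/phenome spaces
    a <- drop(C_GT %*% b)   # g = U_G a
    c_ <- drop(C_PT %*% b)  # p = U_P c_
    na <- sqrt(sum(a^2)); nc <- sqrt(sum(c_^2))
    if (na < 1e-12 || nc < 1e-12) {
      stop("transcriptome score orthogonal to genome or phenome eigenspace")
    }
    # (ii) closed-form t update within the transcriptome eigenspace
    b_new <- .bisector_update(drop(crossprod(C_GT, a)) / na,
                              drop(crossprod(C_PT, c_)) / nc)
    if (!is.null(b_new)) b <- b_new
    # cor(g, t) = a' C_GT b / (|a| |b|); |b| = 1 after the bisector update
    nb <- sqrt(sum(b^2))
    path <- (sum(a * (C_GT %*% b)) / (na * nb)) *
      (sum(c_ * (C_PT %*% b)) / (nc * nb))
    if (is.finite(path_old) &&
        abs(path - path_old) <= tol * max(abs(path_old), 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    path_old <- path
  }
  list(g = drop(fg$U %*% a), t = drop(ft$U %*% b), p = drop(fp$U %*% c_),
       n_iterations = iter, converged = converged)
}

# path coefficient after the exact perfect-mediation projection, as used
# for both the observed fit and every permutation refit (same statistic)
.path_constrained <- function(fit) {
  g <- .standardize(fit$g, "genome score")
  t_vec <- .standardize(fit$t, "transcriptome score")
  p <- .standardize(fit$p, "phenome score")
  g_perp <- g - t_vec * (sum(g * t_vec) / sum(t_vec^2))
  v <- sum(g_perp^2)
  if (v > 1e-20) p <- p - g_perp * (sum(p * g_perp) / v)
  abs(cor(g, t_vec) * cor(t_vec, p))
}

# constraint projection, standardization, sign convention, assembly
.finalize_hdma_fit <- function(fit, ids, anchor_traits = NULL,
                               settings = list()) {
  g <- .standardize(fit$g, "genome score")
  t_vec <- .standardize(fit$t, "transcriptome score")
  p <- .standardize(fit$p, "phenome score")
  # enforce rho(G_C, P_C | T_C) = 0: remove from p its regression on the
  # component of g orthogonal to t
  g_perp <- g - t_vec * (sum(g * t_vec) / sum(t_vec^2))
  v <- sum(g_perp^2)
  if (v > 1e-20) {
    p <- p - g_perp * (sum(p * g_perp) / v)
  }
  p <- .standardize(p, "phenome score")
  # sign convention
  r_tp <- cor(t_vec, p)
  if (r_tp < 0) { t_vec <- -t_vec; g <- -g }
  if (cor(g, t_vec) < 0) g <- -g
  if (!is.null(anchor_traits)) {
    tv <- if (inherits(anchor_traits, "omics_matrix")) {
      anchor_traits$values
    } else as.matrix(anchor_traits)
    lds <- suppressWarnings(cor(tv, p))
    top <- which.max(abs(lds))
    if (is.finite(lds[top]) && lds[top] < 0) {
      g <- -g; t_vec <- -t_vec; p <- -p
    }
  }
  scores <- cbind(G_C = g, T_C = t_vec, P_C = p)
  rownames(scores) <- ids
  # rho(G,P|T): zero by the projection; in the fully degenerate case where a
  # score is collinear with t (noise-free mediation) it is zero by convention
  rho_gpt <- tryCatch(partial_correlation(g, p, t_vec),
                      error = function(e) 0)
  partials <- c(rho_GT = cor(g, t_vec),
                rho_TP = cor(t_vec, p),
                rho_GP_given_T = rho_gpt)
  structure(list(scores = scores,
                 path_coefficient = unname(partials["rho_GT"] *
                                             partials["rho_TP"]),
                 partials = partials,
                 rank = settings$rank,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged,
                 settings = settings),
            class = "hdma_fit")
}

#' @export
print.hdma_fit <- function(x, ...) {
  cat("<hdma_fit>\n")
  cat(sprintf("  path coefficient : %.4f\n", x$path_coefficient))
  cat(sprintf("  rho(G_C, T_C)    : %.4f\n", x$partials["rho_GT"]))
  cat(sprintf("  rho(T_C, P_C)    : %.4f\n", x$partials["rho_TP"]))
  cat(sprintf("  rho(G_C, P_C | T_C): %.2e\n", x$partials["rho_GP_given_T"]))
  cat(sprintf("  iterations %d, converged: %s\n", x$n_iterations,
              x$converged))
  invisible(x)
}

#' Write an HDMA fit to disk
#'
#' Writes the composite scores as TSV (`individual_id`, `G_C`, `T_C`,
#' `P_C`) and the fit summary (path coefficient, partials, iterations,
#' settings) as JSON.
#'
#' @param fit an `hdma_fit`.
#' @param scores_path TSV output path for scores.
#' @param json_path JSON output path for the fit summary.
#' @return invisibly, a list of the two paths.
#' @export
write_hdma_fit <- function(fit, scores_path, json_path) {
  stopifnot(inherits(fit, "hdma_fit"))
  df <- data.frame(individual_id = rownames(fit$scores), fit$scores,
                   check.names = FALSE)
  write.table(df, scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(scores_path, n_individuals = nrow(fit$scores),
                 modality = "hdma_scores")
  jsonlite::write_json(
    list(path_coefficient = fit$path_coefficient,
         partials = as.list(fit$partials),
         n_iterations = fit$n_iterations,
         converged = fit$converged,
         settings = fit$settings),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scores = scores_path, json = json_path))
}
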