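## Local/distal partitioning of transcript heritability: split the kinship
## at a transcript's locus into a local window and the rest of the genome,
## then fit y ~ N(0, s2 * (hl*K_local + hd*K_distal + (1-hl-hd)*I)) by REML.
##
## Parameterization: (w, h) with hl = w*h, hd = (1-w)*h. For fixed w one
## eigendecomposition of Kw = w*K_local + (1-w)*K_distal makes the profile
## over h a cheap 1-d optimization (rotated residuals), and the
## eigendecompositions are shared across all transcripts fit on the same
## kernel pair. The w grid (step `w_step`, default 0.01) is refined by
## quadratic interpolation of the profile likelihood.

#' Split kinship into local and distal components around a locus
#'
#' Local: markers on the locus chromosome within `window_bp` of the TSS
#' (closed interval). Distal: every other marker. The two marker sets
#' partition the map.
#'
#' @param dosages a [haplotype_dosages()] object.
#' @param chrom chromosome label of the locus.
#' @param tss_bp transcription start position (1-based bp).
#' @param window_bp half-width of the local window in bp (default 10 Mb).
#' @return list with `K_local` and `K_distal` ([kernel_matrix()] objects)
#'   and the local marker ids (`local_markers`).
#' @export
split_kinship <- function(dosages, chrom, tss_bp, window_bp = 10e6) {
  stopifnot(inherits(dosages, "haplotype_dosages"))
  map <- dosages$marker_map
  local <- map$chrom == as.character(chrom) &
    map$pos_bp >= tss_bp - window_bp & map$pos_bp <= tss_bp + window_bp
  if (!any(local)) {
    stop(sprintf("no markers within %.3g bp of %s:%d", window_bp,
                 chrom, as.integer(tss_bp)))
  }
  if (all(local)) stop("no markers outside the local window")
  list(K_local = genome_kernel(dosages, markers = map$marker[local]),
       K_distal = genome_kernel(dosages, markers = map$marker[!local]),
       local_markers = map$marker[local])
}

# REML log-likelihood (up to a constant) of y with covariance
# s2 * (h * Kw + (1 - h) * I), given the eigendecomposition of Kw.
# yt, xt: eigenvector-rotated response and intercept.
.reml_ll <- function(h, lambda, yt, xt, n) {
  d <- h * lambda + (1 - h)
  d <- pmax(d, 1e-12)
  xx <- sum(xt^2 / d)
  beta <- sum(xt * yt / d) / xx
  rss <- sum((yt - xt * beta)^2 / d)
  -0.5 * (sum(log(d)) + log(xx) + (n - 1) * log(rss))
}

#' Two-component (local + distal) REML heritability fit
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(mu, s2 * (hl * K_local + hd * K_distal + (1 - hl - hd) * I))`
#' over the simplex `hl, hd >= 0`, `hl + hd <= 1`. Kinships are rescaled to
#' mean diagonal 1 before fitting, and `y` is rank-inverse-normalized when
#' `normalize = TRUE` (default), so the estimates are variance ratios
#' invariant to the scale of `y`. `y` may be a matrix (one column per
#' transcript sharing the same kernel pair); the per-`w`
#' eigendecompositions are then computed once and shared.
#'
#' If the two kinships are numerically indistinguishable (off-diagonal
#' correlation above 0.999) only the total heritability is identified; the
#' total is split evenly between the two components and the fit is flagged
#' `non_identifiable`.
#'
#' @param y numeric vector or matrix (individuals x transcripts).
#' @param K_local,K_distal [kernel_matrix()] objects (or plain symmetric
#'   matrices) on the same individuals as `y`.
#' @param w_step grid step for the local share `w = hl / (hl + hd)`
#'   (default 0.01).
#' @param normalize rank-inverse-normalize `y` first (default `TRUE`).
#' @param refine quadratic-interpolation refinement of `w` around the grid
#'   optimum (default `TRUE`).
#' @return a data frame of class `heritability_estimate` with one row per
#'   column of `y`: `feature_id`, `h2_local`, `h2_distal`, `residual`,
#'   `loglik`, `boundary_flag`.
#' @export
fit_two_component <- function(y, K_local, K_distal, w_step = 0.01,
                              normalize = TRUE, refine = TRUE) {
  Y <- as.matrix(y)
  if (is.null(colnames(Y))) {
    colnames(Y) <- if (ncol(Y) == 1L) "y" else paste0("y", seq_len(ncol(Y)))
  }
  Kl <- if (inherits(K_local, "kernel_matrix")) K_local$K else K_local
  Kd <- if (inherits(K_distal, "kernel_matrix")) K_distal$K else K_distal
  n <- nrow(Y)
  stopifnot(nrow(Kl) == n, nrow(Kd) == n)
  # standardize kinships to mean diagonal 1
  Kl <- Kl / mean(diag(Kl))
  Kd <- Kd / mean(diag(Kd))
  off <- upper.tri(Kl)
  non_ident <- isTRUE(suppressWarnings(cor(Kl[off], Kd[off])) > 0.999)
  if (normalize) Y <- apply(Y, 2L, rank_inverse_normal)
  for (j in seq_len(ncol(Y))) {
    if (stats::sd(Y[, j]) < 1e-300) stop("y column ", j, " is constant")
  }
  ones <- rep(1, n)

  fit_at_w <- function(w) {
    Kw <- w * Kl + (1 - w) * Kd
    e <- eigen(Kw, symmetric = TRUE)
    lambda <- pmax(e$values, 0)
    Yt <- crossprod(e$vectors, Y)
    xt <- drop(crossprod(e$vectors, ones))
    t(vapply(seq_len(ncol(Y)), function(j) {
      opt <- optimize(.reml_ll, interval = c(0, 1 - 1e-6), lambda = lambda,
                      yt = Yt[, j], xt = xt, n = n, maximum = TRUE,
                      tol = 1e-6)
      # check the h = 0 boundary explicitly (optimize can miss endpoints)
      ll0 <- .reml_ll(0, lambda, Yt[, j], xt, n)
      if (ll0 > opt$objective) c(0, ll0) else
        c(opt$maximum, opt$objective)
    }, numeric(2L)))
  }

  if (non_ident) {
    res <- fit_at_w(0.5)
    out <- data.frame(feature_id = colnames(Y),
                      h2_local = res[, 1L] / 2, h2_distal = res[, 1L] / 2,
                      residual = 1 - res[, 1L], loglik = res[, 2L],
                      boundary_flag = "non_identifiable",
                      stringsAsFactors = FALSE)
    class(out) <- c("heritability_estimate", "data.frame")
    return(out)
  }

  w_grid <- seq(0, 1, by = w_step)
  grid_fits <- lapply(w_grid, fit_at_w)  # each: ncol(Y) x 2 (h, ll)
  ll_mat <- vapply(grid_fits, function(m) m[, 2L], numeric(ncol(Y)))
  ll_mat <- matrix(ll_mat, nrow = ncol(Y))
  out <- do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
    lls <- ll_mat[j, ]
    best <- which.max(lls)
    w_hat <- w_grid[best]
    h_hat <- grid_fits[[best]][j, 1L]
    ll_hat <- lls[best]
    if (refine && best > 1L && best < length(w_grid)) {
      # quadratic interpolation through the three grid points around the max
      l1 <- lls[best - 1L]; l2 <- lls[best]; l3 <- lls[best + 1L]
      denom <- l1 - 2 * l2 + l3
      if (is.finite(denom) && denom < -1e-12) {
        w_ref <- w_hat + w_step * 0.5 * (l1 - l3) / denom
        w_ref <- min(max(w_ref, w_grid[best - 1L]), w_grid[best + 1L])
        ref <- fit_at_w(w_ref)
        if (ref[j, 2L] >= ll_hat) {
          w_hat <- w_ref; h_hat <- ref[j, 1L]; ll_hat <- ref[j, 2L]
        }
      }
    }
    hl <- w_hat * h_hat; hd <- (1 - w_hat) * h_hat
    flag <- if (h_hat < 1e-3 || h_hat > 1 - 1e-4 ||
                (h_hat > 1e-3 && (w_hat <= 0 || w_hat >= 1))) {
      "boundary"
    } else "interior"
    data.frame(feature_id = colnames(Y)[j], h2_local = hl, h2_distal = hd,
               residual = 1 - hl - hd, loglik = ll_hat,
               boundary_flag = flag, stringsAsFactors = FALSE)
  }))
  class(out) <- c("heritability_estimate", "data.frame")
  out
}

#' Local/distal heritability scan over annotated transcripts
#'
#' For each transcript, splits the kinship around its TSS with
#' [split_kinship()] and fits [fit_two_component()]. Transcripts are grouped
#' by locus (chromosome, TSS) so that kernel construction and
#' eigendecompositions are shared; results are returned in the input
#' transcript order and do not depend on grouping.
#'
#' @param expression an [omics_matrix()] with feature annotations carrying
#'   `chrom` and `tss_bp` (and optionally `tissue`).
#' @param dosages a [haplotype_dosages()] object on the same individuals.
#' @param window_bp local window half-width in bp (default 10 Mb).
#' @param ... passed to [fit_two_component()].
#' @return a `heritability_estimate` data frame with one row per transcript
#'   (plus `tissue` if annotated).
#' @export
scan_heritability <- function(expression, dosages, window_bp = 10e6, ...) {
  stopifnot(inherits(expression, "omics_matrix"),
            inherits(dosages, "haplotype_dosages"))
  ann <- expression$feature_annotations
  if (is.null(ann) || !all(c("chrom", "tss_bp") %in% names(ann))) {
    stop("expression must carry feature annotations with chrom and tss_bp")
  }
  stopifnot(identical(rownames(expression$values), dosages$individual_ids))
  locus <- paste(ann$chrom, ann$tss_bp, sep = ":")
  pieces <- lapply(split(seq_len(ncol(expression$values)), locus),
                   function(idx) {
    ks <- split_kinship(dosages, ann$chrom[idx[1L]], ann$tss_bp[idx[1L]],
                        window_bp = window_bp)
    est <- fit_two_component(expression$values[, idx, drop = FALSE],
                             ks$K_local, ks$K_distal, ...)
    est$.col <- idx
    est
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$.col), , drop = FALSE]
  out$.col <- NULL
  rownames(out) <- NULL
  if ("tissue" %in% names(ann)) out$tissue <- ann$tissue
  class(out) <- c("heritability_estimate", "data.frame")
  out
}

#' Trait relevance of each transcript
#'
#' Maximum absolute Pearson correlation between the transcript and any
#' measured trait. Constant transcripts get relevance 0 (flagged with an
#' attribute).
#'
#' @param expression an [omics_matrix()] of transcripts.
#' @param traits an [omics_matrix()] of traits on the same individuals.
#' @return numeric vector named by transcript, in `[0, 1]`; constant
#'   transcripts are listed in `attr(, "constant_features")`.
#' @export
trait_relevance <- function(expression, traits) {
  stopifnot(inherits(expression, "omics_matrix"),
            inherits(traits, "omics_matrix"))
  X <- expression$values; P <- traits$values
  stopifnot(nrow(X) == nrow(P))
  sds <- apply(X, 2L, stats::sd)
  const <- !is.finite(sds) | sds < 1e-12
  rel <- rep(0, ncol(X))
  names(rel) <- colnames(X)
  if (any(!const)) {
    cc <- abs(cor(X[, !const, drop = FALSE], P))
    rel[!const] <- apply(cc, 1L, max)
  }
  attr(rel, "constant_features") <- colnames(X)[const]
  rel
}

#' Correlation between a heritability component and trait relevance
#'
#' Pearson correlation (with two-sided p-value) between the chosen
#' heritability component and transcript trait relevance, over transcripts.
#'
#' @param h2 a `heritability_estimate` data frame (or numeric vector of the
#'   component values).
#' @param relevance numeric vector from [trait_relevance()], same transcript
#'   order.
#' @param component `"local"` or `"distal"` (ignored if `h2` is a vector).
#' @return list with `r` (correlation) and `p` (two-sided p-value).
#' @export
relevance_heritability_correlation <- function(h2, relevance,
                                               component = c("local",
                                                             "distal")) {
  x <- if (is.data.frame(h2)) {
    component <- match.arg(component)
    h2[[paste0("h2_", component)]]
  } else as.numeric(h2)
  if (length(x) < 10L) stop("need at least 10 transcripts")
  stopifnot(length(x) == length(relevance))
  if (stats::sd(x) < 1e-300 || stats::sd(relevance) < 1e-300) {
    stop("zero-variance input")
  }
  ct <- cor.test(x, as.numeric(relevance))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Write heritability estimates as TSV
#'
#' @param h2 a `heritability_estimate` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_heritability <- function(h2, path) {
  write.table(as.data.frame(h2), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(path, n_features = nrow(h2), modality = "heritability")
  invisible(path)
}
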