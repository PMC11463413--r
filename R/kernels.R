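## Centered linear kernels: one individual-by-individual similarity matrix
## per modality. All downstream mediation machinery operates on these.

#' Kernel matrix container
#'
#' @param K symmetric n x n numeric matrix with individual ids as dimnames.
#' @param modality label, typically one of `"genome"`, `"transcriptome"`,
#'   `"phenome"`.
#' @param individual_ids optional ids (default: rownames of `K`).
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(K, modality = "kernel", individual_ids = NULL) {
  K <- as.matrix(K)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(K) %||% paste0("ind", seq_len(nrow(K)))
  }
  dimnames(K) <- list(individual_ids, individual_ids)
  obj <- structure(list(K = K, modality = modality,
                        individual_ids = as.character(individual_ids)),
                   class = "kernel_matrix")
  validate_kernel(obj)
  obj
}

#' Validate a kernel matrix
#'
#' Checks symmetry (within `1e-10`) and positive semi-definiteness
#' (smallest eigenvalue at least `-tol` relative to the largest).
#'
#' @param x a [kernel_matrix()].
#' @param tol PSD tolerance (default `1e-8`).
#' @return `x`, invisibly.
#' @export
validate_kernel <- function(x, tol = 1e-8) {
  K <- x$K
  if (nrow(K) != ncol(K)) stop("kernel must be square")
  if (max(abs(K - t(K))) > 1e-10) stop("kernel is not symmetric within 1e-10")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tol * scale) {
    stop("kernel is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(x)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix: %s> %d x %d, trace %.3f\n",
              x$modality, nrow(x$K), ncol(x$K), sum(diag(x$K))))
  invisible(x)
}

# double-center (rows and columns sum to zero) and scale to trace = n
.center_and_normalize <- function(K) {
  n <- nrow(K)
  J <- diag(n) - matrix(1 / n, n, n)
  K <- J %*% K %*% J
  K <- (K + t(K)) / 2
  tr <- sum(diag(K))
  if (tr < 1e-12) stop("kernel has (numerically) zero trace after centering")
  K * (n / tr)
}

#' Linear kernel of an individuals-by-features matrix
#'
#' Columns are standardized to mean 0 and unit variance (constant columns
#' dropped with a warning), the cross-product `Z Z' / m` is formed, and the
#' result is double-centered and trace-normalized to `trace = n` so that
#' kernels from different modalities are on a common scale.
#'
#' @param x an [omics_matrix()] or a plain numeric matrix (individuals x
#'   features) with at least 2 individuals and one non-constant feature.
#' @param modality label for the resulting kernel.
#' @return a [kernel_matrix()].
#' @export
linear_kernel <- function(x, modality = "kernel") {
  X <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  if (nrow(X) < 2L) stop("need at least 2 individuals")
  Z <- .standardize_columns(X)
  K <- tcrossprod(Z) / ncol(Z)
  K <- .center_and_normalize(K)
  dimnames(K) <- list(rownames(X) %||% paste0("ind", seq_len(nrow(X))),
                      rownames(X) %||% paste0("ind", seq_len(nrow(X))))
  kernel_matrix(K, modality = modality)
}

#' Genome kernel from founder-haplotype dosages
#'
#' Unfolds the dosage array to individuals x (markers * founders), optionally
#' excludes a genomic interval (closed, 1-based bp), and applies
#' [linear_kernel()]. The exclusion option supports building "distal"
#' kinship matrices that omit the neighborhood of a locus.
#'
#' @param dosages a [haplotype_dosages()] object.
#' @param exclude optional list with elements `chrom`, `start_bp`, `end_bp`;
#'   markers on `chrom` with `start_bp <= pos_bp <= end_bp` are dropped.
#' @param markers optional character vector restricting to a marker subset
#'   (applied before `exclude`).
#' @return a [kernel_matrix()] with modality `"genome"`.
#' @export
genome_kernel <- function(dosages, exclude = NULL, markers = NULL) {
  stopifnot(inherits(dosages, "haplotype_dosages"))
  map <- dosages$marker_map
  keep <- rep(TRUE, nrow(map))
  if (!is.null(markers)) keep <- keep & map$marker %in% markers
  if (!is.null(exclude) && length(exclude) > 0L) {
    stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(exclude)))
    inside <- map$chrom == exclude$chrom &
      map$pos_bp >= exclude$start_bp & map$pos_bp <= exclude$end_bp
    keep <- keep & !inside
  }
  if (!any(keep)) stop("no markers retained after exclusion/subsetting")
  d <- dosages$dosages[, keep, , drop = FALSE]
  n <- dim(d)[1L]
  X <- matrix(d, nrow = n)  # unfold markers x founders into columns
  rownames(X) <- dosages$individual_ids
  suppressWarnings(linear_kernel(X, modality = "genome"))
}

#' Concatenate per-tissue expression matrices feature-wise
#'
#' Joins tissues on the shared individual set, qualifying feature ids as
#' `<tissue>:<feature>`. With column standardization inside
#' [linear_kernel()], the kernel of the concatenation equals the
#' feature-count-weighted average of the per-tissue kernels.
#'
#' @param tissue_matrices named list of [omics_matrix()] objects on the same
#'   individuals (names are tissue labels).
#' @return a single [omics_matrix()] with tissue-qualified feature ids and a
#'   `tissue` column in its annotations.
#' @export
concat_tissues <- function(tissue_matrices) {
  stopifnot(is.list(tissue_matrices), length(tissue_matrices) >= 1L)
  if (is.null(names(tissue_matrices)) || any(names(tissue_matrices) == "")) {
    stop("tissue_matrices must be a fully named list (names = tissue labels)")
  }
  ids <- rownames(tissue_matrices[[1L]]$values)
  blocks <- lapply(names(tissue_matrices), function(tis) {
    m <- tissue_matrices[[tis]]
    stopifnot(inherits(m, "omics_matrix"))
    if (!identical(sort(rownames(m$values)), sort(ids))) {
      stop("tissue '", tis, "' does not share the aligned individual set")
    }
    v <- m$values[ids, , drop = FALSE]
    colnames(v) <- paste0(tis, ":", colnames(v))
    v
  })
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values))) {
    stop("clashing feature ids after tissue qualification")
  }
  ann_list <- lapply(names(tissue_matrices), function(tis) {
    m <- tissue_matrices[[tis]]
    a <- m$feature_annotations
    if (is.null(a)) {
      a <- data.frame(feature_id = colnames(m$values),
                      stringsAsFactors = FALSE)
    }
    a$tissue <- tis
    a$feature_id <- paste0(tis, ":", colnames(m$values))
    a
  })
  common <- Reduce(intersect, lapply(ann_list, names))
  ann <- do.call(rbind, lapply(ann_list, function(a) {
    a[, common, drop = FALSE]
  }))
  omics_matrix(values, feature_annotations = ann, modality = "expression")
}

#' Write a kernel matrix as dense TSV
#'
#' @param x a [kernel_matrix()].
#' @param path output path; individual ids become header and first column.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(x, path) {
  stopifnot(inherits(x, "kernel_matrix"))
  df <- data.frame(individual_id = x$individual_ids, x$K, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(path, n_individuals = nrow(x$K), modality = x$modality)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel()]
#'
#' @param path TSV path.
#' @param modality label to attach.
#' @return a [kernel_matrix()].
#' @export
read_kernel <- function(path, modality = "kernel") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1L, drop = FALSE])
  rownames(K) <- as.character(df$individual_id)
  K <- (K + t(K)) / 2  # text round-trips can break symmetry in the last digit
  kernel_matrix(K, modality = modality)
}
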