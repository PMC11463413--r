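## S3 containers for the three data modalities and derived objects.
## Kept deliberately lightweight (lists of base objects with validators),
## in the style of multiparent-population genetics packages.

#' Founder-haplotype dosage array
#'
#' Represents expected founder-haplotype counts (0--2) for each individual at
#' each marker, as produced upstream by haplotype reconstruction in a
#' multiparent population (e.g. eight-founder Diversity Outbred mice). The
#' dosages across founders sum to 2 at every marker (diploid).
#'
#' @param dosages numeric array, individuals x markers x founders, entries in
#'   `[0, 2]`.
#' @param marker_map data frame with columns `marker`, `chrom`, `pos_bp`
#'   (1-based physical position); rows in marker order, positions strictly
#'   increasing within each chromosome.
#' @param individual_ids character vector of unique individual identifiers.
#' @return an object of class `haplotype_dosages` with elements
#'   `individual_ids`, `marker_map`, `dosages` (dimnames set).
#' @export
haplotype_dosages <- function(dosages, marker_map, individual_ids = NULL) {
  if (length(dim(dosages)) != 3L) {
    stop("`dosages` must be a 3-d array (individuals x markers x founders)")
  }
  if (is.null(individual_ids)) {
    individual_ids <- dimnames(dosages)[[1L]] %||%
      paste0("ind", seq_len(dim(dosages)[1L]))
  }
  stopifnot(is.data.frame(marker_map),
            all(c("marker", "chrom", "pos_bp") %in% names(marker_map)))
  marker_map$marker <- as.character(marker_map$marker)
  marker_map$chrom <- as.character(marker_map$chrom)
  dimnames(dosages) <- list(individual_ids, marker_map$marker,
                            dimnames(dosages)[[3L]] %||%
                              paste0("F", seq_len(dim(dosages)[3L])))
  obj <- structure(list(individual_ids = as.character(individual_ids),
                        marker_map = marker_map,
                        dosages = dosages),
                   class = "haplotype_dosages")
  validate_haplotype_dosages(obj)
  obj
}

#' Validate a haplotype_dosages object
#'
#' Checks the diploid constraint (founder dosages sum to 2 within `tol` at
#' every individual x marker), strictly increasing positions within each
#' chromosome, and at least two founders.
#'
#' @param x a [haplotype_dosages()] object.
#' @param tol tolerance on the diploid sum (default `1e-6`).
#' @return `x`, invisibly; errors describe the first offending entry.
#' @export
validate_haplotype_dosages <- function(x, tol = 1e-6) {
  d <- dim(x$dosages)
  if (d[3L] < 2L) stop("need at least 2 founders, got ", d[3L])
  if (d[2L] != nrow(x$marker_map)) {
    stop("marker_map has ", nrow(x$marker_map), " rows but dosages have ",
         d[2L], " markers")
  }
  if (anyDuplicated(x$individual_ids)) stop("duplicated individual ids")
  sums <- rowSums(x$dosages, dims = 2L)  # individuals x markers
  bad <- which(abs(sums - 2) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "founder dosages for individual '%s' at marker '%s' sum to %.6g, not 2",
      x$individual_ids[i], x$marker_map$marker[j], sums[i, j]))
  }
  for (ch in unique(x$marker_map$chrom)) {
    p <- x$marker_map$pos_bp[x$marker_map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(x)
}

#' @export
print.haplotype_dosages <- function(x, ...) {
  d <- dim(x$dosages)
  cat(sprintf("<haplotype_dosages> %d individuals x %d markers x %d founders\n",
              d[1L], d[2L], d[3L]))
  cat("  chromosomes:", paste(unique(x$marker_map$chrom), collapse = ", "),
      "\n")
  invisible(x)
}

#' Individuals-by-features omics matrix
#'
#' A named real matrix (rows = individuals, columns = features) with optional
#' per-feature annotations. Used for per-tissue expression matrices and for
#' the clinical-trait (phenome) matrix.
#'
#' @param values numeric matrix, individuals x features, no non-finite
#'   entries; dimnames used as identifiers if `individual_ids`/`feature_ids`
#'   are not given.
#' @param feature_annotations optional data frame with one row per feature;
#'   for transcripts, columns `feature_id`, `gene_id`, `chrom`, `tss_bp`,
#'   `tissue` are understood by downstream functions.
#' @param modality free-text label (e.g. `"expression"`, `"phenotype"`).
#' @param individual_ids,feature_ids optional identifier vectors.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, feature_annotations = NULL,
                         modality = "omics",
                         individual_ids = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(values) %||% paste0("ind", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values) %||% paste0("feat", seq_len(ncol(values)))
  }
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids")
  if (any(!is.finite(values))) {
    stop("omics matrix contains non-finite values; resolve missingness first ",
         "(see align_individuals complete-case handling)")
  }
  dimnames(values) <- list(individual_ids, feature_ids)
  if (!is.null(feature_annotations)) {
    stopifnot(is.data.frame(feature_annotations))
    if (!"feature_id" %in% names(feature_annotations)) {
      feature_annotations$feature_id <- feature_ids
    }
    stopifnot(nrow(feature_annotations) == ncol(values))
  }
  structure(list(values = values,
                 feature_annotations = feature_annotations,
                 modality = modality),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s> %d individuals x %d features\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Covariate table
#'
#' Numeric covariates (e.g. sex coded 0/1) used to residualize expression and
#' phenotype matrices before kernel construction. The design matrix with an
#' added intercept must have full column rank.
#'
#' @param covariates numeric matrix or data frame, individuals x q.
#' @param individual_ids optional identifiers (default: rownames).
#' @return an object of class `covariate_table`.
#' @export
covariate_table <- function(covariates, individual_ids = NULL) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- rownames(covariates) %||%
      paste0("ind", seq_len(nrow(covariates)))
  }
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
  }
  rownames(covariates) <- individual_ids
  X <- cbind(intercept = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  structure(list(individual_ids = as.character(individual_ids),
                 covariates = covariates),
            class = "covariate_table")
}

## Subsetting by individual, shared across containers ------------------------

#' Restrict a kermed object to a set of individuals (in the given order)
#'
#' @param x a `haplotype_dosages`, `omics_matrix`, or `covariate_table`.
#' @param ids character vector of individual ids, all present in `x`.
#' @return object of the same class restricted to `ids`.
#' @export
subset_individuals <- function(x, ids) UseMethod("subset_individuals")

#' @export
subset_individuals.haplotype_dosages <- function(x, ids) {
  stopifnot(all(ids %in% x$individual_ids))
  x$dosages <- x$dosages[ids, , , drop = FALSE]
  x$individual_ids <- as.character(ids)
  x
}

#' @export
subset_individuals.omics_matrix <- function(x, ids) {
  stopifnot(all(ids %in% rownames(x$values)))
  x$values <- x$values[ids, , drop = FALSE]
  x
}

#' @export
subset_individuals.covariate_table <- function(x, ids) {
  stopifnot(all(ids %in% x$individual_ids))
  x$covariates <- x$covariates[ids, , drop = FALSE]
  x$individual_ids <- as.character(ids)
  x
}

# individual ids of any container
.individual_ids <- function(x) {
  if (inherits(x, "omics_matrix")) return(rownames(x$values))
  if (inherits(x, "kernel_matrix")) return(x$individual_ids)
  x$individual_ids
}
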