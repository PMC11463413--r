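## Delimited-text readers/writers for all containers, with JSON sidecar
## manifests so pipelines can validate their inputs.

#' Write a tab-delimited individuals-by-features matrix
#'
#' First column `individual_id`, remaining columns one per feature. If the
#' matrix carries feature annotations they are written alongside as
#' `<path base>.features.tsv`. A JSON manifest sidecar (`<path>.manifest.json`)
#' records dimensions and an md5 checksum.
#'
#' @param x an [omics_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(individual_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$feature_annotations)) {
    write.table(x$feature_annotations,
                paste0(sub("\\.tsv$", "", path), ".features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(path, n_individuals = nrow(x$values),
                 n_features = ncol(x$values), modality = x$modality)
  invisible(path)
}

#' Read a tab-delimited individuals-by-features matrix
#'
#' @param path TSV path as written by [write_omics_matrix()]; a
#'   `<base>.features.tsv` annotation sidecar is picked up automatically.
#' @param modality label to attach.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, modality = "omics") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "individual_id") {
    stop("expected first column 'individual_id' in ", path)
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df$individual_id)
  ann_path <- paste0(sub("\\.tsv$", "", path), ".features.tsv")
  ann <- if (file.exists(ann_path)) {
    read.delim(ann_path, stringsAsFactors = FALSE)
  } else NULL
  omics_matrix(values, feature_annotations = ann, modality = modality)
}

#' Write founder-haplotype dosages as long-format TSV plus marker map
#'
#' The dosage table has columns `individual_id`, `marker`, `founder`,
#' `dosage`; the marker map is written to `<base>.markers.tsv` with columns
#' `marker`, `chrom`, `pos_bp`.
#'
#' @param x a [haplotype_dosages()] object.
#' @param path output TSV path for the long-format dosage table.
#' @return `path`, invisibly.
#' @export
write_haplotype_dosages <- function(x, path) {
  stopifnot(inherits(x, "haplotype_dosages"))
  d <- dim(x$dosages)
  long <- data.frame(
    individual_id = rep(x$individual_ids, times = d[2L] * d[3L]),
    marker = rep(rep(x$marker_map$marker, each = d[1L]), times = d[3L]),
    founder = rep(dimnames(x$dosages)[[3L]], each = d[1L] * d[2L]),
    dosage = as.vector(x$dosages))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$marker_map, paste0(sub("\\.tsv$", "", path), ".markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(path, n_individuals = d[1L], n_markers = d[2L],
                 n_founders = d[3L], modality = "haplotype_dosages")
  invisible(path)
}

#' Read founder-haplotype dosages from long-format TSV
#'
#' @param path long-format dosage TSV as written by
#'   [write_haplotype_dosages()]; the `<base>.markers.tsv` map is required.
#' @return a validated [haplotype_dosages()] object.
#' @export
read_haplotype_dosages <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "marker", "founder", "dosage")
  if (!all(need %in% names(long))) {
    stop("dosage table must have columns ", paste(need, collapse = ", "))
  }
  map_path <- paste0(sub("\\.tsv$", "", path), ".markers.tsv")
  if (!file.exists(map_path)) stop("marker map not found: ", map_path)
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos_bp") %in% names(map))) {
    stop("malformed marker map ", map_path,
         ": need columns marker, chrom, pos_bp")
  }
  inds <- unique(long$individual_id)
  founders <- sort(unique(long$founder))
  arr <- array(NA_real_,
               dim = c(length(inds), nrow(map), length(founders)),
               dimnames = list(inds, map$marker, founders))
  arr[cbind(match(long$individual_id, inds),
            match(long$marker, map$marker),
            match(long$founder, founders))] <- long$dosage
  if (anyNA(arr)) stop("dosage table is not a complete individual x marker x ",
                       "founder grid")
  haplotype_dosages(arr, map, individual_ids = inds)
}

#' Write a JSON manifest sidecar for a data file
#'
#' @param path data file the manifest describes; the manifest is written to
#'   `<path>.manifest.json`.
#' @param ... scalar fields to record (dimensions, labels).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(path, ...) {
  info <- list(file = basename(path),
               md5 = unname(tools::md5sum(path)), ...)
  mpath <- paste0(path, ".manifest.json")
  jsonlite::write_json(info, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read and verify a manifest sidecar
#'
#' @param path the data file (not the manifest).
#' @param verify if `TRUE` (default), recompute the md5 checksum and error on
#'   mismatch.
#' @return the manifest as a named list.
#' @export
read_manifest <- function(path, verify = TRUE) {
  mpath <- paste0(path, ".manifest.json")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  info <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (verify) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, info$md5)) {
      stop("checksum mismatch for ", path, " (file changed since manifest)")
    }
  }
  info
}

#' Load and align a full dataset from delimited files
#'
#' Reads founder dosages, one or more tissue expression matrices, the
#' phenotype matrix, and (optionally) covariates, restricts every object to
#' the individuals present in all inputs, and returns them in one canonical
#' (sorted) individual order. Individuals with any missing entry in an
#' expression or phenotype matrix are dropped before intersecting
#' (complete-case).
#'
#' @param dosage_path long-format dosage TSV (see [read_haplotype_dosages()]).
#' @param expression_paths named character vector of per-tissue expression
#'   TSVs; names are tissue labels.
#' @param phenotype_path phenotype TSV.
#' @param covariate_path optional covariate TSV (first column
#'   `individual_id`).
#' @return a list with elements `dosages`, `expression` (named list of
#'   [omics_matrix()]), `phenotypes`, `covariates` (or `NULL`), and
#'   `individual_ids`.
#' @export
load_dataset <- function(dosage_path, expression_paths, phenotype_path,
                         covariate_path = NULL) {
  dosages <- read_haplotype_dosages(dosage_path)
  if (is.null(names(expression_paths))) {
    names(expression_paths) <- paste0("tissue", seq_along(expression_paths))
  }
  expression <- lapply(names(expression_paths), function(tis) {
    read_expression_complete(expression_paths[[tis]], tis)
  })
  names(expression) <- names(expression_paths)
  phenotypes <- read_expression_complete(phenotype_path, NULL,
                                         modality = "phenotype")
  covariates <- if (!is.null(covariate_path)) {
    df <- read.delim(covariate_path, stringsAsFactors = FALSE)
    covariate_table(as.matrix(df[, -1L, drop = FALSE]),
                    individual_ids = as.character(df[[1L]]))
  } else NULL
  objs <- c(list(dosages), expression, list(phenotypes),
            if (!is.null(covariates)) list(covariates))
  shared <- Reduce(intersect, lapply(objs, .individual_ids))
  if (length(shared) == 0L) {
    stop("no individuals shared across all inputs (empty intersection)")
  }
  shared <- sort(shared)
  list(dosages = subset_individuals(dosages, shared),
       expression = lapply(expression, subset_individuals, ids = shared),
       phenotypes = subset_individuals(phenotypes, shared),
       covariates = if (!is.null(covariates)) {
         subset_individuals(covariates, shared)
       },
       individual_ids = shared)
}

# read an expression/phenotype TSV and drop individuals with missing entries
read_expression_complete <- function(path, tissue, modality = "expression") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "individual_id") {
    stop("expected first column 'individual_id' in ", path)
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df$individual_id)
  keep <- complete.cases(values)
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) with missing values dropped from ",
            basename(path), call. = FALSE)
    values <- values[keep, , drop = FALSE]
  }
  ann_path <- paste0(sub("\\.tsv$", "", path), ".features.tsv")
  ann <- if (file.exists(ann_path)) {
    read.delim(ann_path, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(tissue) && !is.null(ann) && !"tissue" %in% names(ann)) {
    ann$tissue <- tissue
  }
  omics_matrix(values, feature_annotations = ann, modality = modality)
}
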