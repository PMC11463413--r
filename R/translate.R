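## Transfer of transcript loadings to an independent population: score
## individuals from measured expression, or from expression imputed out of
## local founder genotype, and evaluate predictions.

#' Predict composite scores in a new population from transcript loadings
#'
#' Each individual's score is the loading-weighted sum of its expression,
#' standardized per gene within the new population (the loadings carry
#' direction and relative importance; absolute scale is population
#' specific). Genes are matched through `gene_map`; unmapped genes and
#' zero-variance genes are dropped with a warning.
#'
#' @param expression_new an [omics_matrix()] for the new population.
#' @param loadings a [variable_loadings()] result from the training
#'   population.
#' @param gene_map optional two-column data frame (`from` = loading feature
#'   id, `to` = new-population feature id); by default features are matched
#'   by identical id.
#' @return numeric vector of scores named by individual, with attributes
#'   `n_genes` (mapped genes used) and `dropped` (genes dropped).
#' @export
predict_scores <- function(expression_new, loadings, gene_map = NULL) {
  stopifnot(inherits(expression_new, "omics_matrix"),
            inherits(loadings, "loading_vector"))
  X <- expression_new$values
  if (is.null(gene_map)) {
    gene_map <- data.frame(from = loadings$feature_id,
                           to = loadings$feature_id,
                           stringsAsFactors = FALSE)
  }
  stopifnot(ncol(gene_map) >= 2L)
  names(gene_map)[1:2] <- c("from", "to")
  gene_map <- gene_map[gene_map$from %in% loadings$feature_id &
                         gene_map$to %in% colnames(X), , drop = FALSE]
  if (nrow(gene_map) == 0L) {
    stop("no genes map between loadings and new-population expression")
  }
  w <- loadings$loading[match(gene_map$from, loadings$feature_id)]
  Xm <- X[, gene_map$to, drop = FALSE]
  sds <- apply(Xm, 2L, stats::sd)
  ok <- is.finite(sds) & sds > 1e-12
  dropped <- gene_map$to[!ok]
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance gene(s) dropped from prediction",
            call. = FALSE)
  }
  if (!any(ok)) stop("all mapped genes have zero variance")
  Z <- scale(Xm[, ok, drop = FALSE])
  scores <- drop(Z %*% w[ok])
  names(scores) <- rownames(X)
  attr(scores, "n_genes") <- sum(ok)
  attr(scores, "dropped") <- dropped
  scores
}

#' Fit per-gene local founder-effect models
#'
#' For each annotated gene, regresses its expression on the founder-haplotype
#' dosages at the marker nearest its TSS on the same chromosome. The founder
#' dosages sum to 2, so the design (intercept + founders) is collinear; the
#' minimum-norm least-squares solution via the Moore-Penrose pseudoinverse
#' absorbs this. Genes whose chromosome has no markers are skipped with a
#' warning.
#'
#' @param expression_train an [omics_matrix()] with annotations carrying
#'   `chrom` and `tss_bp`.
#' @param dosages_train a [haplotype_dosages()] on the same individuals (same
#'   order).
#' @param annotations optional annotation data frame overriding the one in
#'   `expression_train` (columns `feature_id`, `chrom`, `tss_bp`).
#' @return object of class `local_model_set`: list with `models` (data frame:
#'   `feature_id`, `marker`, `intercept`, `training_r2`), `founder_effects`
#'   (genes x founders matrix), `founders`.
#' @export
fit_local_models <- function(expression_train, dosages_train,
                             annotations = NULL) {
  stopifnot(inherits(expression_train, "omics_matrix"),
            inherits(dosages_train, "haplotype_dosages"))
  ann <- annotations %||% expression_train$feature_annotations
  if (is.null(ann) || !all(c("chrom", "tss_bp") %in% names(ann))) {
    stop("need feature annotations with chrom and tss_bp")
  }
  if (!"feature_id" %in% names(ann)) {
    ann$feature_id <- colnames(expression_train$values)
  }
  X <- expression_train$values
  stopifnot(identical(rownames(X), dosages_train$individual_ids))
  map <- dosages_train$marker_map
  founders <- dimnames(dosages_train$dosages)[[3L]]
  # nearest same-chromosome marker per gene
  nearest <- vapply(seq_len(nrow(ann)), function(i) {
    on_chr <- which(map$chrom == as.character(ann$chrom[i]))
    if (length(on_chr) == 0L) return(NA_character_)
    map$marker[on_chr[which.min(abs(map$pos_bp[on_chr] - ann$tss_bp[i]))]]
  }, character(1L))
  skipped <- ann$feature_id[is.na(nearest)]
  if (length(skipped) > 0L) {
    warning(length(skipped), " gene(s) skipped: chromosome absent from ",
            "marker map", call. = FALSE)
  }
  keep <- which(!is.na(nearest))
  eff <- matrix(NA_real_, nrow = length(keep), ncol = length(founders),
                dimnames = list(ann$feature_id[keep], founders))
  intercept <- numeric(length(keep))
  r2 <- numeric(length(keep))
  # group genes by marker: one pseudoinverse per marker serves all its genes
  for (mk in unique(nearest[keep])) {
    gidx <- keep[nearest[keep] == mk]
    D <- dosages_train$dosages[, mk, ]
    Xd <- cbind(1, D)
    B <- MASS::ginv(Xd) %*% X[, ann$feature_id[gidx], drop = FALSE]
    fitted <- Xd %*% B
    pos <- match(gidx, keep)
    intercept[pos] <- B[1L, ]
    eff[pos, ] <- t(B[-1L, , drop = FALSE])
    obs <- X[, ann$feature_id[gidx], drop = FALSE]
    r2[pos] <- vapply(seq_along(gidx), function(j) {
      vy <- stats::var(obs[, j])
      if (vy < 1e-300) return(0)
      max(0, min(1, 1 - stats::var(obs[, j] - fitted[, j]) / vy))
    }, numeric(1L))
  }
  structure(list(models = data.frame(feature_id = ann$feature_id[keep],
                                     marker = nearest[keep],
                                     intercept = intercept,
                                     training_r2 = r2,
                                     stringsAsFactors = FALSE),
                 founder_effects = eff,
                 founders = founders,
                 skipped = skipped),
            class = "local_model_set")
}

#' @export
print.local_model_set <- function(x, ...) {
  cat(sprintf("<local_model_set> %d gene(s), %d founder(s)\n",
              nrow(x$models), length(x$founders)))
  cat(sprintf("  mean training R2: %.3f\n", mean(x$models$training_r2)))
  invisible(x)
}

#' Impute expression in a new population from local founder genotype
#'
#' For each modeled gene, predicted expression is
#' `intercept + dosages %*% founder_effects` at the model's marker in the
#' new population. Genes whose marker is absent from the new map are
#' dropped with a warning.
#'
#' @param dosages_new a [haplotype_dosages()] for the new population (same
#'   founders).
#' @param models a [fit_local_models()] result.
#' @return an [omics_matrix()] of imputed expression (modality
#'   `"imputed_expression"`).
#' @export
impute_expression <- function(dosages_new, models) {
  stopifnot(inherits(dosages_new, "haplotype_dosages"),
            inherits(models, "local_model_set"))
  founders <- dimnames(dosages_new$dosages)[[3L]]
  if (!identical(founders, models$founders)) {
    stop("founder labels differ between models and new population")
  }
  present <- models$models$marker %in% dosages_new$marker_map$marker
  if (!any(present)) stop("no model markers present in the new marker map")
  if (!all(present)) {
    warning(sum(!present), " gene(s) dropped: marker missing from the new ",
            "map", call. = FALSE)
  }
  mm <- models$models[present, , drop = FALSE]
  eff <- models$founder_effects[present, , drop = FALSE]
  n <- length(dosages_new$individual_ids)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(mm),
                dimnames = list(dosages_new$individual_ids, mm$feature_id))
  for (mk in unique(mm$marker)) {
    j <- which(mm$marker == mk)
    D <- dosages_new$dosages[, mk, ]
    out[, j] <- sweep(D %*% t(eff[j, , drop = FALSE]), 2L, mm$intercept[j],
                      "+")
  }
  omics_matrix(out, modality = "imputed_expression")
}

#' Evaluate predicted scores against observed outcomes
#'
#' Continuous observed values give a Pearson correlation with two-sided
#' p-value; a two-level grouping gives the difference in group means with a
#' two-sided Wilcoxon rank-sum p-value. An optional `strains` grouping adds
#' per-strain means and standard deviations of both vectors.
#'
#' @param predicted numeric vector of predicted scores.
#' @param observed numeric vector (continuous outcome) or factor/character
#'   with exactly two levels (group labels), aligned with `predicted`.
#' @param strains optional grouping vector for per-strain summaries.
#' @return object of class `prediction_report`: list with `type`
#'   (`"continuous"` or `"groups"`), `r` or `mean_difference`, `p`, `n`, and
#'   optionally `strain_summary`.
#' @export
evaluate_prediction <- function(predicted, observed, strains = NULL) {
  stopifnot(length(predicted) == length(observed))
  if (is.numeric(observed)) {
    ct <- cor.test(predicted, observed)
    out <- list(type = "continuous", r = unname(ct$estimate), p = ct$p.value,
                n = length(predicted))
  } else {
    grp <- factor(observed)
    if (nlevels(grp) < 2L) stop("need at least 2 groups")
    if (nlevels(grp) > 2L) stop("grouped evaluation supports exactly 2 groups")
    if (any(table(grp) < 2L)) stop("need at least 2 individuals per group")
    a <- predicted[grp == levels(grp)[1L]]
    b <- predicted[grp == levels(grp)[2L]]
    wt <- suppressWarnings(wilcox.test(b, a, exact = TRUE))
    out <- list(type = "groups", mean_difference = mean(b) - mean(a),
                p = wt$p.value, n = length(predicted),
                groups = levels(grp))
  }
  if (!is.null(strains)) {
    obs_num <- if (is.numeric(observed)) observed else {
      as.numeric(factor(observed))
    }
    sp <- split(data.frame(predicted = predicted, observed = obs_num),
                strains)
    out$strain_summary <- do.call(rbind, lapply(names(sp), function(s) {
      data.frame(strain = s, n = nrow(sp[[s]]),
                 predicted_mean = mean(sp[[s]]$predicted),
                 predicted_sd = stats::sd(sp[[s]]$predicted),
                 observed_mean = mean(sp[[s]]$observed),
                 observed_sd = stats::sd(sp[[s]]$observed),
                 stringsAsFactors = FALSE)
    }))
  }
  class(out) <- "prediction_report"
  out
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n")
  if (x$type == "continuous") {
    cat(sprintf("  Pearson r = %.3f (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  } else {
    cat(sprintf("  mean difference (%s - %s) = %.3f (rank-sum p = %.3g)\n",
                x$groups[2L], x$groups[1L], x$mean_difference, x$p))
  }
  invisible(x)
}

#' Write a prediction report (JSON summary + per-individual TSV)
#'
#' @param report a `prediction_report`.
#' @param predicted,observed the vectors that produced it.
#' @param json_path output JSON path.
#' @param tsv_path output per-individual TSV path.
#' @return invisibly, the two paths.
#' @export
write_prediction_report <- function(report, predicted, observed, json_path,
                                    tsv_path) {
  stopifnot(inherits(report, "prediction_report"))
  summary <- report[setdiff(names(report), "strain_summary")]
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  df <- data.frame(individual_id = names(predicted) %||%
                     seq_along(predicted),
                   predicted = as.numeric(predicted), observed = observed)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(json = json_path, tsv = tsv_path))
}
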