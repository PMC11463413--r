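make_loadings <- function(ids, values, tissue = NA_character_) {
  ld <- data.frame(feature_id = ids, tissue = tissue, loading = values,
                   z_loading = 0, constant_flag = FALSE,
                   stringsAsFactors = FALSE)
  class(ld) <- c("loading_vector", "data.frame")
  ld
}

test_that("predicted scores are loading-weighted standardized expression", {
  set.seed(71)
  n <- 40
  ids <- paste0("g", 1:6)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("i", 1:n), ids))
  m <- omics_matrix(X)

  # all-zero loadings: all-zero scores
  z <- predict_scores(m, make_loadings(ids, rep(0, 6)))
  expect_true(all(z == 0))

  # rank-one construction: scores proportional to the planted pattern
  v <- rnorm(n)
  w <- c(2, -1, 0.5, 1, -2, 0.25)
  X1 <- outer(v, w) + matrix(rnorm(n * 6, sd = 1e-3), n)
  dimnames(X1) <- dimnames(X)
  s <- predict_scores(omics_matrix(X1), make_loadings(ids, w))
  expect_gt(cor(s, v), 0.999)

  # invariance to per-gene affine rescaling of the new-population matrix
  X2 <- sweep(sweep(X1, 2, c(2, 3, 0.5, 10, 1, 7), "*"), 2, rnorm(6), "+")
  dimnames(X2) <- dimnames(X)
  s2 <- predict_scores(omics_matrix(X2), make_loadings(ids, w))
  expect_equal(unname(s2), unname(s), tolerance = 1e-10)

  expect_error(predict_scores(m, make_loadings(paste0("x", 1:3), 1:3)),
               "no genes map")
})

test_that("local models recover exact founder-effect expression", {
  dat <- cached("translate_train", {
    cfg <- sim_config(n_individuals = 150, n_chromosomes = 4,
                      markers_per_chrom = 8, n_transcripts = 60,
                      n_core_transcripts = 10, seed = 23)
    simulate_dataset(cfg)
  })
  dos <- dat$dosages
  ann <- dat$expression$feature_annotations[1:5, ]
  # noise-free construction at each gene's nearest marker
  eff <- matrix(rnorm(5 * 8), 5)
  X <- sapply(1:5, function(j) {
    mk <- ann$feature_id[j]
    i <- which.min(abs(dos$marker_map$pos_bp - ann$tss_bp[j]) +
                     1e12 * (dos$marker_map$chrom != ann$chrom[j]))
    drop(dos$dosages[, i, ] %*% eff[j, ]) + j
  })
  colnames(X) <- ann$feature_id
  rownames(X) <- dos$individual_ids
  lm_set <- fit_local_models(omics_matrix(X, feature_annotations = ann),
                             dos)
  expect_true(all(lm_set$models$training_r2 > 1 - 1e-8))
  # imputing the training population reproduces the fitted values exactly
  imp <- impute_expression(dos, lm_set)
  expect_equal(unname(imp$values), unname(X), tolerance = 1e-6)
})

test_that("pure-noise expression keeps training R2 at the overfit floor", {
  dat <- cached("translate_train", NULL)
  dos <- dat$dosages
  n <- length(dos$individual_ids)
  set.seed(24)
  ann <- dat$expression$feature_annotations[1:40, ]
  X <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(dos$individual_ids, ann$feature_id))
  lm_set <- fit_local_models(omics_matrix(X, feature_annotations = ann),
                             dos)
  expect_lt(mean(lm_set$models$training_r2), 8 / n + 0.02)
})

test_that("consistent founder relabeling leaves predictions unchanged", {
  dat <- cached("translate_train", NULL)
  dos <- dat$dosages
  expr <- dat$expression
  lm_set <- fit_local_models(expr, dos)
  imp1 <- impute_expression(dos, lm_set)
  # permute founder labels consistently in dosages
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  dos2 <- dos
  dos2$dosages <- dos$dosages[, , perm]
  dimnames(dos2$dosages)[[3]] <- dimnames(dos$dosages)[[3]]
  expr2 <- expr  # same expression; models refit on relabeled dosages
  lm_set2 <- fit_local_models(expr2, dos2)
  imp2 <- impute_expression(dos2, lm_set2)
  expect_equal(imp1$values, imp2$values, tolerance = 1e-6)
})

test_that("zero founder effects impute a constant intercept column", {
  dat <- cached("translate_train", NULL)
  dos <- dat$dosages
  lm_set <- fit_local_models(dat$expression, dos)
  lm_set$founder_effects[1, ] <- 0
  imp <- impute_expression(dos, lm_set)
  expect_equal(unname(imp$values[, 1]),
               rep(lm_set$models$intercept[1],
                   length(dos$individual_ids)), tolerance = 1e-12)
})

test_that("imputation recovers the locally heritable variance share", {
  cfg <- sim_config(n_individuals = 250, n_chromosomes = 5,
                    markers_per_chrom = 10, n_transcripts = 60,
                    n_core_transcripts = 0, h2_local = 0.6, h2_distal = 0,
                    seed = 26)
  dat <- simulate_dataset(cfg)
  lm_set <- fit_local_models(dat$expression, dat$dosages)
  val <- simulate_validation_population(dat$truth, cfg)
  imp <- impute_expression(val$dosages, lm_set)
  r2 <- sapply(colnames(imp$values), function(g) {
    if (sd(imp$values[, g]) < 1e-10) return(NA_real_)
    cor(imp$values[, g], val$expression$values[, g])^2
  })
  expect_lt(abs(mean(r2, na.rm = TRUE) - 0.6), 0.1)
})

test_that("prediction evaluation handles continuous and grouped outcomes", {
  set.seed(27)
  x <- rnorm(30)
  rep1 <- evaluate_prediction(x, x)
  expect_equal(rep1$r, 1, tolerance = 1e-12)

  # fully separated 5/5 groups: exact rank-sum p = 2/252
  pred <- c(1:5, 11:15)
  grp <- rep(c("lean", "obese"), each = 5)
  rep2 <- evaluate_prediction(pred, grp)
  expect_equal(rep2$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(rep2$mean_difference, 10)
  expect_error(evaluate_prediction(pred, rep("one", 10)), "2 groups")

  # strain summaries
  rep3 <- evaluate_prediction(x, x + rnorm(30, sd = 0.1),
                              strains = rep(letters[1:6], each = 5))
  expect_equal(nrow(rep3$strain_summary), 6)
  expect_true(all(rep3$strain_summary$predicted_sd >= 0))
})
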