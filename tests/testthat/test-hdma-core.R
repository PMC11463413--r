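test_that("path coefficient matches hand arithmetic", {
  v <- c(1, 2, 3, 4)
  expect_equal(path_coefficient(v, v, v), 1)
  expect_equal(path_coefficient(v, v, -v), -1)
  g <- c(1, 2, 3, 4); t <- c(1, 3, 2, 4); p <- c(2, 1, 4, 3)
  # cor(g,t) = 0.8 by hand; cor(t,p) = 0
  expect_equal(cor(g, t), 0.8)
  expect_equal(path_coefficient(g, t, p), 0)
  expect_error(path_coefficient(rep(1, 4), v, v), "constant")
})

test_that("partial correlation matches the residual-regression oracle", {
  x <- c(1, 2, 4, 3); y <- c(1, 3, 2, 4); z <- c(1, 2, 3, 4)
  # independent oracle via lm residuals
  oracle <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
  expect_equal(oracle, -2 / 3, tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, z), -2 / 3, tolerance = 1e-12)

  # z orthogonal to x and y: partial equals plain correlation
  set.seed(21)
  n <- 30
  z2 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ z2))
  y2 <- residuals(lm(rnorm(n) ~ z2))
  expect_equal(partial_correlation(x2, y2, z2), cor(x2, y2),
               tolerance = 1e-10)
  expect_error(partial_correlation(2 * z, y, z), "undefined")
})

test_that("a noise-free mediation chain gives a path coefficient near 1", {
  set.seed(31)
  n <- 50
  g <- rnorm(n)
  transcripts <- outer(g, rnorm(8))          # all variance from g
  traits <- outer(drop(transcripts %*% rnorm(8)), rnorm(3))
  K_G <- linear_kernel(cbind(g, g * 2))
  K_T <- linear_kernel(transcripts)
  K_P <- linear_kernel(traits)
  fit <- fit_hdma(K_G, K_T, K_P)
  expect_gte(fit$path_coefficient, 0.99)
  expect_true(fit$converged)
})

test_that("the perfect-mediation constraint holds to 1e-8 on arbitrary inputs", {
  set.seed(32)
  for (rep in 1:8) {
    n <- sample(30:80, 1)
    K_G <- linear_kernel(matrix(rnorm(n * 20), n))
    K_T <- linear_kernel(matrix(rnorm(n * 30), n))
    K_P <- linear_kernel(matrix(rnorm(n * 5), n))
    fit <- fit_hdma(K_G, K_T, K_P)
    expect_lt(abs(fit$partials["rho_GP_given_T"]), 1e-8)
    expect_lt(abs(colMeans(fit$scores)) |> max(), 1e-10)
    expect_equal(unname(apply(fit$scores, 2, var)), rep(1, 3),
                 tolerance = 1e-10)
    expect_gte(fit$partials["rho_GT"], 0)
    expect_gte(fit$partials["rho_TP"], 0)
  }
})

test_that("identical inputs give bitwise-identical fits", {
  ks <- small_kernels()
  K_T <- linear_kernel(ks$expr_n, modality = "transcriptome")
  K_P <- linear_kernel(ks$pheno_n, modality = "phenome")
  f1 <- fit_hdma(ks$K_G, K_T, K_P, seed = 5)
  f2 <- fit_hdma(ks$K_G, K_T, K_P, seed = 5)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$path_coefficient, f2$path_coefficient)
})

test_that("with one perfectly transmitting transcript, T_C recovers it", {
  set.seed(33)
  n <- 60
  g <- rnorm(n)
  x <- g  # single transcript carrying the full genetic signal
  traits <- outer(x, c(1, -0.5)) + matrix(rnorm(n * 2, sd = 0.05), n)
  K_G <- linear_kernel(matrix(rep(g, 4) + rnorm(4 * n, sd = 0.01), n))
  K_T <- linear_kernel(cbind(x))
  K_P <- linear_kernel(traits)
  fit <- fit_hdma(K_G, K_T, K_P, rank = n - 1)
  expect_gte(abs(cor(fit$scores[, "T_C"], x)), 0.99)
})

test_that("the fitted path coefficient is monotone in planted mediation strength", {
  # increase the mediated share by lowering trait noise; compare medians
  strengths <- c(4, 2, 1, 0.5, 0.25)  # phenotype noise sd, decreasing
  meds <- sapply(strengths, function(s) {
    paths <- sapply(1:6, function(r) {
      dat <- simulate_dataset(sim_config(
        n_individuals = 80, n_chromosomes = 4, markers_per_chrom = 8,
        n_transcripts = 120, n_core_transcripts = 10,
        phenotype_noise_sd = s, seed = 400 + 10 * r))
      K_G <- genome_kernel(dat$dosages)
      K_T <- linear_kernel(normalize_features(dat$expression))
      K_P <- linear_kernel(normalize_features(dat$phenotypes))
      fit_hdma(K_G, K_T, K_P)$path_coefficient
    })
    median(paths)
  })
  expect_true(all(diff(meds) >= 0))
})

test_that("loadings are correlations with documented edge cases", {
  set.seed(41)
  n <- 80
  score <- scale(rnorm(n))[, 1]
  X <- cbind(same = score, neg = -score, noise = rnorm(n), flat = rep(1, n))
  rownames(X) <- paste0("i", 1:n)
  m <- omics_matrix(X)
  ld <- suppressWarnings(variable_loadings(m, score))
  expect_equal(ld$loading[1], 1, tolerance = 1e-12)
  expect_equal(ld$loading[2], -1, tolerance = 1e-12)
  expect_true(ld$constant_flag[4])
  expect_equal(ld$loading[4], 0)
  expect_true(all(abs(ld$loading) <= 1))

  # orthogonal features: loadings concentrate near zero (2/sqrt(n) bound)
  draws <- replicate(100, {
    x <- rnorm(n)
    abs(cor(x, score))
  })
  expect_lt(mean(draws), 2 / sqrt(n))
})

test_that("z-loadings standardize within tissue", {
  dat <- small_dataset()
  ks <- small_kernels()
  fit <- cached("small_fit", {
    K_T <- linear_kernel(ks$expr_n, modality = "transcriptome")
    K_P <- linear_kernel(ks$pheno_n, modality = "phenome")
    fit_hdma(ks$K_G, K_T, K_P, anchor_traits = dat$phenotypes)
  })
  ld <- variable_loadings(ks$expr_n, fit$scores[, "T_C"])
  for (tis in unique(ld$tissue)) {
    z <- ld$z_loading[ld$tissue == tis]
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
})

test_that("variance explained follows the squared-correlation formula", {
  set.seed(51)
  n <- 200
  score <- scale(rnorm(n))[, 1]
  t2 <- 0.5 * score + sqrt(1 - 0.25) * scale(residuals(lm(rnorm(n) ~ score)))[, 1]
  tr <- omics_matrix(cbind(t1 = score, t2 = t2),
                     individual_ids = paste0("i", 1:n))
  expect_equal(variance_explained(score, omics_matrix(cbind(t1 = score))),
               1, tolerance = 1e-12)
  expect_equal(variance_explained(score, tr), (1 + 0.25) / 2,
               tolerance = 1e-12)
  # orthogonal score explains ~0
  orth <- scale(residuals(lm(rnorm(n) ~ score + t2)))[, 1]
  expect_lt(variance_explained(orth, tr), 0.05)
})

test_that("marker set test is exact at its boundaries and calibrated", {
  set.seed(61)
  nfeat <- 400
  ld <- data.frame(feature_id = paste0("g", 1:nfeat), tissue = NA_character_,
                   loading = rnorm(nfeat, sd = 0.1),
                   z_loading = 0, constant_flag = FALSE)
  class(ld) <- c("loading_vector", "data.frame")

  # whole-set test: every null draw equals the observed mean
  all_test <- marker_set_test(ld, ld$feature_id, n_perm = 99, seed = 1)
  expect_equal(all_test$p_value, 1)

  # strongly shifted planted set reaches the minimum attainable p
  ld2 <- ld
  planted <- paste0("g", 1:20)
  ld2$loading[1:20] <- ld2$loading[1:20] + 0.3  # +3 sd shift
  shifted <- marker_set_test(ld2, planted, n_perm = 999, seed = 2)
  expect_equal(shifted$p_value, 0.001)
  expect_error(marker_set_test(ld, character(0)), "empty")

  # null calibration: p uniform for random sets under exchangeable loadings
  pvals <- sapply(1:200, function(i) {
    set.seed(7000 + i)
    ids <- sample(ld$feature_id, 25)
    marker_set_test(ld, ids, n_perm = 99, seed = 9000 + i)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
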