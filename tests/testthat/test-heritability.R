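test_that("split_kinship partitions markers by the TSS window", {
  # markers at chr1: 45, 55, 70 Mb and chr2: 10 Mb; locus chr1:50Mb +/-10Mb
  dos <- tiny_dosages(n = 10L, n_markers = 4L, n_founders = 4L, seed = 13L)
  dos$marker_map <- data.frame(marker = paste0("m", 1:4),
                               chrom = c("1", "1", "1", "2"),
                               pos_bp = c(45e6, 55e6, 70e6, 10e6),
                               stringsAsFactors = FALSE)
  dimnames(dos$dosages)[[2]] <- dos$marker_map$marker
  ks <- split_kinship(dos, chrom = "1", tss_bp = 50e6, window_bp = 10e6)
  expect_identical(ks$local_markers, c("m1", "m2"))
  # partition: local + complement = all markers
  expect_identical(sort(c(ks$local_markers,
                          setdiff(dos$marker_map$marker, ks$local_markers))),
                   sort(dos$marker_map$marker))
  # K_local equals the brute-force kernel on the extracted submatrix
  sub <- matrix(dos$dosages[, c("m1", "m2"), ], nrow = 10)
  expect_lt(max(abs(ks$K_local$K - brute_linear_kernel(sub))), 1e-10)
  expect_error(split_kinship(dos, chrom = "1", tss_bp = 200e6,
                             window_bp = 1e6), "no markers within")
})

test_that("grid REML agrees with brute-force dense likelihood on toys", {
  set.seed(14)
  cfg <- sim_config(n_individuals = 50, n_chromosomes = 4,
                    markers_per_chrom = 8, seed = 15)
  dos <- simulate_mosaic_genomes(cfg)
  ks <- split_kinship(dos, chrom = "2", tss_bp = 20e6, window_bp = 12e6)
  Kl <- ks$K_local$K / mean(diag(ks$K_local$K))
  Kd <- ks$K_distal$K / mean(diag(ks$K_distal$K))
  n <- 50
  # dense REML evaluation, written independently of the package internals
  dense_ll <- function(hl, hd, y) {
    V <- hl * Kl + hd * Kd + (1 - hl - hd) * diag(n)
    ev <- eigen(V, symmetric = TRUE)
    d <- pmax(ev$values, 1e-12)
    yt <- crossprod(ev$vectors, y); xt <- crossprod(ev$vectors, rep(1, n))
    xx <- sum(xt^2 / d); beta <- sum(xt * yt / d) / xx
    rss <- sum((yt - xt * beta)^2 / d)
    -0.5 * (sum(log(d)) + log(xx) + (n - 1) * log(rss))
  }
  for (rep in 1:3) {
    y <- rank_inverse_normal(drop(chol(Kd + 0.5 * diag(n)) %*% rnorm(n)))
    est <- fit_two_component(y, ks$K_local, ks$K_distal, w_step = 0.02)
    # brute-force search over the simplex at step 0.02
    grid <- expand.grid(hl = seq(0, 1, 0.02), hd = seq(0, 1, 0.02))
    grid <- grid[grid$hl + grid$hd <= 1, ]
    lls <- mapply(dense_ll, grid$hl, grid$hd, MoreArgs = list(y = y))
    best <- grid[which.max(lls), ]
    expect_lt(abs(est$h2_local - best$hl), 0.025)
    expect_lt(abs(est$h2_distal - best$hd), 0.025)
  }
})

test_that("REML recovers planted variance components and respects nulls", {
  cfg <- sim_config(n_individuals = 250, seed = 16)
  dos <- simulate_mosaic_genomes(cfg)
  ks <- split_kinship(dos, chrom = "3", tss_bp = 50e6, window_bp = 10e6)
  n <- 250
  set.seed(17)
  draw <- function(K) {
    e <- eigen(K, symmetric = TRUE)
    drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n)))
  }
  Y <- sapply(1:25, function(i) {
    sqrt(0.4) * scale(draw(ks$K_local$K))[, 1] +
      sqrt(0.3) * scale(draw(ks$K_distal$K))[, 1] +
      sqrt(0.3) * scale(rnorm(n))[, 1]
  })
  est <- fit_two_component(Y, ks$K_local, ks$K_distal)
  expect_lt(abs(mean(est$h2_local) - 0.4), 0.08)
  expect_lt(abs(mean(est$h2_distal) - 0.3), 0.08)
  expect_true(all(est$h2_local >= 0 & est$h2_distal >= 0))
  expect_true(all(est$h2_local + est$h2_distal <= 1 + 1e-8))

  # pure-noise transcripts give near-zero components
  Y0 <- sapply(1:25, function(i) rnorm(n))
  est0 <- fit_two_component(Y0, ks$K_local, ks$K_distal)
  expect_lt(mean(est0$h2_local), 0.05)
  expect_lt(mean(est0$h2_distal), 0.05)

  # estimates are invariant to scaling of y (variance ratios)
  est_a <- fit_two_component(Y[, 1], ks$K_local, ks$K_distal,
                             normalize = FALSE)
  est_b <- fit_two_component(Y[, 1] * 37.5, ks$K_local, ks$K_distal,
                             normalize = FALSE)
  expect_equal(est_a$h2_local, est_b$h2_local, tolerance = 1e-6)
  expect_equal(est_a$h2_distal, est_b$h2_distal, tolerance = 1e-6)
})

test_that("indistinguishable kinships are flagged non-identifiable", {
  set.seed(18)
  X <- matrix(rnorm(40 * 30), 40)
  K <- linear_kernel(X)
  est <- fit_two_component(rnorm(40), K, K)
  expect_identical(est$boundary_flag, "non_identifiable")
  expect_equal(est$h2_local, est$h2_distal)
})

test_that("trait relevance is the max absolute trait correlation", {
  set.seed(19)
  n <- 100
  t1 <- rnorm(n); t2 <- rnorm(n)
  traits <- omics_matrix(cbind(t1 = t1, t2 = t2),
                         individual_ids = paste0("i", 1:n))
  # transcript equal to a trait: relevance 1
  # construct a transcript with correlations exactly 0.3 and -0.8
  e1 <- scale(residuals(lm(rnorm(n) ~ t1)))[, 1]
  x <- omics_matrix(cbind(a = t1,
                          c = rnorm(n),
                          flat = rep(2, n)),
                    individual_ids = paste0("i", 1:n))
  rel <- trait_relevance(x, traits)
  expect_equal(unname(rel["a"]), 1, tolerance = 1e-12)
  expect_identical(attr(rel, "constant_features"), "flat")
  expect_equal(unname(rel["flat"]), 0)
  # definition: max of |cor| over traits
  expect_equal(unname(rel["c"]),
               max(abs(cor(x$values[, "c"], t1)),
                   abs(cor(x$values[, "c"], t2))), tolerance = 1e-12)
})

test_that("relevance-heritability correlations behave at the edges", {
  set.seed(20)
  v <- runif(50)
  out <- relevance_heritability_correlation(v, v)
  expect_equal(out$r, 1, tolerance = 1e-12)
  # shuffled component: correlation collapses toward zero
  rs <- sapply(1:50, function(i) {
    relevance_heritability_correlation(sample(v), v)$r
  })
  expect_lt(mean(abs(rs)), 2 / sqrt(50))
  expect_error(relevance_heritability_correlation(v[1:5], v[1:5]),
               "at least 10")
  expect_error(relevance_heritability_correlation(rep(0.5, 50), v),
               "zero-variance")
})
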