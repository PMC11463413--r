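# Shared fixtures, built in code. The cache environment persists for the
# duration of one test run so expensive simulations are built once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# hand-sized dosage object: n individuals, markers on 2 chromosomes
tiny_dosages <- function(n = 6L, n_markers = 4L, n_founders = 3L,
                         seed = 42L) {
  set.seed(seed)
  dos <- array(0, dim = c(n, n_markers, n_founders))
  for (i in seq_len(n)) for (m in seq_len(n_markers)) {
    pick <- sample.int(n_founders, 2L, replace = TRUE)
    for (h in pick) dos[i, m, h] <- dos[i, m, h] + 1
  }
  map <- data.frame(marker = paste0("m", seq_len(n_markers)),
                    chrom = rep(c("1", "2"), each = ceiling(n_markers / 2))[
                      seq_len(n_markers)],
                    pos_bp = rep(c(10e6, 20e6, 10e6, 20e6),
                                 length.out = n_markers),
                    stringsAsFactors = FALSE)
  haplotype_dosages(dos, map,
                    individual_ids = paste0("ind", seq_len(n)))
}

# small but complete simulated dataset used across test files
small_dataset <- function() {
  cached("small_dataset", simulate_dataset(sim_config(
    n_individuals = 120L, n_chromosomes = 5L, markers_per_chrom = 10L,
    n_transcripts = 300L, n_core_transcripts = 15L, seed = 99L)))
}

# kernels for the small dataset
small_kernels <- function() {
  cached("small_kernels", {
    dat <- small_dataset()
    list(K_G = genome_kernel(dat$dosages),
         expr_n = normalize_features(dat$expression),
         pheno_n = normalize_features(dat$phenotypes))
  })
}

# independent brute-force linear kernel: standardize columns, pairwise
# inner products / m, double-center, trace-normalize
brute_linear_kernel <- function(X) {
  Z <- scale(X)
  Z <- Z[, apply(X, 2, sd) > 1e-12, drop = FALSE]
  n <- nrow(Z)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- sum(Z[i, ] * Z[j, ]) / ncol(Z)
  }
  J <- diag(n) - 1 / n
  K <- J %*% K %*% J
  K * n / sum(diag(K))
}
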