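## Multiparent-population simulator: founder-mosaic genomes, transcripts
## with controllable local and distal heritability, phenotypes mediated
## entirely by a set of core transcripts, and an independent validation
## population (inbred-line F1s) reusing the same founder allele effects
## under a distinct kinship structure.

#' Simulation configuration
#'
#' Defaults emulate a Diversity-Outbred-like discovery population: 300
#' individuals, 8 founders, 10 chromosomes of 20 evenly spaced markers
#' (5 Mb apart), 2,000 transcripts of which 50 are "core" mediators. Core
#' transcripts are predominantly distally heritable (local 0.05, distal
#' 0.45) while background transcripts are predominantly locally heritable
#' (local 0.30, distal 0.20) — the regime in which trait-relevant
#' transcription is distally driven. Each transcript's distal term sums
#' weak founder effects at 50 trans-loci on other chromosomes. Traits are
#' linear in the core transcripts plus Gaussian noise; there is no direct
#' genotype-to-trait term, so the phenome is perfectly mediated by the core
#' transcriptome by construction.
#'
#' @param n_individuals individuals in the discovery population.
#' @param n_chromosomes,markers_per_chrom marker grid; positions are evenly
#'   spaced `marker_spacing_bp` apart starting at half the spacing.
#' @param marker_spacing_bp spacing between adjacent markers (bp).
#' @param n_founders number of founder haplotypes (>= 2).
#' @param recomb_prob probability of a founder switch between adjacent
#'   markers on one haplotype.
#' @param n_transcripts,n_core_transcripts transcript counts.
#' @param h2_local,h2_distal background-transcript heritability components
#'   (scalars or length-`n_transcripts` vectors; vectors override the core
#'   settings).
#' @param core_h2_local,core_h2_distal heritability components of core
#'   transcripts (ignored when `h2_local`/`h2_distal` are vectors).
#' @param n_distal_loci trans-loci per transcript for the distal term.
#' @param core_weights optional length-`n_core_transcripts` weights of the
#'   core transcripts in the mediating score (default: drawn standard
#'   normal).
#' @param n_traits number of clinical traits.
#' @param phenotype_noise_sd trait noise standard deviation (the mediating
#'   core score is standardized to unit variance, so `1` gives traits with
#'   roughly half their variance mediated).
#' @param tissue tissue label attached to transcript annotations.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 300L,
                       n_chromosomes = 10L,
                       markers_per_chrom = 20L,
                       marker_spacing_bp = 5e6,
                       n_founders = 8L,
                       recomb_prob = 0.1,
                       n_transcripts = 2000L,
                       n_core_transcripts = 50L,
                       h2_local = 0.30,
                       h2_distal = 0.20,
                       core_h2_local = 0.05,
                       core_h2_distal = 0.45,
                       n_distal_loci = 50L,
                       core_weights = NULL,
                       n_traits = 10L,
                       phenotype_noise_sd = 1,
                       tissue = "adipose",
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chrom = as.integer(markers_per_chrom),
              marker_spacing_bp = marker_spacing_bp,
              n_founders = as.integer(n_founders),
              recomb_prob = recomb_prob,
              n_transcripts = as.integer(n_transcripts),
              n_core_transcripts = as.integer(n_core_transcripts),
              h2_local = h2_local, h2_distal = h2_distal,
              core_h2_local = core_h2_local,
              core_h2_distal = core_h2_distal,
              n_distal_loci = as.integer(n_distal_loci),
              core_weights = core_weights,
              n_traits = as.integer(n_traits),
              phenotype_noise_sd = phenotype_noise_sd,
              tissue = tissue,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg a list of simulation settings (see [sim_config()]).
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_founders < 2L) stop("need at least 2 founders")
  if (cfg$recomb_prob < 0 || cfg$recomb_prob > 1) {
    stop("recomb_prob must be in [0, 1]")
  }
  if (cfg$n_core_transcripts > cfg$n_transcripts) {
    stop("n_core_transcripts exceeds n_transcripts")
  }
  h2l <- .per_transcript(cfg$h2_local, cfg, cfg$core_h2_local)
  h2d <- .per_transcript(cfg$h2_distal, cfg, cfg$core_h2_distal)
  if (any(h2l < 0) || any(h2d < 0) || any(h2l + h2d > 1 + 1e-12)) {
    stop("infeasible heritabilities: need h2_local, h2_distal >= 0 and ",
         "h2_local + h2_distal <= 1")
  }
  if (!is.null(cfg$core_weights) &&
      length(cfg$core_weights) != cfg$n_core_transcripts) {
    stop("core_weights must have length n_core_transcripts")
  }
  invisible(cfg)
}

# expand scalar h2 settings to per-transcript vectors (core overrides)
.per_transcript <- function(x, cfg, core_value = NULL) {
  if (length(x) == cfg$n_transcripts) return(as.numeric(x))
  if (length(x) != 1L) {
    stop("h2 settings must be scalars or length n_transcripts")
  }
  v <- rep(as.numeric(x), cfg$n_transcripts)
  if (!is.null(core_value)) {
    v[seq_len(cfg$n_core_transcripts)] <- core_value
  }
  v
}

#' Simulate founder-mosaic diploid genomes
#'
#' Two independent founder-label Markov chains per individual per
#' chromosome: the founder at the first marker is uniform over founders; at
#' each subsequent marker the label switches, with probability
#' `recomb_prob`, to a uniformly drawn founder. The two haplotypes are
#' summed to dosages, so every row sums to 2 and stationary founder
#' frequencies are uniform.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_dosages()] object.
#' @export
simulate_mosaic_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  map <- .sim_marker_map(config)
  n <- config$n_individuals
  M <- nrow(map)
  f <- config$n_founders
  hap <- matrix(0L, nrow = n, ncol = M)
  dos <- array(0, dim = c(n, M, f))
  for (h in 1:2) {
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      state <- sample.int(f, n, replace = TRUE)
      hap[, idx[1L]] <- state
      for (k in idx[-1L]) {
        switch_ <- runif(n) < config$recomb_prob
        if (any(switch_)) {
          state[switch_] <- sample.int(f, sum(switch_), replace = TRUE)
        }
        hap[, k] <- state
      }
    }
    for (ff in seq_len(f)) {
      dos[, , ff] <- dos[, , ff] + (hap == ff)
    }
  }
  haplotype_dosages(dos, map,
                    individual_ids = sprintf("ind%03d", seq_len(n)))
}

.sim_marker_map <- function(config) {
  data.frame(
    marker = sprintf("m%d_%d",
                     rep(seq_len(config$n_chromosomes),
                         each = config$markers_per_chrom),
                     rep(seq_len(config$markers_per_chrom),
                         times = config$n_chromosomes)),
    chrom = as.character(rep(seq_len(config$n_chromosomes),
                             each = config$markers_per_chrom)),
    pos_bp = rep(config$marker_spacing_bp / 2 +
                   config$marker_spacing_bp *
                   (seq_len(config$markers_per_chrom) - 1L),
                 times = config$n_chromosomes),
    stringsAsFactors = FALSE)
}

#' Simulate a transcriptome with planted local and distal heritability
#'
#' Each transcript sits at one marker (its local eQTL; TSS = marker
#' position). Its expression is a local founder-effect term at that marker,
#' plus a distal term summing independent founder effects at
#' `n_distal_loci` markers on other chromosomes, plus Gaussian noise. The
#' components are scaled so the realized sample-variance shares of the local
#' and distal terms equal the targets; the effective (post-scaling) founder
#' effects are recorded in `truth` and reused verbatim by
#' [simulate_validation_population()]. The first `n_core_transcripts`
#' transcripts are the core mediators; their mediating weights
#' (`core_weights`) and the per-trait coefficients are also drawn here and
#' stored in `truth`.
#'
#' @param dosages a [haplotype_dosages()] from [simulate_mosaic_genomes()].
#' @param config the same [sim_config()].
#' @return list with `expression` (an [omics_matrix()] with annotations) and
#'   `truth` (effects, targets, realized shares, core structure).
#' @export
simulate_transcriptome <- function(dosages, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))
  map <- dosages$marker_map
  n <- length(dosages$individual_ids)
  M <- nrow(map)
  f <- dim(dosages$dosages)[3L]
  nt <- config$n_transcripts
  h2l <- .per_transcript(config$h2_local, config, config$core_h2_local)
  h2d <- .per_transcript(config$h2_distal, config, config$core_h2_distal)
  D_flat <- matrix(dosages$dosages, nrow = n)  # n x (M*f), marker-major
  flat_col <- function(m, ff) (ff - 1L) * M + m

  local_marker <- sample.int(M, nt, replace = TRUE)
  # trans-loci per transcript, capped by the sparsest off-chromosome count
  min_off <- M - max(table(map$chrom))
  if (min_off < 1L) stop("need markers on at least two chromosomes")
  n_dist <- min(config$n_distal_loci, min_off)
  distal_markers <- matrix(0L, nrow = nt, ncol = n_dist)
  for (j in seq_len(nt)) {
    off_chrom <- which(map$chrom != map$chrom[local_marker[j]])
    distal_markers[j, ] <- sample(off_chrom, n_dist)
  }
  beta_local <- matrix(rnorm(nt * f), nrow = nt)
  beta_local <- beta_local - rowMeans(beta_local)  # centered founder effects
  gamma_distal <- array(rnorm(nt * n_dist * f), dim = c(nt, n_dist, f))
  gamma_distal <- sweep(gamma_distal, c(1L, 2L),
                        apply(gamma_distal, c(1L, 2L), mean), "-")

  # shared distal program of the core module: one polygenic genetic factor
  # (weak founder effects at n_dist genome-wide loci); each core transcript
  # loads on it with signed membership rho = weight / max|weight|, so the
  # mediating module is genetically correlated, as trait-relevant
  # transcripts are expected to be
  nc <- config$n_core_transcripts
  core_weights <- config$core_weights %||%
    { if (nc > 0L) rnorm(nc) else numeric(0) }
  rho <- rep(0, nt)
  if (nc > 0L && max(abs(core_weights)) > 0) {
    rho[seq_len(nc)] <- core_weights / max(abs(core_weights))
  }
  shared_markers <- sample.int(M, n_dist)
  gamma_shared <- matrix(rnorm(n_dist * f), nrow = n_dist)
  gamma_shared <- gamma_shared - rowMeans(gamma_shared)
  F_raw <- rowSums(vapply(seq_len(f), function(ff) {
    D_flat[, flat_col(shared_markers, rep(ff, n_dist)), drop = FALSE] %*%
      gamma_shared[, ff]
  }, numeric(n)))
  sd_F <- stats::sd(F_raw)
  if (sd_F < 1e-12) sd_F <- 1
  F_std <- (F_raw - mean(F_raw)) / sd_F

  # raw genetic values via one sparse-pattern dense multiply per term
  B_local <- matrix(0, nrow = M * f, ncol = nt)
  B_local[cbind(rep(flat_col(local_marker, rep(1L, nt)), f) +
                  rep((seq_len(f) - 1L) * M, each = nt),
                rep(seq_len(nt), f))] <- as.vector(beta_local)
  u_local <- D_flat %*% B_local
  B_distal <- matrix(0, nrow = M * f, ncol = nt)
  idx <- cbind(rep(as.vector(distal_markers), f) +
                 rep((seq_len(f) - 1L) * M, each = nt * n_dist),
               rep(rep(seq_len(nt), n_dist), f))
  B_distal[idx] <- as.vector(gamma_distal)
  u_distal <- D_flat %*% B_distal

  # scale components to the target variance shares (realized exactly in the
  # training sample up to component covariances)
  scale_to <- function(u, target) {
    s <- apply(u, 2L, stats::sd)
    fac <- ifelse(target > 0 & s > 1e-12, sqrt(target) / s, 0)
    list(u = sweep(u, 2L, fac, "*"), fac = fac)
  }
  sl <- scale_to(u_local, h2l)
  shared_coef <- sqrt(h2d) * rho
  sdst <- scale_to(u_distal, h2d * (1 - rho^2))  # own (idiosyncratic) distal
  u_dist_all <- sdst$u + outer(F_std, shared_coef)
  noise_sd <- sqrt(pmax(1 - h2l - h2d, 0))
  noise <- sweep(matrix(rnorm(n * nt), nrow = n), 2L, noise_sd, "*")
  X <- sl$u + u_dist_all + noise
  tvar <- apply(X, 2L, stats::var)
  colnames(X) <- sprintf("gene%04d", seq_len(nt))
  rownames(X) <- dosages$individual_ids

  core_ids <- colnames(X)[seq_len(nc)]
  trait_coefs <- runif(config$n_traits, 0.5, 1.5)

  ann <- data.frame(feature_id = colnames(X),
                    gene_id = colnames(X),
                    chrom = map$chrom[local_marker],
                    tss_bp = map$pos_bp[local_marker],
                    tissue = config$tissue,
                    stringsAsFactors = FALSE)
  truth <- list(
    marker_map = map,
    founders = dimnames(dosages$dosages)[[3L]],
    feature_ids = colnames(X),
    local_marker = map$marker[local_marker],
    distal_markers = matrix(map$marker[distal_markers], nrow = nt),
    local_effects = beta_local * sl$fac,        # nt x f, post-scaling
    distal_effects = sweep(gamma_distal, 1L, sdst$fac, "*"),
    shared_markers = map$marker[shared_markers],
    shared_effects = gamma_shared / sd_F,       # n_dist x f, post-scaling
    shared_coef = shared_coef,                  # per-transcript loading on F
    noise_sd = noise_sd,
    h2_local_target = h2l,
    h2_distal_target = h2d,
    realized_local_share = apply(sl$u, 2L, stats::var) / tvar,
    realized_distal_share = apply(u_dist_all, 2L, stats::var) / tvar,
    core_ids = core_ids,
    core_weights = core_weights,
    trait_coefs = trait_coefs)
  list(expression = omics_matrix(X, feature_annotations = ann,
                                 modality = "expression"),
       truth = truth)
}

#' Simulate phenotypes mediated entirely by core transcripts
#'
#' The mediating score is the core-weight combination of the (measured)
#' core transcripts, standardized to unit variance; each trait is its own
#' positive coefficient times that score plus Gaussian noise. No direct
#' genotype term enters, so conditional on the core transcriptome the
#' genome carries no information about the phenome (perfect mediation by
#' construction). The standardization constants are stored in `truth` (as
#' attributes of the return) the first time and reused for validation
#' populations via [simulate_validation_population()].
#'
#' @param transcriptome `expression` element from [simulate_transcriptome()]
#'   (or a compatible [omics_matrix()]).
#' @param truth the matching `truth` list.
#' @param config the [sim_config()].
#' @param noise_seed_offset internal offset so validation populations draw
#'   distinct noise.
#' @param score_center,score_scale optional standardization constants for
#'   the mediating score (default: computed from this population).
#' @return an [omics_matrix()] of traits with attributes `mediator_score`,
#'   `score_center`, `score_scale`.
#' @export
simulate_phenotypes <- function(transcriptome, truth, config,
                                noise_seed_offset = 4L,
                                score_center = NULL, score_scale = NULL) {
  stopifnot(inherits(transcriptome, "omics_matrix"))
  set.seed(derive_seed(config$seed, noise_seed_offset))
  X <- transcriptome$values
  stopifnot(all(truth$core_ids %in% colnames(X)))
  S_raw <- drop(X[, truth$core_ids, drop = FALSE] %*% truth$core_weights)
  ctr <- score_center %||% mean(S_raw)
  scl <- score_scale %||% stats::sd(S_raw)
  if (all(truth$core_weights == 0) && config$phenotype_noise_sd == 0) {
    stop("zero core weights with zero noise give constant traits")
  }
  S <- if (scl > 1e-12) (S_raw - ctr) / scl else S_raw * 0
  P <- outer(S, truth$trait_coefs) +
    matrix(rnorm(length(S) * config$n_traits, sd = config$phenotype_noise_sd),
           nrow = length(S))
  dimnames(P) <- list(rownames(X),
                      sprintf("trait%02d", seq_len(config$n_traits)))
  out <- omics_matrix(P, modality = "phenotype")
  attr(out, "mediator_score") <- S
  attr(out, "score_center") <- ctr
  attr(out, "score_scale") <- scl
  out
}

#' Simulate an independent validation population sharing founder effects
#'
#' Builds recombinant-inbred-intercross-like genomes: `n_lines` fully
#' inbred founder mosaics (one Markov chain per chromosome, homozygous) are
#' paired at random to give F1 individuals whose dosage is the sum of the
#' two parental haplotypes. Expression is regenerated with exactly the
#' founder allele effects stored in `truth` (local and distal), plus fresh
#' noise at the training noise level; phenotypes use the same core weights,
#' trait coefficients, and mediating-score standardization as the training
#' population.
#'
#' @param truth the `truth` list from [simulate_transcriptome()].
#' @param config2 a [sim_config()] for the validation population; its
#'   `n_individuals`, `recomb_prob`, `phenotype_noise_sd`, and `seed` are
#'   used, and its marker grid must match the training map.
#' @param n_lines number of inbred lines to intercross (default 2 *
#'   sqrt(n_individuals), at least 8).
#' @param score_center,score_scale mediating-score standardization from the
#'   training population (defaults to the values stored by
#'   [simulate_phenotypes()] if given, else this population's own).
#' @return list with `dosages`, `expression`, `phenotypes`, and `pairs`
#'   (the line pairing).
#' @export
simulate_validation_population <- function(truth, config2, n_lines = NULL,
                                           score_center = NULL,
                                           score_scale = NULL) {
  validate_sim_config(config2)
  map2 <- .sim_marker_map(config2)
  if (!identical(map2$marker, truth$marker_map$marker) ||
      !identical(map2$pos_bp, truth$marker_map$pos_bp)) {
    stop("validation marker map is incompatible with the training map")
  }
  set.seed(derive_seed(config2$seed, 5L))
  n <- config2$n_individuals
  n_lines <- n_lines %||% max(8L, ceiling(2 * sqrt(n)))
  map <- truth$marker_map
  M <- nrow(map)
  f <- length(truth$founders)
  # inbred line haplotypes: one founder chain per line per chromosome
  line_hap <- matrix(0L, nrow = n_lines, ncol = M)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    state <- sample.int(f, n_lines, replace = TRUE)
    line_hap[, idx[1L]] <- state
    for (k in idx[-1L]) {
      switch_ <- runif(n_lines) < config2$recomb_prob
      if (any(switch_)) {
        state[switch_] <- sample.int(f, sum(switch_), replace = TRUE)
      }
      line_hap[, k] <- state
    }
  }
  pairs <- cbind(sample.int(n_lines, n, replace = TRUE),
                 sample.int(n_lines, n, replace = TRUE))
  same <- pairs[, 1L] == pairs[, 2L]
  while (any(same)) {  # F1s of two distinct lines
    pairs[same, 2L] <- sample.int(n_lines, sum(same), replace = TRUE)
    same <- pairs[, 1L] == pairs[, 2L]
  }
  dos <- array(0, dim = c(n, M, f))
  for (ff in seq_len(f)) {
    dos[, , ff] <- (line_hap[pairs[, 1L], ] == ff) +
      (line_hap[pairs[, 2L], ] == ff)
  }
  dosages <- haplotype_dosages(dos, map,
                               individual_ids = sprintf("rix%03d",
                                                        seq_len(n)))
  expression <- .expression_from_truth(dosages, truth,
                                       seed = derive_seed(config2$seed, 6L))
  cfg_ph <- config2
  cfg_ph$n_traits <- length(truth$trait_coefs)
  phenotypes <- simulate_phenotypes(expression, truth, cfg_ph,
                                    noise_seed_offset = 7L,
                                    score_center = score_center,
                                    score_scale = score_scale)
  list(dosages = dosages, expression = expression, phenotypes = phenotypes,
       pairs = pairs)
}

# regenerate expression in any population from stored effective effects
.expression_from_truth <- function(dosages, truth, seed) {
  set.seed(seed)
  map <- truth$marker_map
  n <- length(dosages$individual_ids)
  M <- nrow(map)
  f <- length(truth$founders)
  nt <- length(truth$feature_ids)
  D_flat <- matrix(dosages$dosages, nrow = n)
  B <- matrix(0, nrow = M * f, ncol = nt)
  lm_idx <- match(truth$local_marker, map$marker)
  B[cbind(rep(lm_idx, f) + rep((seq_len(f) - 1L) * M, each = nt),
          rep(seq_len(nt), f))] <- as.vector(truth$local_effects)
  n_dist <- ncol(truth$distal_markers)
  dm_idx <- matrix(match(truth$distal_markers, map$marker), nrow = nt)
  idx <- cbind(rep(as.vector(dm_idx), f) +
                 rep((seq_len(f) - 1L) * M, each = nt * n_dist),
               rep(rep(seq_len(nt), n_dist), f))
  B[idx] <- B[idx] + as.vector(truth$distal_effects)
  G <- D_flat %*% B
  # shared distal program of the core module
  sm_idx <- match(truth$shared_markers, map$marker)
  F_new <- rowSums(vapply(seq_len(f), function(ff) {
    D_flat[, (ff - 1L) * M + sm_idx, drop = FALSE] %*%
      truth$shared_effects[, ff]
  }, numeric(n)))
  G <- G + outer(F_new - mean(F_new), truth$shared_coef)
  X <- G + sweep(matrix(rnorm(n * nt), nrow = n), 2L, truth$noise_sd, "*")
  dimnames(X) <- list(dosages$individual_ids, truth$feature_ids)
  ann <- data.frame(feature_id = truth$feature_ids,
                    gene_id = truth$feature_ids,
                    chrom = map$chrom[lm_idx],
                    tss_bp = map$pos_bp[lm_idx],
                    stringsAsFactors = FALSE)
  out <- omics_matrix(X, feature_annotations = ann, modality = "expression")
  attr(out, "genetic_values") <- G
  out
}

#' Simulate a complete discovery dataset
#'
#' Convenience wrapper chaining [simulate_mosaic_genomes()],
#' [simulate_transcriptome()], and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list with `dosages`, `expression`, `phenotypes`, `truth`, and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  dosages <- simulate_mosaic_genomes(config)
  tr <- simulate_transcriptome(dosages, config)
  phenotypes <- simulate_phenotypes(tr$expression, tr$truth, config)
  list(dosages = dosages, expression = tr$expression,
       phenotypes = phenotypes, truth = tr$truth, config = config)
}
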