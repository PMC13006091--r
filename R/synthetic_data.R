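# Synthetic population simulator.
#
# Emulates the data regime the predictive model is built for: families of
# related individuals (kinship for the GRM pathway to exploit), chromosome-
# ordered markers with local LD (so patches are locally redundant), a small
# set of causal loci with additive and pairwise-epistatic effects under a
# controlled heritability, plus missing genotypes and deliberately
# QC-failing markers.

#' Simulation configuration
#'
#' Defaults describe the reference study population used throughout the
#' package's tests: 40 families of 2 founders + 18 offspring (n = 800),
#' 2,000 markers on 10 chromosomes with strong local LD, 20 additive causal
#' loci and 5 epistatic pairs at heritability 0.7.
#'
#' @param n_families number of families.
#' @param offspring_per_family offspring gene-dropped from two founders.
#' @param n_founders_per_family founders per family (>= 2 for offspring).
#' @param n_markers marker count (before any appended QC-failing markers).
#' @param n_chromosomes chromosomes; markers are split evenly.
#' @param ld_rho first-order copy probability in \[0, 1) between adjacent
#'   markers on a haplotype — larger means stronger local LD.
#' @param maf_range uniform range for per-marker second-allele frequency.
#' @param n_causal_additive number of additive causal loci.
#' @param n_causal_epistatic_pairs number of (i, j) interaction pairs.
#' @param h2 fraction of phenotypic variance that is genetic, in \[0, 1\].
#' @param missing_rate uniform missing-genotype rate.
#' @param qc_fail_markers extra markers appended that each violate exactly
#'   one QC criterion (cycling call-rate / MAF / HWE).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 40, offspring_per_family = 18,
                       n_founders_per_family = 2, n_markers = 2000,
                       n_chromosomes = 10, ld_rho = 0.6,
                       maf_range = c(0.05, 0.5), n_causal_additive = 20,
                       n_causal_epistatic_pairs = 5, h2 = 0.7,
                       missing_rate = 0.01, qc_fail_markers = 0, seed = 1) {
  cfg <- list(n_families = n_families, offspring_per_family = offspring_per_family,
              n_founders_per_family = n_founders_per_family, n_markers = n_markers,
              n_chromosomes = n_chromosomes, ld_rho = ld_rho,
              maf_range = maf_range, n_causal_additive = n_causal_additive,
              n_causal_epistatic_pairs = n_causal_epistatic_pairs, h2 = h2,
              missing_rate = missing_rate, qc_fail_markers = qc_fail_markers,
              seed = as.integer(seed))
  n <- n_families * (n_founders_per_family + offspring_per_family)
  if (n < 1 || n_markers < 1) gv_config_error("need at least one sample and one marker")
  if (n_founders_per_family < 1) gv_config_error("need at least one founder per family")
  if (offspring_per_family > 0 && n_founders_per_family < 2) {
    gv_config_error("offspring require >= 2 founders per family")
  }
  if (ld_rho < 0 || ld_rho >= 1) gv_config_error("ld_rho must be in [0, 1)")
  if (h2 < 0 || h2 > 1) gv_config_error("h2 must be in [0, 1]")
  if (n_causal_additive + 2 * n_causal_epistatic_pairs > n_markers) {
    gv_config_error("causal loci exceed marker count")
  }
  class(cfg) <- "sim_config"
  cfg
}

# one haplotype matrix (n_hap x m): first-order Markov copying within
# chromosomes; resets at chromosome boundaries.
sim_haplotypes <- function(n_hap, p, chrom, ld_rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  for (j in seq_len(m)) {
    fresh <- stats::rbinom(n_hap, 1L, p[j])
    if (j > 1 && chrom[j] == chrom[j - 1] && ld_rho > 0) {
      copy <- stats::runif(n_hap) < ld_rho
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    } else {
      H[, j] <- fresh
    }
  }
  H
}

#' Simulate genotypes with family structure and local LD
#'
#' Founder haplotypes are drawn per marker from `Bernoulli(p_j)` with
#' `p_j ~ Uniform(maf_range)` and a first-order copying process (probability
#' `ld_rho`) between adjacent markers of the same chromosome. Offspring
#' receive one recombination-free chromosome copy from each of two founders
#' (gene dropping), creating within-family kinship. Markers are emitted in
#' chromosome/position order; missingness is applied uniformly; optional
#' QC-failing markers are appended at the end of the last chromosome.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a `genotype_matrix`) and `truth` (partial:
#'   `family_ids` named by sample, `freqs` the generating allele
#'   frequencies, `qc_fail_ids`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_markers
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(500:5000, length(idx), replace = TRUE))
  }
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

  nf <- cfg$n_founders_per_family
  no <- cfg$offspring_per_family
  n_founders <- cfg$n_families * nf
  H <- sim_haplotypes(2L * n_founders, p, chrom, cfg$ld_rho)

  fam_of_founder <- rep(seq_len(cfg$n_families), each = nf)
  dos_f <- H[seq(1, 2 * n_founders, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n_founders, by = 2), , drop = FALSE]

  chrom_ids <- unique(chrom)
  dos_o <- NULL
  fam_of_off <- integer(0)
  if (no > 0) {
    n_off <- cfg$n_families * no
    dos_o <- matrix(0L, n_off, m)
    fam_of_off <- rep(seq_len(cfg$n_families), each = no)
    for (fam in seq_len(cfg$n_families)) {
      founders <- which(fam_of_founder == fam)
      for (k in seq_len(no)) {
        parents <- sample(founders, 2L)
        row <- (fam - 1L) * no + k
        child <- integer(m)
        for (ch in chrom_ids) {
          idx <- which(chrom == ch)
          for (par in parents) {
            hap <- sample(1:2, 1L)
            child[idx] <- child[idx] + H[2L * (par - 1L) + hap, idx]
          }
        }
        dos_o[row, ] <- child
      }
    }
  }

  d <- rbind(dos_f, dos_o)
  ids <- c(sprintf("F%03d_P%d", fam_of_founder, sequence(rep(nf, cfg$n_families))),
           if (no > 0) sprintf("F%03d_O%d", fam_of_off, sequence(rep(no, cfg$n_families))))
  family_ids <- c(fam_of_founder, fam_of_off)
  names(family_ids) <- ids
  n <- nrow(d)

  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    d[mask] <- NA_real_
  }

  map <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                    chrom = as.character(chrom), pos = pos,
                    stringsAsFactors = FALSE)

  qc_fail_ids <- character(0)
  if (cfg$qc_fail_markers > 0) {
    last_ch <- as.character(chrom[m])
    base_pos <- max(pos[chrom == chrom[m]])
    extra <- matrix(NA_real_, n, cfg$qc_fail_markers)
    kinds <- rep(c("callrate", "maf", "hwe"), length.out = cfg$qc_fail_markers)
    for (q in seq_len(cfg$qc_fail_markers)) {
      col <- switch(kinds[q],
        callrate = {                      # ~90% missing, rest benign hets/homs
          v <- rep(NA_real_, n)
          obs <- sample(n, max(2, round(0.1 * n)))
          v[obs] <- stats::rbinom(length(obs), 2, 0.5)
          v
        },
        maf = rep(0, n),                  # monomorphic: MAF = 0
        hwe = {                           # no heterozygotes at p = 0.5
          v <- rep(0, n); v[sample(n, floor(n / 2))] <- 2; v
        })
      extra[, q] <- col
    }
    qc_fail_ids <- sprintf("qcfail%02d_%s", seq_len(cfg$qc_fail_markers), kinds)
    d <- cbind(d, extra)
    map <- rbind(map, data.frame(id = qc_fail_ids, chrom = last_ch,
                                 pos = base_pos + 1000L * seq_len(cfg$qc_fail_markers),
                                 stringsAsFactors = FALSE))
  }

  g <- genotype_matrix(d, map, ids)
  list(genotypes = g,
       truth = list(family_ids = family_ids, freqs = p, qc_fail_ids = qc_fail_ids))
}

#' Simulate a quantitative phenotype on a genotype panel
#'
#' Genetic value = sum of additive effects `a_i * x_i` plus centered pairwise
#' products `b_ij * (x_i - mean_i)(x_j - mean_j)`. Effects are N(0,1); the
#' genetic and noise components are rescaled so the genetic fraction of the
#' phenotypic variance equals `h2`, and the phenotype is standardized to
#' mean 0, variance 1 over the cohort. Missing genotypes are column-mean
#' filled for effect computation only. Causal loci are drawn from the clean
#' (non-QC-failing) markers.
#'
#' @param g `genotype_matrix` from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @param truth optional partial truth from [simulate_genotypes()] (used to
#'   exclude QC-fail markers from the causal draw).
#' @return list with `phenotypes` (data.frame sample_id, trait) and `truth`
#'   (causal indices/effects, epistatic pairs, per-sample genetic values,
#'   family ids).
#' @export
simulate_phenotype <- function(g, cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 7919L))
  n <- nrow(g$dosages)
  eligible <- seq_len(ncol(g$dosages))
  if (!is.null(truth) && length(truth$qc_fail_ids)) {
    eligible <- which(!(g$map$id %in% truth$qc_fail_ids))
  }
  n_caus <- cfg$n_causal_additive
  n_epi <- cfg$n_causal_epistatic_pairs
  if (cfg$h2 == 1 && n_caus + n_epi == 0) {
    gv_config_error("h2 = 1 with zero causal loci is infeasible")
  }
  X <- g$dosages
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]

  picked <- if (n_caus + 2 * n_epi > 0) sample(eligible, n_caus + 2 * n_epi) else integer(0)
  add_idx <- sort(picked[seq_len(n_caus)])
  epi_idx <- picked[-seq_len(n_caus)]
  a <- if (n_caus) stats::rnorm(n_caus) else numeric(0)
  genetic <- if (n_caus) drop(X[, add_idx, drop = FALSE] %*% a) else numeric(n)
  epi <- if (n_epi) {
    data.frame(i = epi_idx[seq_len(n_epi)], j = epi_idx[n_epi + seq_len(n_epi)],
               effect = stats::rnorm(n_epi))
  } else data.frame(i = integer(0), j = integer(0), effect = numeric(0))
  if (n_epi) {
    for (r in seq_len(n_epi)) {
      xi <- X[, epi$i[r]] - mean(X[, epi$i[r]])
      xj <- X[, epi$j[r]] - mean(X[, epi$j[r]])
      genetic <- genetic + epi$effect[r] * xi * xj
    }
  }

  h2 <- cfg$h2
  if (stats::sd(genetic) == 0) {
    if (h2 > 0) gv_config_error("degenerate genetic values: no variance among causal loci")
    gsc <- numeric(n)
  } else {
    gsc <- sqrt(h2) * as.numeric(scale(genetic))
  }
  if (h2 == 0) gsc <- numeric(n)
  e <- sqrt(1 - h2) * stats::rnorm(n)
  y_raw <- gsc + e
  sdy <- stats::sd(y_raw)
  if (sdy == 0) sdy <- 1
  y <- (y_raw - mean(y_raw)) / sdy
  gval <- gsc / sdy

  ph <- data.frame(sample_id = g$sample_ids, trait = y, stringsAsFactors = FALSE)
  list(phenotypes = ph,
       truth = list(causal_indices = add_idx, causal_effects = a,
                    epistatic_pairs = epi, genetic_values = stats::setNames(gval, g$sample_ids),
                    family_ids = if (!is.null(truth)) truth$family_ids else NULL,
                    h2 = h2))
}

#' Simulate a full dataset (genotypes + phenotype)
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotype()].
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  sg <- simulate_genotypes(cfg)
  sp <- simulate_phenotype(sg$genotypes, cfg, sg$truth)
  truth <- c(sp$truth, sg$truth[c("freqs", "qc_fail_ids")])
  list(genotypes = sg$genotypes, phenotypes = sp$phenotypes, truth = truth)
}
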