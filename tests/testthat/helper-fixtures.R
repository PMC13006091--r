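# Shared fixtures, built in code at test time.

# tiny hand-addressable genotype matrix
tiny_genotypes <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  genotype_matrix(dosages,
                  data.frame(id = sprintf("m%02d", seq_len(m)),
                             chrom = chrom %||% rep("1", m),
                             pos = pos %||% seq_len(m) * 1000L),
                  sprintf("s%02d", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small related population used across module tests
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(n_families = 8, offspring_per_family = 8,
                    n_markers = 300, n_chromosomes = 3, maf_range = c(0.1, 0.5),
                    n_causal_additive = 5, n_causal_epistatic_pairs = 1,
                    h2 = 0.7, missing_rate = 0.01, seed = seed, ...)
  simulate_dataset(cfg)
}

# independent brute-force VanRaden oracle (elementwise double loop)
grm_oracle <- function(dos, p, rows, cols) {
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, length(rows), length(cols))
  for (a in seq_along(rows)) {
    for (b in seq_along(cols)) {
      acc <- 0
      for (j in seq_along(p)) {
        if (p[j] <= 0 || p[j] >= 1) next
        xa <- dos[rows[a], j]; if (is.na(xa)) xa <- 2 * p[j]
        xb <- dos[cols[b], j]; if (is.na(xb)) xb <- 2 * p[j]
        acc <- acc + (xa - 2 * p[j]) * (xb - 2 * p[j])
      }
      G[a, b] <- acc / denom
    }
  }
  G
}

# independent HWE enumeration oracle: direct factorial arithmetic over all
# heterozygote counts compatible with the allele totals
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h) {
    2^h / (factorial((rare - h) / 2) * factorial(h) * factorial((2 * n - rare - h) / 2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# exact (error-function) GELU for fidelity checks
gelu_exact <- function(x) x * pnorm(x)

# tiny model + inputs used by several model tests
tiny_model_setup <- function(variant = "gvit_gp", embed = "spe", seed = 5,
                             B = 3, Np = 4, P = 5, D = 8, n_heads = 2,
                             m_g = 1, n_ref = 6, dropout = 0) {
  k <- 4
  S <- if (embed == "sie") k + 1L else Np + 1L
  cfg <- gvit_config(variant, embed, S = S, P = if (embed == "sie") NULL else P,
                     D = D, n_heads = n_heads, L_pre = 1, L_post = 1,
                     ffn_mult = 2, n_ref = n_ref, grm_hidden = 7, m_g = m_g,
                     dropout = dropout, seed = seed)
  model <- init_gvit(cfg)
  set.seed(seed + 100)
  inputs <- list(grm = matrix(rnorm(B * n_ref), B))
  inputs$X_embed <- if (embed == "sie") matrix(rnorm(B * k), B) else
    array(rnorm(B * Np * P), c(B, Np, P))
  if (variant == "gvit_base") inputs$grm <- NULL
  list(model = model, inputs = inputs, B = B, S = S, D = D)
}

# parameter-tree helpers for surgery/gradient tests
flat_paths <- function(p, prefix = character()) {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    unlist(lapply(keys, function(k) flat_paths(p[[k]], c(prefix, k))),
           recursive = FALSE)
  } else list(prefix)
}

get_leaf <- function(p, path) {
  for (k in path) p <- p[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
  p
}

set_leaf <- function(p, path, v) {
  k <- path[1]
  ki <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
  if (length(path) == 1) p[[ki]] <- v else p[[ki]] <- set_leaf(p[[ki]], path[-1], v)
  p
}
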