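# fixture builders shared across test files; everything generated in code

# a compact planted study: two modules plus noise, control-coupled module 1
small_config <- function(seed = 1L, sizes = c(60L, 50L), within_cor = c(0.7, 0.6),
                         n_genes = 300L, n_per_group = c(case = 60L, control = 60L),
                         coupling = NULL, hub_fraction = c(case = 1, control = 1)) {
  k <- length(sizes)
  within_cor <- rep(within_cor, length.out = k)
  if (is.null(coupling)) {
    coupling <- matrix(0, k, 2, dimnames = list(NULL, c("case", "control")))
    if (k >= 1) coupling[1, "control"] <- 0.5
    if (k >= 2) coupling[2, "case"] <- 0.4
  }
  synthetic_config(
    n_genes = n_genes, n_samples_per_group = n_per_group,
    module_specs = data.frame(size = sizes, within_cor = within_cor),
    trait_coupling = coupling, hub_fraction_coupled = hub_fraction,
    seed = seed
  )
}

# all-noise configuration (no planted modules, no coupling)
noise_config <- function(seed = 1L, n_genes = 300L,
                         n_per_group = c(case = 60L, control = 60L)) {
  synthetic_config(
    n_genes = n_genes, n_samples_per_group = n_per_group,
    module_specs = data.frame(size = integer(0), within_cor = numeric(0)),
    trait_coupling = matrix(0, 0, 2, dimnames = list(NULL, c("case", "control"))),
    seed = seed
  )
}

# direct sample-table builder for tests that do not need expression
make_samples <- function(n, trait, group = rep(c("case", "control"), length.out = n),
                         age = rep(2, n)) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = group,
    age_years = age,
    tbv_cc = trait,
    tbv_residual_cc = trait - mean(trait),
    replicate_of = NA_character_,
    stringsAsFactors = FALSE
  )
}

# two vectors with an exact Pearson correlation r (Gram-Schmidt construction)
exact_cor_pair <- function(r, n, seed = 1L) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
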