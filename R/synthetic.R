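#' Configuration for the synthetic two-group study generator
#'
#' Builds a validated configuration describing a planted-module expression
#' study: a two-group (case/control) cohort with block-correlated gene
#' modules generated from a single latent factor each, and a normally
#' distributed trait (total brain volume, cc) coupled to chosen module
#' factors with group-specific strength. The defaults emulate the study
#' design the package targets: 12,208 gene probes, 87 case and 55 control
#' male toddlers aged 1-4 years, a 253-gene cell-cycle-like module that is
#' trait-coupled in controls through its hub genes, and a cell-adhesion-like
#' module coupled in cases.
#'
#' Each planted module \code{m} of size \code{s} generates genes as
#' \code{x_i = lambda_i * f_m + sqrt(1 - lambda_i^2) * eps_i} with
#' \code{f_m} a standard-normal latent factor shared by the module and
#' per-gene loadings \code{lambda_i} drawn around \code{sqrt(within_cor)},
#' so the expected mean pairwise within-module correlation is
#' \code{within_cor} while genes still differ in connectivity (hubs carry
#' large loadings). Values are placed on a log-intensity scale
#' (\code{intensity_mean + noise_sd * z}).
#'
#' Trait coupling is per module and group: the trait receives
#' \code{coupling * z(signal)} where the signal is a mix of the module
#' factor and the averaged residuals of the module's lowest-loading
#' (peripheral) genes, weighted by \code{hub_fraction_coupled}. With
#' \code{hub_fraction_coupled = 1} the trait couples purely to the factor
#' (hub genes carry the signal); small values route the coupling mainly
#' through peripheral genes, emulating the hub-to-periphery reorganization
#' seen in the case group.
#'
#' @param n_genes total number of genes (planted + independent noise).
#' @param n_samples_per_group named or unnamed length-2 integer vector,
#'   case then control.
#' @param module_specs data frame with columns \code{size} and
#'   \code{within_cor} (one row per planted module).
#' @param trait_coupling numeric matrix, modules x 2 (columns
#'   \code{case}, \code{control}): target correlation between each module
#'   eigengene and the trait in each group. Magnitudes must be < 1 and the
#'   per-group sum of squares must not exceed 1.
#' @param hub_fraction_coupled length-2 numeric in \[0, 1\] (case,
#'   control): fraction of the coupled signal carried by the module
#'   factor (hub genes) rather than peripheral-gene residuals.
#' @param noise_sd log-intensity scale standard deviation.
#' @param intensity_mean log-intensity location.
#' @param age_range numeric length 2, age span in years.
#' @param age_effect function of age (years) giving the expected trait
#'   (cc); default a smooth increasing toddler-growth curve.
#' @param trait_sd residual trait standard deviation (cc).
#' @param loading_spread half-width of the uniform loading distribution
#'   around \code{sqrt(within_cor)}.
#' @param missing_frac fraction of entries set missing at random
#'   (default 0; used to exercise the preprocessing filter).
#' @param seed integer seed; the same seed gives bit-identical studies.
#'
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 12208L,
                             n_samples_per_group = c(case = 87L, control = 55L),
                             module_specs = data.frame(
                               size = c(253L, 180L, 120L, 90L, 60L, 40L),
                               within_cor = c(0.7, 0.65, 0.6, 0.55, 0.5, 0.45)
                             ),
                             trait_coupling = NULL,
                             hub_fraction_coupled = c(case = 0.2, control = 1),
                             noise_sd = 1,
                             intensity_mean = 8,
                             age_range = c(1, 4),
                             age_effect = function(age) 950 + 80 * log1p(age),
                             trait_sd = 80,
                             loading_spread = 0.12,
                             missing_frac = 0,
                             seed = 1L) {
  k <- nrow(module_specs)
  if (is.null(trait_coupling)) {
    trait_coupling <- matrix(0, k, 2, dimnames = list(NULL, c("case", "control")))
    # module 1 (cell-cycle-like) and 2 (protein-folding-like) couple in
    # controls; module 3 (cell-adhesion-like) couples in cases
    if (k >= 1) trait_coupling[1, ] <- c(0.15, 0.55)
    if (k >= 2) trait_coupling[2, ] <- c(0.15, 0.45)
    if (k >= 3) trait_coupling[3, ] <- c(0.45, 0)
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = stats::setNames(as.integer(n_samples_per_group),
                                          c("case", "control")),
    module_specs = module_specs,
    trait_coupling = trait_coupling,
    hub_fraction_coupled = stats::setNames(as.numeric(hub_fraction_coupled),
                                           c("case", "control")),
    noise_sd = noise_sd,
    intensity_mean = intensity_mean,
    age_range = age_range,
    age_effect = age_effect,
    trait_sd = trait_sd,
    loading_spread = loading_spread,
    missing_frac = missing_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  ms <- cfg$module_specs
  if (nrow(ms) > 0 && sum(ms$size) > cfg$n_genes) {
    stop("module sizes (", sum(ms$size), ") exceed n_genes (", cfg$n_genes, ")")
  }
  if (any(ms$within_cor < 0 | ms$within_cor >= 1)) {
    stop("within_cor must lie in [0, 1)")
  }
  if (any(cfg$n_samples_per_group < 1L)) {
    stop("each group needs at least one sample")
  }
  tc <- cfg$trait_coupling
  if (!is.matrix(tc) || nrow(tc) != nrow(ms) || ncol(tc) != 2) {
    stop("trait_coupling must be a modules x 2 (case, control) matrix")
  }
  if (any(abs(tc) >= 1)) stop("coupling magnitudes must be < 1")
  if (any(colSums(tc^2) > 1)) {
    stop("per-group sum of squared couplings must be <= 1")
  }
  if (any(cfg$hub_fraction_coupled < 0 | cfg$hub_fraction_coupled > 1)) {
    stop("hub_fraction_coupled must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0 || cfg$trait_sd <= 0) stop("scale parameters must be positive")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) stop("missing_frac must lie in [0, 1)")
  cfg
}

#' Generate a planted-module expression matrix
#'
#' Draws the latent module factors and gene values described in
#' [synthetic_config()]. Genes outside the planted modules are independent
#' noise. The returned truth object records the planted partition (label
#' \code{"noise"} for unplanted genes), the latent factor per module, the
#' gene loadings, and the standardized peripheral-residual signal used by
#' [generate_trait()].
#'
#' @param config a [synthetic_config()].
#' @return list with \code{expr} (genes x samples log-intensity matrix)
#'   and \code{truth} (planted ground truth).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  ns <- config$n_samples_per_group
  n <- sum(ns)
  groups <- rep(c("case", "control"), ns)
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  ms <- config$module_specs
  k <- nrow(ms)

  withr::with_seed(config$seed, {
    factors <- matrix(stats::rnorm(k * n), nrow = max(k, 0L), ncol = n,
                      dimnames = list(if (k) paste0("M", seq_len(k)), sample_ids))
    z <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    partition <- rep("noise", config$n_genes)
    loadings <- rep(NA_real_, config$n_genes)
    periph <- matrix(NA_real_, nrow = max(k, 0L), ncol = n)
    offset <- 0L
    for (m in seq_len(k)) {
      idx <- offset + seq_len(ms$size[m])
      offset <- offset + ms$size[m]
      lam <- sqrt(ms$within_cor[m]) +
        stats::runif(ms$size[m], -config$loading_spread, config$loading_spread)
      lam <- pmin(pmax(lam, 0), 0.995)
      eps <- z[idx, , drop = FALSE]
      z[idx, ] <- lam * matrix(factors[m, ], length(idx), n, byrow = TRUE) +
        sqrt(1 - lam^2) * eps
      partition[idx] <- paste0("M", m)
      loadings[idx] <- lam
      # peripheral signal: standardized mean residual of the lowest-loading genes
      np <- max(3L, round(0.1 * ms$size[m]))
      pidx <- order(lam)[seq_len(min(np, length(lam)))]
      pm <- colMeans(eps[pidx, , drop = FALSE] * sqrt(1 - lam[pidx]^2))
      periph[m, ] <- as.numeric(scale(pm))
    }
    expr <- config$intensity_mean + config$noise_sd * z
    dimnames(expr) <- list(gene_ids, sample_ids)
    if (config$missing_frac > 0) {
      nmiss <- round(config$missing_frac * length(expr))
      expr[sample(length(expr), nmiss)] <- NA_real_
    }
  })

  truth <- list(
    planted_partition = stats::setNames(partition, gene_ids),
    planted_eigensignals = factors,
    loadings = stats::setNames(loadings, gene_ids),
    peripheral_signals = periph,
    groups = stats::setNames(groups, sample_ids),
    realized_couplings = NULL
  )
  list(expr = expr, truth = truth)
}

#' Generate the trait and sample table for a synthetic study
#'
#' Builds per-sample age, group, and trait (TBV, cc). The trait is the
#' smooth age trend plus per-module coupled signals plus Gaussian noise,
#' standardized within group so that realized module-eigengene/trait
#' correlations approximate the configured couplings. Realized couplings
#' (empirical correlation between each latent factor and the age-detrended
#' trait, per group) are recorded in the returned truth.
#'
#' @param config a [synthetic_config()].
#' @param truth truth object from [generate_expression()].
#' @return list with \code{samples} (a sample table data frame) and the
#'   updated \code{truth}.
#' @export
generate_trait <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- truth$groups
  n <- length(groups)
  sample_ids <- names(groups)
  k <- nrow(config$module_specs)
  tc <- config$trait_coupling

  withr::with_seed(config$seed + 1L, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    noise <- stats::rnorm(n)
    trait_z <- numeric(n)
    for (g in c("case", "control")) {
      sel <- groups == g
      fh <- config$hub_fraction_coupled[[g]]
      acc <- numeric(sum(sel))
      for (m in seq_len(k)) {
        cc <- tc[m, g]
        if (cc == 0) next
        fz <- as.numeric(scale(truth$planted_eigensignals[m, sel]))
        pz <- as.numeric(scale(truth$peripheral_signals[m, sel]))
        sig <- fh * fz + (1 - fh) * pz
        acc <- acc + cc * as.numeric(scale(sig))
      }
      resid_var <- max(0, 1 - sum(tc[, g]^2))
      trait_z[sel] <- acc + sqrt(resid_var) * as.numeric(scale(noise[sel]))
    }
    tbv <- config$age_effect(age) + config$trait_sd * trait_z
  })

  samples <- data.frame(
    sample_id = sample_ids,
    group = unname(groups),
    age_years = age,
    tbv_cc = tbv,
    tbv_residual_cc = NA_real_,
    replicate_of = NA_character_,
    stringsAsFactors = FALSE
  )
  det <- tbv - config$age_effect(age)
  rc <- matrix(NA_real_, max(k, 0L), 2, dimnames = list(rownames(tc), c("case", "control")))
  for (g in c("case", "control")) {
    sel <- groups == g
    for (m in seq_len(k)) {
      rc[m, g] <- stats::cor(truth$planted_eigensignals[m, sel], det[sel])
    }
  }
  truth$realized_couplings <- rc
  list(samples = samples, truth = truth)
}

#' Generate a complete synthetic two-group study
#'
#' Convenience composition of [generate_expression()] and
#' [generate_trait()]; optionally writes the study in the package's
#' external-interface formats (expression TSV, sample CSV, truth JSON).
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given, \code{expression.tsv},
#'   \code{samples.csv} and \code{truth.json} are written there.
#' @return list with \code{expr}, \code{samples}, \code{truth} and (when
#'   written) \code{paths}.
#' @export
generate_two_group_study <- function(config, dir = NULL) {
  ge <- generate_expression(config)
  gt <- generate_trait(config, ge$truth)
  study <- list(expr = ge$expr, samples = gt$samples, truth = gt$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      expression = file.path(dir, "expression.tsv"),
      samples = file.path(dir, "samples.csv"),
      truth = file.path(dir, "truth.json")
    )
    write_study(study$expr, study$samples, paths$expression, paths$samples)
    truth_json <- list(
      planted_partition = as.list(study$truth$planted_partition),
      realized_couplings = study$truth$realized_couplings,
      groups = as.list(study$truth$groups)
    )
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE, digits = NA)
    study$paths <- paths
  }
  study
}
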