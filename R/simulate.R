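#' Simulate an expression cohort with a known latent activity factor
#'
#' Each sample carries a scalar latent factor z_i ~ N(0, 1) standing in for
#' its true REST activity. Gene g's expression is
#' e_gi = mu_g + beta_g * z_i + eps_gi, eps ~ N(0, sigma^2), where beta_g is
#' +beta for planted positive genes, -beta for planted negative genes and 0
#' for null genes. The population correlation of a planted gene with z is
#' r* = beta / sqrt(beta^2 + sigma^2); the default beta = 1/sqrt(3) with
#' sigma = 1 gives |r*| = 0.5. The designated seed gene is written as a
#' noiseless readout of the factor (e_seed,i = mu + beta z_i), so each
#' gene's correlation with the seed gene equals its correlation with z and
#' the planted r* is what a seed-guided search sees.
#'
#' @param n_samples samples to draw (>= 3).
#' @param n_pos,n_neg,n_null planted positive / negative / null gene counts.
#' @param beta loading magnitude of planted genes.
#' @param sigma residual standard deviation (> 0).
#' @param mu baseline mean expression, scalar or per-gene vector.
#' @param seed_gene name given to the designated seed gene (loads +beta).
#' @param z optional latent factor to reuse (length `n_samples`); lets paired
#'   cohorts share one factor for debugging.
#' @param sample_prefix prefix for generated sample ids.
#' @param gene_names optional list with `pos` / `neg` character vectors to
#'   name planted genes (defaults POS###/NEG###).
#' @param seed RNG seed; identical (arguments, seed) give identical output.
#' @return list with `expr` (expression matrix) and `truth` (list: `z`,
#'   `seed_gene`, `planted_pos`, `planted_neg`, `null_genes`, `beta`,
#'   `sigma`, `r_star`).
#' @export
simulate_cohort <- function(n_samples, n_pos = 30, n_neg = 10, n_null = 500,
                            beta = 1 / sqrt(3), sigma = 1, mu = 8,
                            seed_gene = "REST", z = NULL,
                            sample_prefix = "S", gene_names = NULL,
                            seed = NULL) {
  if (n_samples < 3L) stop("need at least 3 samples (correlations undefined below)")
  stopifnot(n_pos >= 0, n_neg >= 0, n_null >= 0, sigma > 0)
  pos_names <- gene_names$pos %||% sprintf("POS%03d", seq_len(n_pos))
  neg_names <- gene_names$neg %||% sprintf("NEG%03d", seq_len(n_neg))
  if (length(pos_names) != n_pos || length(neg_names) != n_neg) {
    stop("gene_names lengths must match n_pos / n_neg")
  }
  null_names <- if (n_null) sprintf("NULL%04d", seq_len(n_null)) else character()
  genes <- c(seed_gene, pos_names, neg_names, null_names)
  if (anyDuplicated(genes)) stop("generated gene names collide")
  betas <- c(beta, rep(beta, n_pos), rep(-beta, n_neg), rep(0, n_null))
  mu <- rep_len(mu, length(genes))
  with_seed(seed, {
    if (is.null(z)) z <- stats::rnorm(n_samples)
    if (length(z) != n_samples) stop("z must have length n_samples")
    eps <- matrix(stats::rnorm(length(genes) * n_samples, sd = sigma),
                  nrow = length(genes))
    # The seed gene is a noiseless readout of the latent factor, so that a
    # gene's correlation with the seed equals its correlation with z (= r*).
    eps[1L, ] <- 0
    vals <- mu + outer(betas, z) + eps
    dimnames(vals) <- list(genes, sprintf("%s%04d", sample_prefix,
                                          seq_len(n_samples)))
    names(z) <- colnames(vals)
    list(expr = expression_matrix(vals),
         truth = list(z = z, seed_gene = seed_gene, planted_pos = pos_names,
                      planted_neg = neg_names, null_genes = null_names,
                      beta = beta, sigma = sigma,
                      r_star = beta / sqrt(beta^2 + sigma^2)))
  })
}

#' Simulate survival times driven by a latent factor
#'
#' Event times are exponential with hazard h0 * exp(gamma * z_i); censoring
#' times are uniform on [0, T_max] with T_max solved numerically so that the
#' expected censored fraction equals `censor_frac`. With `censor_frac = 0`
#' every event is observed.
#'
#' @param z latent factor per sample (finite; names become sample ids).
#' @param gamma log-hazard increase per unit of z.
#' @param h0 baseline hazard (> 0), per day.
#' @param censor_frac target fraction censored, in [0, 1).
#' @param sample_ids sample identifiers; default `names(z)`.
#' @param seed RNG seed.
#' @return a `survival_table` with the true `z` attached as covariate column.
#' @export
simulate_survival <- function(z, gamma, h0 = 1 / 500, censor_frac = 0.3,
                              sample_ids = names(z), seed = NULL) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (h0 <= 0) stop("h0 must be > 0")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must be in [0, 1)")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_along(z))
  rate <- h0 * exp(gamma * z)
  with_seed(seed, {
    t_event <- stats::rexp(length(z), rate = rate)
    if (censor_frac == 0) {
      time <- t_event
      event <- rep(1, length(z))
    } else {
      # P(censored | T_max) = mean_i (1 - exp(-rate_i T)) / (rate_i T),
      # monotone decreasing in T; solve for the target fraction.
      p_cens <- function(tm) mean((1 - exp(-rate * tm)) / (rate * tm))
      upper <- 1 / min(rate)
      while (p_cens(upper) > censor_frac) upper <- upper * 2
      t_max <- stats::uniroot(function(tm) p_cens(tm) - censor_frac,
                              lower = 1e-8 / max(rate), upper = upper,
                              tol = 1e-10)$root
      c_time <- stats::runif(length(z), 0, t_max)
      event <- as.numeric(t_event <= c_time)
      time <- pmin(t_event, c_time)
    }
    survival_table(sample_ids, time, event, covariates = data.frame(z = z))
  })
}

#' Simulate auxiliary feature matrices tied to the latent factor
#'
#' Gaussian features reuse the expression model (miRNA-style panels):
#' x_fi = baseline_f + effect_f * z_i + N(0, sigma^2). Binary features are
#' mutation-style indicators x_fi ~ Bernoulli(plogis(baseline_f +
#' effect_f * z_i)), so a positive effect makes carriers have higher mean z.
#'
#' @param z latent factor per sample.
#' @param n_features number of features.
#' @param effects per-feature effect sizes (recycled to `n_features`).
#' @param family `"gaussian"` or `"binary"`.
#' @param baseline per-feature intercept (gaussian mean / logit carrier rate);
#'   recycled. Default 0 for gaussian, -1 for binary.
#' @param sigma gaussian residual sd.
#' @param prefix feature-name prefix.
#' @param sample_ids sample identifiers; default `names(z)`.
#' @param seed RNG seed.
#' @return features x samples numeric matrix with an `effects` attribute.
#' @export
simulate_feature_matrix <- function(z, n_features, effects = 0,
                                    family = c("gaussian", "binary"),
                                    baseline = NULL, sigma = 1,
                                    prefix = NULL, sample_ids = names(z),
                                    seed = NULL) {
  family <- match.arg(family)
  effects <- rep_len(effects, n_features)
  baseline <- rep_len(baseline %||% if (family == "binary") -1 else 0,
                      n_features)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_along(z))
  prefix <- prefix %||% if (family == "binary") "MUT" else "FEAT"
  with_seed(seed, {
    lin <- baseline + outer(effects, z)
    x <- if (family == "gaussian") {
      lin + matrix(stats::rnorm(n_features * length(z), sd = sigma),
                   nrow = n_features)
    } else {
      matrix(stats::rbinom(n_features * length(z), 1L, stats::plogis(lin)),
             nrow = n_features)
    }
    dimnames(x) <- list(sprintf("%s%03d", prefix, seq_len(n_features)),
                        sample_ids)
    attr(x, "effects") <- stats::setNames(effects, rownames(x))
    x
  })
}

#' Simulate a log-IC50 drug-response table with group effects
#'
#' Log IC50 of cell line i on drug d is N(baseline_d + delta_d * [i in the
#' "high" group], sigma^2). A negative planted delta makes the high-activity
#' group more sensitive (smaller IC50, fold change < 1).
#'
#' @param group_labels factor/character per cell line with two levels
#'   (reference level = "low" arm); names become cell-line ids.
#' @param drug_effects named numeric vector of per-drug deltas (log scale).
#' @param sigma residual sd of log IC50.
#' @param baseline per-drug baseline log IC50 (recycled).
#' @param seed RNG seed.
#' @return drugs x cell-lines numeric matrix of log IC50 values.
#' @export
simulate_drug_response <- function(group_labels, drug_effects, sigma = 0.5,
                                   baseline = 0, seed = NULL) {
  labs <- as.factor(group_labels)
  if (nlevels(labs) < 2L) stop("need at least two groups of cell lines")
  if (any(table(labs) < 2L)) stop("need at least 2 cell lines per group")
  if (is.null(names(drug_effects))) {
    names(drug_effects) <- sprintf("DRUG%03d", seq_along(drug_effects))
  }
  ids <- names(group_labels) %||% sprintf("CL%03d", seq_along(labs))
  high <- as.numeric(labs == levels(labs)[2L])
  baseline <- rep_len(baseline, length(drug_effects))
  with_seed(seed, {
    m <- baseline + outer(drug_effects, high)
    x <- m + matrix(stats::rnorm(length(m), sd = sigma), nrow = nrow(m))
    dimnames(x) <- list(names(drug_effects), ids)
    x
  })
}

#' Simulate a healthy-tissue panel with depressed brain activity
#'
#' Emulates a multi-tissue panel in which brain-derived samples have lower
#' latent REST activity: brain samples draw z ~ N(-delta_brain, 1), all other
#' tissues z ~ N(0, 1); expression then follows the planted-gene model of
#' [simulate_cohort()].
#'
#' @param n_brain,n_other sample counts per class.
#' @param delta_brain downward shift of the brain-class latent mean (in sd
#'   units of z).
#' @param n_pos,n_neg,n_null,beta,sigma,mu passed to the expression model.
#' @param seed RNG seed.
#' @return list with `expr`, `tissue` (character per sample: "brain_region_k"
#'   or a non-brain tissue name), `is_brain` (logical), and `truth`.
#' @export
simulate_healthy_panel <- function(n_brain = 7, n_other = 36, delta_brain = 2,
                                   n_pos = 30, n_neg = 10, n_null = 100,
                                   beta = 1 / sqrt(3), sigma = 1, mu = 8,
                                   seed = NULL) {
  if (n_brain + n_other < 2L) stop("need at least two tissue samples")
  if (n_brain == 0L && delta_brain != 0) {
    warning("delta_brain has no effect with zero brain samples")
  }
  others <- c("adipose", "adrenal", "bladder", "blood", "bone", "breast",
              "colon", "esophagus", "heart", "kidney", "liver", "lung",
              "muscle", "ovary", "pancreas", "prostate", "skin", "spleen",
              "stomach", "testis", "thyroid", "uterus")
  with_seed(seed, {
    z <- c(stats::rnorm(n_brain, mean = -delta_brain),
           stats::rnorm(n_other, mean = 0))
    sim <- simulate_cohort(n_samples = n_brain + n_other, n_pos = n_pos,
                           n_neg = n_neg, n_null = n_null, beta = beta,
                           sigma = sigma, mu = mu, z = z,
                           sample_prefix = "HT", seed = NULL)
    tissue <- c(sprintf("brain_region_%d", seq_len(n_brain)),
                sprintf("%s_%d", rep_len(others, n_other),
                        seq_len(n_other)))
    sim$tissue <- tissue
    sim$is_brain <- c(rep(TRUE, n_brain), rep(FALSE, n_other))
    sim$truth$delta_brain <- delta_brain
    sim
  })
}

#' Simulate a complete two-cohort study with every downstream data type
#'
#' Generates the full bundle the pipeline consumes: a small cell-line cohort
#' and a larger tumor cohort sharing the planted-gene design (independent
#' latent factors by default), tumor survival driven by the tumor factor,
#' binary mutations and a gaussian miRNA panel tied to the tumor factor, a
#' drug screen with one strongly sensitizing drug among nulls (groups taken
#' from the cell-line factor's median split), and a healthy-tissue panel.
#'
#' @param n_tumors,n_cell_lines cohort sizes.
#' @param n_pos,n_neg,n_null,beta,sigma planted-gene design shared by both
#'   cohorts (defaults give true planted |r*| = 0.5).
#' @param gamma log hazard per unit latent factor in the tumor cohort.
#' @param h0,censor_frac survival baseline hazard and censored fraction.
#' @param n_mutations,mutation_delta mutation panel size and planted effects
#'   (first `length(mutation_delta)` features planted, rest null).
#' @param n_mirna,mirna_beta miRNA panel size and planted loadings.
#' @param n_null_drugs,drug_delta,drug_sigma drug screen: one planted drug
#'   (`drug_delta` log-fold effect, negative = high group sensitive) among
#'   `n_null_drugs` inert drugs.
#' @param shared_z reuse the tumor latent factor for the cell lines
#'   (debugging aid; default FALSE, disjoint cohorts).
#' @param seed master RNG seed; every component draws from a stream derived
#'   from it.
#' @return list with elements `cell_lines`, `tumors` (each expr + truth),
#'   `clinical`, `mutations`, `mirna`, `ic50`, `cell_line_groups`, `healthy`,
#'   and `config`.
#' @export
simulate_study <- function(n_tumors = 400, n_cell_lines = 50, n_pos = 30,
                           n_neg = 10, n_null = 500, beta = 1 / sqrt(3),
                           sigma = 1, gamma = log(1.5), h0 = 1 / 500,
                           censor_frac = 0.3, n_mutations = 20,
                           mutation_delta = c(2, 2), n_mirna = 50,
                           mirna_beta = 0.6, n_null_drugs = 30,
                           drug_delta = -2, drug_sigma = 0.5,
                           shared_z = FALSE, seed = 1) {
  tum <- simulate_cohort(n_tumors, n_pos, n_neg, n_null, beta, sigma,
                         sample_prefix = "TCGA", seed = child_seed(seed, 1))
  cl <- simulate_cohort(n_cell_lines, n_pos, n_neg, n_null, beta, sigma,
                        sample_prefix = "CL",
                        z = if (shared_z) tum$truth$z[seq_len(n_cell_lines)] else NULL,
                        seed = child_seed(seed, 2))
  clinical <- simulate_survival(tum$truth$z, gamma = gamma, h0 = h0,
                                censor_frac = censor_frac,
                                seed = child_seed(seed, 3))
  mut_eff <- c(mutation_delta, rep(0, max(0L, n_mutations - length(mutation_delta))))
  mutations <- simulate_feature_matrix(tum$truth$z, n_mutations, mut_eff,
                                       family = "binary",
                                       seed = child_seed(seed, 4))
  mir_eff <- c(rep(mirna_beta, 5), rep(-mirna_beta, 5),
               rep(0, max(0L, n_mirna - 10)))[seq_len(n_mirna)]
  mirna <- simulate_feature_matrix(tum$truth$z, n_mirna, mir_eff,
                                   family = "gaussian", prefix = "MIR",
                                   seed = child_seed(seed, 5))
  groups <- factor(ifelse(cl$truth$z <= stats::median(cl$truth$z),
                          "low", "high"), levels = c("low", "high"))
  names(groups) <- names(cl$truth$z)
  drug_eff <- c(DRUG_PLANTED = drug_delta,
                stats::setNames(rep(0, n_null_drugs),
                                sprintf("DRUG%03d", seq_len(n_null_drugs))))
  ic50 <- simulate_drug_response(groups, drug_eff, sigma = drug_sigma,
                                 seed = child_seed(seed, 6))
  healthy <- simulate_healthy_panel(seed = child_seed(seed, 7))
  list(cell_lines = cl, tumors = tum, clinical = clinical,
       mutations = mutations, mirna = mirna, ic50 = ic50,
       cell_line_groups = groups, healthy = healthy,
       config = list(n_tumors = n_tumors, n_cell_lines = n_cell_lines,
                     n_pos = n_pos, n_neg = n_neg, n_null = n_null,
                     beta = beta, sigma = sigma, gamma = gamma, h0 = h0,
                     censor_frac = censor_frac, seed = seed))
}
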