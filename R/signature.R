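#' Correlate every gene against a seed gene
#'
#' Computes the Pearson correlation of each gene's expression with the seed
#' gene's expression across samples of one cohort. Genes with zero variance
#' cannot be correlated and are excluded (their names are reported in the
#' `dropped` field). The seed gene itself maps to exactly 1.
#'
#' @param expr expression matrix (genes x samples).
#' @param seed_gene gene symbol present in `expr`.
#' @param cohort optional cohort label carried through to the result.
#' @return object of class `correlation_profile`: list with `r` (named vector
#'   of correlations), `n` (samples used), `seed_gene`, `cohort`, `dropped`.
#' @export
pearson_profile <- function(expr, seed_gene, cohort = "cohort") {
  validate_expression_matrix(expr)
  if (!seed_gene %in% rownames(expr)) {
    stop("seed gene '", seed_gene, "' not found in expression matrix")
  }
  if (ncol(expr) < 3L) stop("need at least 3 samples to correlate")
  seed <- expr[seed_gene, ]
  if (stats::sd(seed) == 0) stop("seed gene '", seed_gene, "' has zero variance")
  sds <- apply(expr, 1L, stats::sd)
  dropped <- rownames(expr)[sds == 0]
  keep <- sds > 0
  r <- as.vector(stats::cor(t(expr[keep, , drop = FALSE]), seed))
  names(r) <- rownames(expr)[keep]
  r[seed_gene] <- 1  # guard against fp round-off in self-correlation
  structure(list(r = r, n = ncol(expr), seed_gene = seed_gene,
                 cohort = cohort, dropped = dropped),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("Seed-gene correlation profile ('%s', seed '%s'): %d genes over %d samples\n",
              x$cohort, x$seed_gene, length(x$r), x$n))
  if (length(x$dropped)) {
    cat("  dropped (zero variance):", length(x$dropped), "gene(s)\n")
  }
  invisible(x)
}

new_exprest <- function(genes, seed_gene, cutoff, cohorts, call = NULL,
                        n = c(NA_integer_, NA_integer_)) {
  structure(list(genes = genes, seed_gene = seed_gene, cutoff = cutoff,
                 cohorts = cohorts, n = n, call = call),
            class = "exprest")
}

#' Derive a two-set signature from two correlation profiles
#'
#' A gene becomes a signature member iff its correlations with the seed gene
#' agree in sign between the two cohorts and both reach `cutoff` in absolute
#' value. Positive members form the REST-type set (G_R), negative members the
#' RESTless-type set (G_L). The seed gene itself is kept in G_R unless
#' `include_seed = FALSE`.
#'
#' @param profile_a,profile_b `correlation_profile` objects sharing a seed.
#' @param cutoff absolute-correlation cutoff, default 0.3.
#' @param rule how the cutoff is applied across the two cohorts: `"both"`
#'   (default; |r| >= cutoff in each cohort), `"either"`, or `"mean"`
#'   ((|r_a| + |r_b|)/2 >= cutoff). Sign consistency is always required.
#' @param include_seed keep the seed gene in G_R (default TRUE).
#' @return an `exprest` signature object.
#' @export
derive_signature <- function(profile_a, profile_b, cutoff = 0.3,
                             rule = c("both", "either", "mean"),
                             include_seed = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile_a, "correlation_profile"),
            inherits(profile_b, "correlation_profile"))
  if (profile_a$seed_gene != profile_b$seed_gene) {
    stop("profiles were built from different seed genes")
  }
  seed_gene <- profile_a$seed_gene
  shared <- intersect(names(profile_a$r), names(profile_b$r))
  if (length(setdiff(shared, seed_gene)) == 0L) {
    stop("correlation profiles share no genes beyond the seed")
  }
  ra <- profile_a$r[shared]
  rb <- profile_b$r[shared]
  consistent <- sign(ra) == sign(rb) & ra != 0
  strong <- switch(rule,
    both = pmin(abs(ra), abs(rb)) >= cutoff,
    either = pmax(abs(ra), abs(rb)) >= cutoff,
    mean = (abs(ra) + abs(rb)) / 2 >= cutoff)
  member <- consistent & strong
  member[shared == seed_gene] <- include_seed
  if (!any(member)) stop("empty signature: no gene passes the cutoff")
  genes <- data.frame(gene = shared[member],
                      set = ifelse(ra[member] > 0, "REST", "RESTless"),
                      r_cohort_a = unname(ra[member]),
                      r_cohort_b = unname(rb[member]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$set, -abs(genes$r_cohort_a)), , drop = FALSE]
  rownames(genes) <- NULL
  new_exprest(genes, seed_gene, cutoff,
              cohorts = c(profile_a$cohort, profile_b$cohort),
              n = c(profile_a$n, profile_b$n),
              call = sys.call(-1L))
}

#' Fit a seed-guided expression signature on two cohorts
#'
#' The fitting function of the package: correlates every gene with the seed
#' gene in each of two cohorts (e.g. CNS cell lines and tumors), keeps genes
#' whose correlations are sign-consistent and at least `cutoff` in magnitude,
#' and returns the resulting two-set signature. Samples are then scored with
#' [predict.exprest()]: the score of a sample is the mean expression of the
#' REST-type genes minus the mean expression of the RESTless-type genes, so a
#' larger score means higher seed-gene (REST) activity.
#'
#' @param cohort_a,cohort_b expression matrices (genes x samples); gene
#'   universes must overlap beyond the seed gene.
#' @param seed_gene seed gene symbol, default `"REST"`.
#' @param cutoff absolute-correlation cutoff, default 0.3.
#' @param rule cutoff rule across cohorts; see [derive_signature()].
#' @param include_seed keep the seed gene in the positive set.
#' @return an object of class `exprest` with components `genes` (data.frame:
#'   gene, set, r_cohort_a, r_cohort_b), `seed_gene`, `cutoff`, `cohorts`,
#'   `n`, `call`.
#' @seealso [predict.exprest()], [rest_score()], [dichotomize_by_median()]
#' @examples
#' sim_a <- simulate_cohort(n_samples = 50, n_pos = 10, n_neg = 5,
#'                          n_null = 50, seed = 1)
#' sim_b <- simulate_cohort(n_samples = 120, n_pos = 10, n_neg = 5,
#'                          n_null = 50, seed = 2)
#' fit <- exprest(sim_a$expr, sim_b$expr, seed_gene = "REST")
#' fit
#' scores <- predict(fit, sim_b$expr)
#' @export
exprest <- function(cohort_a, cohort_b, seed_gene = "REST", cutoff = 0.3,
                    rule = c("both", "either", "mean"), include_seed = TRUE) {
  rule <- match.arg(rule)
  pa <- pearson_profile(cohort_a, seed_gene, cohort = "cohort_a")
  pb <- pearson_profile(cohort_b, seed_gene, cohort = "cohort_b")
  if (length(intersect(names(pa$r), names(pb$r))) == 0L) {
    stop("cohorts share no genes")
  }
  fit <- derive_signature(pa, pb, cutoff = cutoff, rule = rule,
                          include_seed = include_seed)
  fit$call <- match.call()
  fit
}

#' REST-type and RESTless-type member genes of a signature
#'
#' @param signature an `exprest` object.
#' @return character vector of gene symbols.
#' @export
rest_type_genes <- function(signature) {
  signature$genes$gene[signature$genes$set == "REST"]
}

#' @rdname rest_type_genes
#' @export
restless_type_genes <- function(signature) {
  signature$genes$gene[signature$genes$set == "RESTless"]
}

#' @export
print.exprest <- function(x, ...) {
  cat("Seed-guided expression signature\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Seed gene: %s   cutoff |r| >= %s\n", x$seed_gene,
              format(x$cutoff)))
  cat(sprintf("%d genes: %d REST-type (G_R), %d RESTless-type (G_L)\n",
              nrow(x$genes), length(rest_type_genes(x)),
              length(restless_type_genes(x))))
  invisible(x)
}

#' @export
summary.exprest <- function(object, ...) {
  g <- object$genes
  out <- list(signature = object,
              n_rest = length(rest_type_genes(object)),
              n_restless = length(restless_type_genes(object)),
              cor_range_a = range(g$r_cohort_a),
              cor_range_b = range(g$r_cohort_b),
              top = utils::head(g[order(-pmin(abs(g$r_cohort_a),
                                              abs(g$r_cohort_b))), ], 10L))
  class(out) <- "summary.exprest"
  out
}

#' @export
print.summary.exprest <- function(x, ...) {
  print(x$signature)
  cat(sprintf("cohort A correlations in [%.3f, %.3f]; cohort B in [%.3f, %.3f]\n",
              x$cor_range_a[1L], x$cor_range_a[2L],
              x$cor_range_b[1L], x$cor_range_b[2L]))
  cat("Strongest members:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.exprest <- function(object, ...) {
  # signed per-gene weight: mean cross-cohort correlation, sign = set side
  g <- object$genes
  stats::setNames((g$r_cohort_a + g$r_cohort_b) / 2, g$gene)
}

#' Scatter of per-gene correlations across the two derivation cohorts
#'
#' @param x an `exprest` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.exprest <- function(x, ...) {
  g <- x$genes
  col <- ifelse(g$set == "REST", "firebrick", "navy")
  graphics::plot(g$r_cohort_a, g$r_cohort_b, col = col, pch = 19,
                 xlab = sprintf("r with %s (%s)", x$seed_gene, x$cohorts[1L]),
                 ylab = sprintf("r with %s (%s)", x$seed_gene, x$cohorts[2L]),
                 main = "Signature member correlations", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(h = c(-x$cutoff, x$cutoff), v = c(-x$cutoff, x$cutoff),
                   lty = 3, col = "grey70")
  invisible(x)
}

#' Score samples with a two-set signature
#'
#' The score of sample i is the mean expression of REST-type genes minus the
#' mean expression of RESTless-type genes:
#' S_i = mean(e_gi, g in G_R) - mean(e_gi, g in G_L).
#' With `standardize = "zscore"` each gene is z-scored across the scored
#' cohort first, which makes scores comparable across platforms; `"none"`
#' applies the formula to the raw values. Signature genes absent from the
#' matrix are skipped; a warning is raised if either set's coverage drops
#' below 80%. An empty RESTless set contributes 0.
#'
#' @param expr expression matrix to score.
#' @param signature an `exprest` object.
#' @param standardize `"zscore"` (default) or `"none"`.
#' @return a data.frame of class `rest_scores` with columns `sample` and
#'   `score`, plus attributes `coverage` (fraction of each set found) and
#'   `standardize`.
#' @export
rest_score <- function(expr, signature, standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  validate_expression_matrix(expr)
  stopifnot(inherits(signature, "exprest"))
  gr <- rest_type_genes(signature)
  gl <- restless_type_genes(signature)
  gr_in <- intersect(gr, rownames(expr))
  gl_in <- intersect(gl, rownames(expr))
  if (length(gr_in) + length(gl_in) == 0L) {
    stop("no signature gene present in the expression matrix")
  }
  cov_r <- if (length(gr)) length(gr_in) / length(gr) else NA_real_
  cov_l <- if (length(gl)) length(gl_in) / length(gl) else NA_real_
  low <- c(if (isTRUE(cov_r < 0.8)) "REST", if (isTRUE(cov_l < 0.8)) "RESTless")
  if (length(low)) {
    warning("signature coverage below 80% for set(s): ",
            paste(low, collapse = ", "))
  }
  x <- expr
  if (standardize == "zscore") {
    if (ncol(x) < 2L) stop("z-scoring needs at least 2 samples")
    use <- unique(c(gr_in, gl_in))
    x <- x[use, , drop = FALSE]
    mu <- rowMeans(x)
    sd_ <- apply(x, 1L, stats::sd)
    sd_[sd_ == 0] <- 1  # constant genes carry no signal; leave them at 0
    x <- (x - mu) / sd_
  }
  mean_r <- if (length(gr_in)) colMeans(x[gr_in, , drop = FALSE]) else 0
  mean_l <- if (length(gl_in)) colMeans(x[gl_in, , drop = FALSE]) else 0
  s <- mean_r - mean_l
  out <- data.frame(sample = colnames(expr), score = as.numeric(s),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- c(REST = cov_r, RESTless = cov_l)
  attr(out, "standardize") <- standardize
  class(out) <- c("rest_scores", "data.frame")
  out
}

#' Score new samples with a fitted signature
#'
#' @param object an `exprest` object.
#' @param newdata expression matrix to score.
#' @param standardize `"zscore"` (default) or `"none"`; see [rest_score()].
#' @param dichotomize also split samples into low/high groups at the median.
#' @param ... unused.
#' @return a `rest_scores` data.frame (with a `group` column when
#'   `dichotomize = TRUE`).
#' @export
predict.exprest <- function(object, newdata, standardize = c("zscore", "none"),
                            dichotomize = FALSE, ...) {
  scores <- rest_score(newdata, object, standardize = match.arg(standardize))
  if (dichotomize) scores <- dichotomize_by_median(scores)
  scores
}

#' Simulate cohorts whose planted structure matches a fitted signature
#'
#' Generates expression matrices in which each signature member loads on a
#' latent activity factor with the sign of its set (+ for REST-type, - for
#' RESTless-type), plus unrelated null genes — useful for power checks of a
#' derived signature's size and composition.
#'
#' @param object an `exprest` object.
#' @param nsim number of cohorts to generate.
#' @param seed RNG seed.
#' @param n_samples samples per cohort.
#' @param beta loading magnitude per planted gene.
#' @param sigma residual standard deviation.
#' @param n_null unrelated null genes appended.
#' @param ... unused.
#' @return a list of `nsim` elements, each a list with `expr` and `truth`
#'   (as in [simulate_cohort()]).
#' @export
simulate.exprest <- function(object, nsim = 1, seed = NULL, n_samples = 100,
                             beta = 0.5, sigma = 1, n_null = 200, ...) {
  gr <- setdiff(rest_type_genes(object), object$seed_gene)
  gl <- restless_type_genes(object)
  lapply(seq_len(nsim), function(k) {
    simulate_cohort(n_samples = n_samples, n_pos = length(gr),
                    n_neg = length(gl), n_null = n_null, beta = beta,
                    sigma = sigma, seed = child_seed(seed, k),
                    gene_names = list(pos = gr, neg = gl),
                    seed_gene = object$seed_gene)
  })
}

#' Split scored samples into low/high groups at the median
#'
#' Samples with score <= median are labelled `"low"`, the rest `"high"`.
#' The tie-at-median rule keeps groups deterministic and near-balanced (with
#' distinct scores the group sizes differ by at most one).
#'
#' @param scores a `rest_scores` data.frame (or any data.frame with `sample`
#'   and `score` columns).
#' @return `scores` with a `group` factor column (levels low, high).
#' @export
dichotomize_by_median <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("sample", "score") %in% names(scores)))
  s <- scores$score
  if (length(s) < 2L) stop("need at least 2 samples to dichotomize")
  if (length(unique(s)) == 1L) stop("degenerate split: all scores identical")
  med <- stats::median(s)
  scores$group <- factor(ifelse(s <= med, "low", "high"),
                         levels = c("low", "high"))
  scores
}

#' @export
print.rest_scores <- function(x, ...) {
  cat(sprintf("REST scores for %d samples (standardize = %s)\n", nrow(x),
              attr(x, "standardize") %||% "?"))
  cat(sprintf("  range [%.3f, %.3f], median %.3f\n", min(x$score),
              max(x$score), stats::median(x$score)))
  if (!is.null(x$group)) print(table(x$group))
  invisible(x)
}
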