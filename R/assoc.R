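# Coerce scores given as a rest_scores data.frame or named numeric vector.
as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample", "score") %in% names(scores)))
    return(stats::setNames(scores$score, scores$sample))
  }
  if (is.numeric(scores)) return(scores)
  stop("scores must be a rest_scores data.frame or a numeric vector")
}

# All permutations of 1..n as an (n! x n) integer matrix, in lexicographic
# order of the leading element. Practical up to n = 10.
all_permutations <- function(n) {
  if (n > 10L) stop("permutation enumeration supported up to n = 10")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Spearman rho with midranks, plus a two-sided p-value: exact by full
# permutation enumeration for n <= `exact_max`, t approximation otherwise.
spearman_test <- function(x, y, exact_max = 10L) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  sx <- stats::sd(rx)
  sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # rho is linear in sum(rx * ry_perm); enumerate that inner product
    s <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    mx <- mean(rx); my <- mean(ry)
    rho_perm <- (s / n - mx * my) / (sx * sy) * n / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

#' Spearman scan of a score against a feature matrix
#'
#' Rank-correlates the per-sample score with every feature (gene, protein or
#' miRNA) over the shared samples. Ties get midranks. P-values are two-sided:
#' exact by permutation enumeration for n <= 10, t approximation otherwise.
#' Features with fewer than two distinct values are skipped and reported in
#' the `skipped` attribute.
#'
#' @param scores `rest_scores` data.frame or named numeric vector.
#' @param features features x samples numeric matrix.
#' @return data.frame (class `association_table`) with columns `feature`,
#'   `rho`, `n`, `p`, `p_adj` (Benjamini-Hochberg), ordered by p.
#' @export
spearman_scan <- function(scores, features) {
  s <- as_score_vector(scores)
  shared <- intersect(names(s), colnames(features))
  if (length(shared) < 4L) stop("need at least 4 shared samples")
  s <- s[shared]
  features <- features[, shared, drop = FALSE]
  distinct <- apply(features, 1L, function(v) length(unique(v)))
  skipped <- rownames(features)[distinct < 2L]
  keep <- distinct >= 2L
  res <- lapply(which(keep), function(i) spearman_test(s, features[i, ]))
  out <- data.frame(feature = rownames(features)[keep],
                    rho = vapply(res, `[[`, 0, "rho"),
                    n = vapply(res, `[[`, 0, "n"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("association_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment; monotone and capped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample pooled-variance t test for a score shift
#'
#' Compares mean score between two groups (e.g. mutated vs wildtype) with the
#' equal-variance Student's t test. The reported difference is
#' mean(group 1) - mean(group 0), and Cohen's d divides it by the pooled sd.
#'
#' @param scores `rest_scores` data.frame or numeric vector.
#' @param labels binary group membership per sample (0/1, logical, or a
#'   two-level factor whose second level is "group 1"). If named (or if
#'   scores is a data.frame) samples are matched by id.
#' @return list with `delta`, `t`, `p`, `cohen_d`, `n0`, `n1`, `df`.
#' @export
mean_shift_ttest <- function(scores, labels) {
  s <- as_score_vector(scores)
  if (!is.null(names(labels)) && !is.null(names(s))) {
    shared <- intersect(names(s), names(labels))
    s <- s[shared]
    labels <- labels[shared]
  }
  if (length(labels) != length(s)) stop("scores and labels length mismatch")
  g <- if (is.factor(labels)) as.integer(labels) - 1L
       else as.integer(as.logical(as.numeric(labels)))
  if (any(is.na(g)) || !all(g %in% c(0L, 1L))) stop("labels must be binary")
  x0 <- s[g == 0L]
  x1 <- s[g == 1L]
  if (length(x0) < 2L || length(x1) < 2L) {
    stop("each group needs at least 2 samples")
  }
  sp2 <- ((length(x0) - 1) * stats::var(x0) + (length(x1) - 1) * stats::var(x1)) /
    (length(x0) + length(x1) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- stats::t.test(x1, x0, var.equal = TRUE)
  list(delta = mean(x1) - mean(x0), t = unname(tt$statistic),
       p = tt$p.value, cohen_d = (mean(x1) - mean(x0)) / sqrt(sp2),
       n0 = length(x0), n1 = length(x1), df = unname(tt$parameter))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param scores `rest_scores` data.frame or numeric vector.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples); matched by name when available.
#' @return list with `F`, `p`, `df`, and `tukey` — a data.frame of all
#'   pairwise comparisons (diff, lwr, upr, p_adj from the studentized range
#'   distribution). Tukey p-values are reported for every pair regardless of
#'   the omnibus result.
#' @export
anova_tukey <- function(scores, groups) {
  s <- as_score_vector(scores)
  if (!is.null(names(groups)) && !is.null(names(s))) {
    shared <- intersect(names(s), names(groups))
    s <- s[shared]
    groups <- groups[shared]
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) {
    stop("singleton group(s): ",
         paste(names(which(table(g) < 2L)), collapse = ", "))
  }
  fit <- stats::aov(s ~ g, data = data.frame(s = as.numeric(s), g = g))
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       df = c(an[["Df"]][1L], an[["Df"]][2L]), tukey = tukey)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y paired numeric vectors (>= 3 values, nonzero variance each).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fisher's exact test for set overlap
#'
#' Tests whether an overlap of `k` genes between a set of size `K` and a
#' query of size `n` drawn from a universe of `N` genes is larger than
#' expected (exact hypergeometric tail).
#'
#' @param k overlap size.
#' @param K set size.
#' @param n query (target list) size.
#' @param N universe size.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return list with `odds` (sample odds ratio of the 2x2 table), `p`, and
#'   the `table`.
#' @export
fisher_enrichment <- function(k, K, n, N,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k > min(K, n)) stop("inconsistent margins: overlap exceeds a set size")
  if (N < K + n - k) stop("inconsistent margins: universe too small")
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2L, 2L,
                dimnames = list(in_set = c("yes", "no"),
                                in_query = c("yes", "no")))
  p <- switch(alternative,
    greater = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    less = stats::phyper(k, K, N - K, n),
    two.sided = stats::fisher.test(tab)$p.value)
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds = odds, p = p, table = tab)
}

#' Kolmogorov-Smirnov comparison of two p-value samples
#'
#' Designed for the target-vs-non-target comparison: are association
#' p-values of the target features stochastically smaller than those of
#' non-targets? Default alternative `"smaller"` tests exactly that; exact
#' p-values are used when m*n <= 10^4 and there are no ties.
#'
#' @param x target-sample values (e.g. p-values of validated targets).
#' @param y reference-sample values.
#' @param alternative `"smaller"` (x stochastically smaller), `"two.sided"`,
#'   or `"larger"`.
#' @return list with `D`, `p`, and the sample sizes.
#' @export
ks_shift_test <- function(x, y, alternative = c("smaller", "two.sided",
                                                "larger")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  # stats::ks.test "greater" means the CDF of x lies above y, i.e. x smaller
  alt <- switch(alternative, smaller = "greater", larger = "less",
                two.sided = "two.sided")
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = alt,
                                        exact = length(x) * length(y) <= 1e4))
  list(D = unname(kt$statistic), p = kt$p.value,
       n = c(length(x), length(y)))
}

#' Hypergeometric gene-set enrichment scan
#'
#' Tests each set of a collection for over-representation of the query genes
#' within a stated universe, with Benjamini-Hochberg adjustment across sets.
#' Sets are intersected with the universe before testing.
#'
#' @param query_genes character vector, must be contained in `universe`.
#' @param collection a `gene_set_collection`.
#' @param universe character vector of all testable genes.
#' @return `association_table` data.frame: set, overlap, set_size,
#'   query_size, universe_size, odds, p, p_adj; ordered by p.
#' @export
hypergeom_geneset_scan <- function(query_genes, collection, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query_genes)
  out_of <- setdiff(query, universe)
  if (length(out_of)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(out_of, 5L), collapse = ", "))
  }
  if (!inherits(collection, "gene_set_collection")) {
    collection <- gene_set_collection(collection)
  }
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    k <- length(intersect(query, set))
    fe <- fisher_enrichment(k, length(set), length(query), length(universe),
                            alternative = "greater")
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               odds = fe$odds, p = fe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' Per-drug sensitivity scan between score groups
#'
#' For each drug, compares mean log IC50 between the high- and low-score
#' groups with a pooled t test. The effect is reported as the geometric-mean
#' IC50 ratio fold change = exp(mean log IC50 high - mean log IC50 low), so
#' fold change < 1 means the high-activity group is more sensitive. A
#' `linear_mean` option instead reports the ratio of arithmetic means of the
#' raw IC50s. Drugs with fewer than 2 usable lines in either arm are skipped
#' and reported in the `skipped` attribute.
#'
#' @param group_labels two-level factor/character per cell line (levels
#'   ordered low, high); names are cell-line ids.
#' @param log_ic50 drugs x cell-lines matrix of log IC50 (NA = not screened).
#' @param linear_mean use arithmetic-mean IC50 ratio instead of the
#'   geometric-mean (log-scale) ratio.
#' @return `association_table` data.frame: drug, delta (mean log IC50
#'   difference high - low), fold_change, n_high, n_low, t, p, p_adj.
#' @export
drug_sensitivity_scan <- function(group_labels, log_ic50,
                                  linear_mean = FALSE) {
  labs <- as.factor(group_labels)
  if (nlevels(droplevels(labs)) != 2L) stop("need exactly two groups")
  ids <- names(group_labels) %||% colnames(log_ic50)
  shared <- intersect(ids, colnames(log_ic50))
  if (!length(shared)) stop("no shared cell lines between groups and IC50 table")
  labs <- stats::setNames(labs, ids)[shared]
  m <- log_ic50[, shared, drop = FALSE]
  lv <- levels(droplevels(labs))
  rows <- list()
  skipped <- character()
  for (d in rownames(m)) {
    v <- m[d, ]
    ok <- is.finite(v)
    hi <- v[ok & labs == lv[2L]]
    lo <- v[ok & labs == lv[1L]]
    if (length(hi) < 2L || length(lo) < 2L) {
      skipped <- c(skipped, d)
      next
    }
    delta <- mean(hi) - mean(lo)
    fc <- if (linear_mean) mean(exp(hi)) / mean(exp(lo)) else exp(delta)
    # pooled t computed directly so that zero-variance arms stay defined
    sp2 <- ((length(hi) - 1) * stats::var(hi) +
              (length(lo) - 1) * stats::var(lo)) /
      (length(hi) + length(lo) - 2)
    if (sp2 == 0) {
      tstat <- if (delta == 0) 0 else sign(delta) * Inf
      p <- if (delta == 0) 1 else 0
    } else {
      tstat <- delta / sqrt(sp2 * (1 / length(hi) + 1 / length(lo)))
      p <- 2 * stats::pt(-abs(tstat), df = length(hi) + length(lo) - 2)
    }
    rows[[d]] <- data.frame(drug = d, delta = delta, fold_change = fc,
                            n_high = length(hi), n_low = length(lo),
                            t = tstat, p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no drug with at least 2 cell lines per arm")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("association_table", "data.frame")
  out
}

#' Ward clustering of genes on 1 - Pearson correlation distance
#'
#' Agglomerative clustering with Ward's linkage rule applied (via the
#' Lance-Williams recurrence) to the dissimilarity d(g, h) = 1 - cor(g, h),
#' as used to order signature genes in expression heatmaps. Leaf order is
#' deterministic; ties are broken by input order.
#'
#' @param expr genes x samples expression matrix (>= 2 genes, each with
#'   nonzero variance).
#' @return list with `order` (gene names in leaf order), `heights` (merge
#'   heights), and the underlying `hclust` object.
#' @export
ward_corr_cluster_order <- function(expr) {
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(expr)))
  h <- stats::hclust(d, method = "ward.D")
  list(order = rownames(expr)[h$order], heights = h$height, hclust = h)
}
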