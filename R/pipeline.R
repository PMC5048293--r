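write_table_tsv <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study bundle to disk
#'
#' Serializes every component of [simulate_study()] as plain text: expression
#' TSVs for both cohorts and the healthy panel, clinical TSV, mutation TSV,
#' miRNA TSV, log-IC50 TSV, and a `truth.json` with the latent factors and
#' planted labels.
#'
#' @param study result of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(outdir, x)
  write_expression_matrix(study$cell_lines$expr, f("expr_cell_lines.tsv"))
  write_expression_matrix(study$tumors$expr, f("expr_tumors.tsv"))
  write_expression_matrix(study$healthy$expr, f("expr_healthy.tsv"))
  write_clinical_table(study$clinical, f("clinical.tsv"))
  write_expression_matrix(study$mutations, f("mutations.tsv"))
  write_expression_matrix(study$mirna, f("mirna.tsv"))
  write_expression_matrix(study$ic50, f("ic50.tsv"))
  truth <- list(tumor_z = as.list(study$tumors$truth$z),
                cell_line_z = as.list(study$cell_lines$truth$z),
                planted_pos = study$tumors$truth$planted_pos,
                planted_neg = study$tumors$truth$planted_neg,
                config = study$config)
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("expr_cell_lines.tsv", "expr_tumors.tsv", "expr_healthy.tsv",
             "clinical.tsv", "mutations.tsv", "mirna.tsv", "ic50.tsv",
             "truth.json")
  invisible(stats::setNames(file.path(outdir, files), files))
}

# Built-in gene-set collection over a simulated universe: the planted sets
# plus deterministic null sets carved from the null genes.
planted_gene_sets <- function(truth, n_null_sets = 5L) {
  nulls <- truth$null_genes
  sets <- list(planted_positive = truth$planted_pos,
               planted_negative = truth$planted_neg)
  if (length(nulls) >= n_null_sets * 10L) {
    for (i in seq_len(n_null_sets)) {
      sets[[sprintf("null_set_%d", i)]] <-
        nulls[seq.int(i, by = n_null_sets, length.out = 10L)]
    }
  }
  gene_set_collection(sets)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full signature pipeline
#'
#' Orchestrates derive -> score -> median split -> association battery ->
#' survival on one study, writing every result table plus a manifest with
#' content hashes. Identical configuration and seed give byte-identical
#' outputs.
#'
#' The study can come from two sources: `config$simulate` (a list of
#' [simulate_study()] arguments; the packaged synthetic demo) or
#' `config$inputs` (paths: `cohort_a`, `cohort_b`, `clinical`, and optionally
#' `mutations`, `mirna`, `ic50`, `groups`, `gmt`). A YAML file path may be
#' passed instead of a list (requires the `yaml` package).
#'
#' @param config list (or YAML path) with components `simulate` or `inputs`,
#'   plus optional `seed_gene` ("REST"), `cutoff` (0.3), `standardize`
#'   ("zscore"), `fdr_level` (0.01), `seed` (1).
#' @param outdir output directory.
#' @return list with the in-memory results (`signature`, `scores`, `groups`,
#'   association tables, `survival`, `manifest`), invisibly; files are
#'   written under `outdir`.
#' @export
run_exprest_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  seed_gene <- config$seed_gene %||% "REST"
  cutoff <- config$cutoff %||% 0.3
  standardize <- config$standardize %||% "zscore"
  fdr_level <- config$fdr_level %||% 0.01
  seed <- config$seed %||% 1
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  study <- NULL
  if (!is.null(config$simulate)) {
    study <- run_stage("simulate", do.call(simulate_study,
                                           c(config$simulate,
                                             if (is.null(config$simulate$seed))
                                               list(seed = seed))))
    cohort_a <- study$cell_lines$expr
    cohort_b <- study$tumors$expr
    clinical <- study$clinical
    mutations <- study$mutations
    mirna <- study$mirna
    ic50 <- study$ic50
    sets <- planted_gene_sets(study$tumors$truth)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    paths <- unlist(inp[vapply(inp, is.character, TRUE)])
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    }
    cohort_a <- run_stage("read_cohort_a", read_expression_matrix(inp$cohort_a))
    cohort_b <- run_stage("read_cohort_b", read_expression_matrix(inp$cohort_b))
    clinical <- run_stage("read_clinical", read_clinical_table(inp$clinical))
    mutations <- if (!is.null(inp$mutations))
      run_stage("read_mutations", read_expression_matrix(inp$mutations))
    mirna <- if (!is.null(inp$mirna))
      run_stage("read_mirna", read_expression_matrix(inp$mirna))
    ic50 <- if (!is.null(inp$ic50))
      run_stage("read_ic50", read_expression_matrix(inp$ic50))
    sets <- if (!is.null(inp$gmt)) run_stage("read_gmt", read_gene_sets(inp$gmt))
  } else {
    stop("config must provide either 'simulate' or 'inputs'")
  }

  fit <- run_stage("derive", exprest(cohort_a, cohort_b,
                                     seed_gene = seed_gene, cutoff = cutoff))
  scores_b <- run_stage("score", predict(fit, cohort_b,
                                         standardize = standardize,
                                         dichotomize = TRUE))
  scores_a <- run_stage("score", predict(fit, cohort_a,
                                         standardize = standardize,
                                         dichotomize = TRUE))

  assoc_mrna <- run_stage("associate_mrna", {
    tab <- spearman_scan(scores_b, cohort_b)
    bum <- fit_bum(tab$p[tab$p > 0])
    sig <- bum_significant(bum, tab$p, fdr_level)
    tab$bum_significant <- sig$significant
    attr(tab, "bum") <- bum
    attr(tab, "bum_tau") <- sig$tau
    tab
  })
  assoc_mirna <- if (!is.null(mirna)) {
    run_stage("associate_mirna", spearman_scan(scores_b, mirna))
  }
  assoc_mut <- if (!is.null(mutations)) run_stage("associate_mutations", {
    s <- as_score_vector(scores_b)
    rows <- list()
    skipped <- character()
    for (m in rownames(mutations)) {
      res <- try(mean_shift_ttest(s, mutations[m, ]), silent = TRUE)
      if (inherits(res, "try-error")) {
        skipped <- c(skipped, m)
        next
      }
      rows[[m]] <- data.frame(feature = m, delta = res$delta, t = res$t,
                              cohen_d = res$cohen_d, p = res$p,
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$p_adj <- bh_adjust(tab$p)
    tab <- tab[order(tab$p), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "skipped") <- skipped
    tab
  })
  drugs <- if (!is.null(ic50)) run_stage("drugs", {
    grp <- stats::setNames(scores_a$group, scores_a$sample)
    drug_sensitivity_scan(grp, ic50)
  })
  enrich <- if (!is.null(sets)) run_stage("enrich", {
    universe <- rownames(cohort_b)
    query <- intersect(fit$genes$gene, universe)
    hypergeom_geneset_scan(query, sets, universe)
  })

  surv_res <- run_stage("survival", {
    grp <- stats::setNames(as.character(scores_b$group), scores_b$sample)
    grp <- grp[intersect(names(grp), clinical$sample)]
    lr <- logrank_test(clinical, grp)
    cox_bin <- cox_hr(clinical, factor(grp, levels = c("low", "high")))
    cox_cont <- cox_hr(clinical, as_score_vector(scores_b))
    km <- km_estimate(clinical, grp)
    list(logrank = lr[c("chi2", "p")],
         cox_group = cox_bin[c("coef", "hr", "ci", "p_wald", "n_events")],
         cox_continuous = cox_cont[c("coef", "hr", "ci", "p_wald", "n_events")],
         km = lapply(km, function(cv) as.list(cv[c("time", "surv")])))
  })

  f <- function(x) file.path(outdir, x)
  write_signature(fit, f("signature.tsv"))
  write_table_tsv(scores_b, f("scores.tsv"))
  write_table_tsv(scores_b[, c("sample", "group")], f("groups.tsv"))
  write_table_tsv(scores_a, f("scores_cohort_a.tsv"))
  write_table_tsv(as.data.frame(assoc_mrna), f("assoc_mrna.tsv"))
  if (!is.null(assoc_mirna)) write_table_tsv(as.data.frame(assoc_mirna),
                                             f("assoc_mirna.tsv"))
  if (!is.null(assoc_mut)) write_table_tsv(assoc_mut, f("assoc_mutations.tsv"))
  if (!is.null(drugs)) write_table_tsv(as.data.frame(drugs), f("drugs.tsv"))
  if (!is.null(enrich)) write_table_tsv(as.data.frame(enrich), f("enrich.tsv"))
  jsonlite::write_json(surv_res, f("survival.json"), auto_unbox = TRUE,
                       digits = NA)

  outputs <- list.files(outdir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(
    parameters = list(seed_gene = seed_gene, cutoff = cutoff,
                      standardize = standardize, fdr_level = fdr_level,
                      seed = seed),
    signature = list(n_rest = length(rest_type_genes(fit)),
                     n_restless = length(restless_type_genes(fit))),
    mrna_fdr = list(level = fdr_level, tau = attr(assoc_mrna, "bum_tau"),
                    n_significant = sum(assoc_mrna$bum_significant),
                    pi0_upper = attr(assoc_mrna, "bum")$pi0_upper),
    files = lapply(stats::setNames(outputs, outputs), function(fn) {
      list(md5 = unname(tools::md5sum(file.path(outdir, fn))))
    }))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(signature = fit, scores = scores_b,
                 scores_cohort_a = scores_a, assoc_mrna = assoc_mrna,
                 assoc_mirna = assoc_mirna, assoc_mutations = assoc_mut,
                 drugs = drugs, enrich = enrich, survival = surv_res,
                 manifest = manifest, study = study))
}
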