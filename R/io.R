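#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, log-scale values, and unique row/column identifiers.
#' All package functions that take expression data expect this layout.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids,sample_ids identifiers; default to the dimnames of `values`.
#' @return the matrix with dimnames set, after validation.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  values
}

#' Validate expression-matrix invariants
#'
#' Checks for missing dimnames, duplicated gene or sample identifiers, and
#' non-finite values. Identifiers are case-sensitive.
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_expression_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene (row) and sample (column) names")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: first column holds gene symbols, header row holds sample ids,
#' tab-separated, UTF-8, lines starting with `#` skipped. GCT 1.2 is the
#' standard four-line-header variant with a Description column.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param transform `"none"` or `"log2p1"` (log2(x + 1), for RSEM-style counts
#'   that arrive on the linear scale).
#' @param missing `"error"` (default) rejects missing cells; `"impute_row_mean"`
#'   replaces them with the gene's mean over observed samples.
#' @return a validated expression matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct"),
                                   transform = c("none", "log2p1"),
                                   missing = c("error", "impute_row_mean")) {
  format <- match.arg(format)
  transform <- match.arg(transform)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || trimws(lines[[1L]]) != "#1.2") {
      stop("not a GCT 1.2 file (expected '#1.2' on line 1): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT dimension line: ", path)
    }
    tab <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                             header = TRUE, sep = "\t", quote = "",
                             check.names = FALSE, colClasses = "character")
    if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
      stop(sprintf("GCT header declares %d x %d but data is %d x %d",
                   dims[1L], dims[2L], nrow(tab), ncol(tab) - 2L))
    }
    genes <- tab[[1L]]
    body <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             comment.char = "#", check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L) stop("expression TSV needs a gene column plus samples")
    genes <- tab[[1L]]
    body <- tab[, -1L, drop = FALSE]
  }

  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))

  vals <- matrix(NA_real_, nrow = length(genes), ncol = ncol(body),
                 dimnames = list(genes, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !(cell %in% c("", "NA", "na", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   cell[bad[1L]], genes[bad[1L]], colnames(body)[j]))
    }
    vals[, j] <- num
  }

  if (anyNA(vals)) {
    if (missing == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("missing value at gene '%s', sample '%s' ",
                          "(use missing = 'impute_row_mean' to impute)"),
                   rownames(vals)[bad[1L]], colnames(vals)[bad[2L]]))
    }
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      mu <- mean(vals[i, ], na.rm = TRUE)
      if (is.nan(mu)) stop("gene '", rownames(vals)[i], "' has no observed values")
      vals[i, is.na(vals[i, ])] <- mu
    }
  }
  if (transform == "log2p1") vals <- log2(vals + 1)
  expression_matrix(vals)
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression_matrix(x)
  body <- apply(x, 2L, fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x), dimnames = dimnames(x))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), "na",
                     apply(body, 1L, paste, collapse = "\t"), sep = "\t"), con)
  } else {
    writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member genes).
#' @param descriptions optional character vector, one per set.
#' @return an object of class `gene_set_collection`: a named list of
#'   character vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list of gene vectors")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L)) {
    stop("empty member list in set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  structure(sets, descriptions = stats::setNames(as.character(descriptions),
                                                 names(sets)),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  for (i in seq_along(members)) {
    if (anyDuplicated(members[[i]])) {
      warning("duplicate member gene(s) in set '", nm[i], "' deduplicated")
      members[[i]] <- unique(members[[i]])
    }
  }
  names(members) <- nm
  gene_set_collection(members, desc)
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_set_collection` (or named list of gene vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!inherits(sets, "gene_set_collection")) sets <- gene_set_collection(sets)
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Construct a validated clinical survival table
#'
#' @param sample sample identifiers (unique).
#' @param time follow-up times, non-negative (days).
#' @param event 1 = death observed, 0 = censored.
#' @param covariates optional data.frame of extra per-sample covariates.
#' @return a data.frame of class `survival_table`.
#' @export
survival_table <- function(sample, time, event, covariates = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stop("negative time (times must be >= 0)")
  event <- as.numeric(event)
  if (anyNA(event) || !all(event %in% c(0, 1))) stop("event must be in {0, 1}")
  out <- data.frame(sample = sample, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    out <- cbind(out, as.data.frame(covariates))
  }
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read a clinical survival table from TSV
#'
#' Expects columns `sample`, `time`, `event`; any extra columns are kept as
#' covariates.
#'
#' @param path TSV file path.
#' @return a `survival_table`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- tab[, setdiff(colnames(tab), need), drop = FALSE]
  survival_table(tab$sample, tab$time, tab$event,
                 covariates = if (ncol(extra)) extra else NULL)
}

#' Write a clinical survival table to TSV
#'
#' @param x a `survival_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  out <- x
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signature to its TSV representation
#'
#' Columns: gene, set (`REST` or `RESTless`), r_cohort_a, r_cohort_b.
#' Correlations are written with 6 decimal places.
#'
#' @param signature an `exprest` signature object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "exprest"))
  g <- signature$genes
  out <- data.frame(gene = g$gene, set = g$set,
                    r_cohort_a = sprintf("%.6f", g$r_cohort_a),
                    r_cohort_b = sprintf("%.6f", g$r_cohort_b))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed_gene=%s cutoff=%s", signature$seed_gene,
                     fmt_num(signature$cutoff)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature from its TSV representation
#'
#' @param path signature TSV (columns gene, set, r_cohort_a, r_cohort_b; an
#'   optional `# seed_gene=... cutoff=...` comment line restores metadata).
#' @return an `exprest` signature object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  seed_gene <- NA_character_
  cutoff <- NA_real_
  if (length(meta)) {
    m <- regmatches(meta[1L], regexec("seed_gene=(\\S+)\\s+cutoff=(\\S+)", meta[1L]))[[1L]]
    if (length(m) == 3L) {
      seed_gene <- m[2L]
      cutoff <- as.numeric(m[3L])
    }
  }
  tab <- utils::read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                             value = TRUE), collapse = "\n"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "set", "r_cohort_a", "r_cohort_b")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("signature table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$set), c("REST", "RESTless"))
  if (length(bad)) stop("unknown set label(s): ", paste(bad, collapse = ", "))
  both <- intersect(tab$gene[tab$set == "REST"], tab$gene[tab$set == "RESTless"])
  if (length(both)) stop("gene(s) listed in both sets: ",
                         paste(both, collapse = ", "))
  if (anyDuplicated(tab$gene)) stop("duplicated gene(s) in signature: ",
                                    paste(unique(tab$gene[duplicated(tab$gene)]),
                                          collapse = ", "))
  new_exprest(genes = data.frame(gene = as.character(tab$gene),
                                 set = as.character(tab$set),
                                 r_cohort_a = as.numeric(tab$r_cohort_a),
                                 r_cohort_b = as.numeric(tab$r_cohort_b),
                                 stringsAsFactors = FALSE),
              seed_gene = seed_gene, cutoff = cutoff,
              cohorts = c("cohort_a", "cohort_b"), call = NULL)
}
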